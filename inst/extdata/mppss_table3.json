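{
  "entries": [
    {"pair_id": "hsa00100-hsa00190", "coef": 1.0285978},
    {"pair_id": "hsa00563-hsa00190", "coef": 1.4211556},
    {"pair_id": "hsa00534-hsa00190", "coef": 1.0289191},
    {"pair_id": "hsa00900-hsa00190", "coef": 1.1686399},
    {"pair_id": "hsa00310-hsa00534", "coef": -0.6982631},
    {"pair_id": "hsa00760-hsa00190", "coef": 1.1373381},
    {"pair_id": "hsa00531-hsa00860", "coef": 0.1188049},
    {"pair_id": "hsa00513-hsa00620", "coef": 1.3416181},
    {"pair_id": "hsa01040-hsa00190", "coef": 1.0216412},
    {"pair_id": "hsa00310-hsa00600", "coef": -0.8491503},
    {"pair_id": "hsa00534-hsa00620", "coef": 0.1976417},
    {"pair_id": "hsa00310-hsa00531", "coef": -1.1770501},
    {"pair_id": "hsa00051-hsa00860", "coef": 0.4476219}
  ],
  "intercept": 0,
  "representation": "continuous",
  "provenance": "Published 13-pair blood diagnostic model; the source reports coefficients only, so the representation flag is a package convention (the score formula calls each signature an activity) and the intercept is zero as printed."
}
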