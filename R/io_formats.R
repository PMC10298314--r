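#' Read a GMT gene-set file
#'
#' Parses the standard tab-separated GMT format (one gene set per line:
#' identifier, description, then one or more gene symbols) into a gene-set
#' catalog. The catalog preserves file order, which downstream fixes the
#' enumeration order of pathway pairs, so re-reading the same file always
#' yields the same pair identifiers.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_catalog`: a list with `ids`
#'   (character), `names` (character) and `genes` (list of character
#'   vectors, duplicates within a set removed).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file '", path, "' contains no gene sets")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1L],
         ": expected at least 3 tab-separated fields (id, description, genes...)")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate gene-set id in GMT: ", ids[duplicated(ids)][1L])
  }
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  empty <- which(vapply(genes, length, 1L) == 0L)
  if (length(empty)) stop("gene set '", ids[empty[1L]], "' is empty")
  gene_set_catalog(ids, vapply(fields, `[[`, "", 2L), genes)
}

#' Construct a gene-set catalog
#'
#' @param ids Unique pathway identifiers (e.g. KEGG ids such as "hsa00190").
#' @param names Display names, recycled from `ids` if missing.
#' @param genes List of character vectors of gene symbols, one per pathway.
#' @return A `gene_set_catalog` object.
#' @export
gene_set_catalog <- function(ids, names = ids, genes) {
  ids <- as.character(ids)
  stopifnot(length(ids) == length(genes), length(ids) == length(names))
  if (anyDuplicated(ids)) stop("pathway ids must be unique")
  if (any(vapply(genes, length, 1L) == 0L)) stop("every gene set must be non-empty")
  structure(list(ids = ids, names = as.character(names),
                 genes = lapply(genes, as.character)),
            class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat("gene_set_catalog:", length(x$ids), "pathways,",
      "set sizes", min(lengths(x$genes)), "-", max(lengths(x$genes)), "\n")
  invisible(x)
}

#' Number of pathways in a catalog
#' @param catalog A `gene_set_catalog`.
#' @return Integer pathway count m.
#' @export
n_pathways <- function(catalog) length(catalog$ids)

#' Write a catalog back to GMT
#' @param catalog A `gene_set_catalog`.
#' @param path Output file path.
#' @export
write_gmt <- function(catalog, path) {
  lines <- mapply(function(id, nm, g) paste(c(id, nm, g), collapse = "\t"),
                  catalog$ids, catalog$names, catalog$genes)
  writeLines(lines, path)
  invisible(path)
}

.sniff_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix with sample metadata
#'
#' Reads a delimited genes-by-samples table (first column gene id, header row
#' of sample ids; TSV or CSV decided by extension) plus a metadata table keyed
#' by sample id with at least a `group` column. Structural defects (duplicate
#' gene ids, samples missing from the metadata, non-numeric cells) are
#' rejected, never repaired. Expression is assumed to already be on a
#' log-like scale; no transformation is applied.
#'
#' @param path Expression table path.
#' @param metadata_path Metadata table path (columns: `sample`, `group`,
#'   optionally `subtype`, `batch`).
#' @return An `expr_dataset`: list with `values` (numeric matrix, genes x
#'   samples) and `metadata` (data.frame aligned to the matrix columns).
#' @export
read_expression <- function(path, metadata_path) {
  sep <- .sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"")
  gene_ids <- tab[[1L]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id in expression table: ", gene_ids[duplicated(gene_ids)][1L])
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric expression value at gene '", gene_ids[idx[1L]],
         "', sample '", colnames(vals)[idx[2L]], "'")
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  meta <- utils::read.table(metadata_path, header = TRUE, sep = .sniff_sep(metadata_path),
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(meta))) {
    stop("metadata must have 'sample' and 'group' columns")
  }
  expr_dataset(num, meta)
}

#' Construct an expression dataset
#'
#' @param values Numeric genes-by-samples matrix with unique row and column
#'   names; all values finite.
#' @param metadata Data frame with a `sample` column covering every matrix
#'   column and a `group` column.
#' @return An `expr_dataset` object.
#' @export
expr_dataset <- function(values, metadata) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!all(is.finite(values))) stop("expression values must be finite")
  missing <- setdiff(colnames(values), metadata$sample)
  if (length(missing)) {
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  }
  metadata <- metadata[match(colnames(values), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("expr_dataset:", nrow(x$values), "genes x", ncol(x$values), "samples; groups:",
      paste(names(table(x$metadata$group)), table(x$metadata$group),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write an expression dataset to disk
#' @param x An `expr_dataset`.
#' @param path Expression table output path (TSV or CSV by extension).
#' @param metadata_path Metadata output path; omit to skip.
#' @export
write_expression <- function(x, path, metadata_path = NULL) {
  sep <- .sniff_sep(path)
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.table(x$metadata, metadata_path, sep = .sniff_sep(metadata_path),
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Construct an MPPSS scoring model
#'
#' A model is a sparse linear scorer over pathway-pair signatures: risk score
#' = intercept + sum over entries of coef * signature value, where each
#' signature is the (continuous or discrete) within-sample contrast of a pair
#' of pathway activities named "idA-idB".
#'
#' @param pair_ids Character pair identifiers, "idA-idB".
#' @param coefs Numeric coefficients (log-odds per unit signature).
#' @param intercept Intercept, default 0 (the published formula has none).
#' @param representation "continuous" (activity difference) or "discrete"
#'   (the +/-1 ordering indicator).
#' @param provenance Free-text note on the model's origin.
#' @return An `mppss_model` object.
#' @export
mppss_model <- function(pair_ids, coefs, intercept = 0,
                        representation = c("continuous", "discrete"),
                        provenance = "") {
  representation <- match.arg(representation)
  pair_ids <- as.character(pair_ids)
  coefs <- as.numeric(coefs)
  stopifnot(length(pair_ids) == length(coefs))
  if (anyDuplicated(pair_ids)) stop("duplicate pair ids in model")
  bad <- !grepl("^[^-]+-[^-]+$", pair_ids)
  if (any(bad)) stop("malformed pair id: ", pair_ids[bad][1L])
  if (!all(is.finite(coefs))) stop("model coefficients must be finite")
  structure(list(pair_ids = pair_ids, coefs = coefs,
                 intercept = as.numeric(intercept)[1L],
                 representation = representation, provenance = provenance),
            class = "mppss_model")
}

#' @export
print.mppss_model <- function(x, ...) {
  cat("mppss_model:", length(x$pair_ids), "pair signatures,",
      x$representation, "representation, intercept", format(x$intercept), "\n")
  invisible(x)
}

#' Read / write an MPPSS model as JSON
#'
#' The JSON layout carries the entries list, the intercept, the
#' representation flag and provenance, and round-trips losslessly
#' (coefficients are written with full precision).
#'
#' @param path JSON file path.
#' @return `read_model` returns an `mppss_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$entries)) stop("model JSON lacks an 'entries' list")
  rep_flag <- if (is.null(obj$representation)) "continuous" else obj$representation
  if (!rep_flag %in% c("continuous", "discrete")) {
    stop("unknown representation flag: ", rep_flag)
  }
  ids <- vapply(obj$entries, function(e) as.character(e$pair_id), "")
  coefs <- vapply(obj$entries, function(e) as.numeric(e$coef), 0)
  mppss_model(ids, coefs,
              intercept = if (is.null(obj$intercept)) 0 else as.numeric(obj$intercept),
              representation = rep_flag,
              provenance = if (is.null(obj$provenance)) "" else obj$provenance)
}

#' @rdname read_model
#' @param model An `mppss_model`.
#' @export
write_model <- function(model, path) {
  obj <- list(
    entries = unname(Map(function(id, co) list(pair_id = id, coef = co),
                         model$pair_ids, model$coefs)),
    intercept = model$intercept,
    representation = model$representation,
    provenance = model$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The published 13-signature MPPSS model
#'
#' Loads the bundled pair-coefficient model (13 pathway-pair signatures, no
#' intercept) distributed with the package. Oxidative phosphorylation
#' (hsa00190) appears as the second pathway in 6 of the 13 pairs, so a sample
#' whose other pathways out-rank it scores high.
#'
#' @return An `mppss_model` with 13 entries.
#' @export
mppss_published_model <- function() {
  read_model(system.file("extdata", "mppss_table3.json", package = "mppsig",
                         mustWork = TRUE))
}
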