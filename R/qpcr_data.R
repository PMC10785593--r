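#' Construct a Ct table
#'
#' A Ct table is the substrate of all four stability algorithms: a complete
#' genes x samples matrix of qPCR quantification-cycle (Ct) values, a group
#' label per sample (time point, condition) and a per-gene amplification
#' efficiency E used when converting Ct differences to expression ratios
#' (fold change per cycle; E = 2 is perfect doubling).
#'
#' @param ct numeric matrix, genes in rows, samples in columns, with unique
#'   dimnames.
#' @param groups group label per sample: a character vector or factor either
#'   named by sample id or in column order of `ct`.
#' @param efficiencies per-gene amplification efficiency, a single value or a
#'   vector named by gene id. Must satisfy 1 < E <= 2. Default 2.
#' @param ct_band plausibility band `(lo, hi)`; any Ct outside the open
#'   interval is rejected (catches sentinel values such as 999 or 0 wells).
#' @param validate run completeness/band validation (see
#'   [validate_complete()]).
#' @return An object of class `ct_table`: a list with elements `ct`,
#'   `groups` (factor named by sample id) and `efficiencies` (numeric named
#'   by gene id).
#' @export
ct_table <- function(ct, groups, efficiencies = 2, ct_band = c(0, 45),
                     validate = TRUE) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have gene row names and sample column names")
  if (anyDuplicated(rownames(ct)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (anyDuplicated(colnames(ct)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  storage.mode(ct) <- "double"

  samples <- colnames(ct)
  if (!is.null(names(groups))) {
    missing_grp <- setdiff(samples, names(groups))
    if (length(missing_grp))
      stop("no group label for sample(s): ", paste(missing_grp, collapse = ", "))
    groups <- groups[samples]
  } else if (length(groups) != length(samples)) {
    stop("`groups` must be named by sample id or match the number of samples")
  }
  groups <- factor(as.character(groups))
  names(groups) <- samples
  if (anyNA(groups)) {
    stop("no group label for sample(s): ",
         paste(samples[is.na(groups)], collapse = ", "))
  }

  genes <- rownames(ct)
  if (length(efficiencies) == 1 && is.null(names(efficiencies)))
    efficiencies <- stats::setNames(rep(efficiencies, length(genes)), genes)
  missing_e <- setdiff(genes, names(efficiencies))
  if (length(missing_e))
    stop("no efficiency for gene(s): ", paste(missing_e, collapse = ", "))
  efficiencies <- efficiencies[genes]
  if (any(efficiencies <= 1 | efficiencies > 2))
    stop("amplification efficiencies must satisfy 1 < E <= 2; offending: ",
         paste(genes[efficiencies <= 1 | efficiencies > 2], collapse = ", "))

  x <- structure(list(ct = ct, groups = groups, efficiencies = efficiencies,
                      ct_band = as.numeric(ct_band)),
                 class = "ct_table")
  if (validate) validate_complete(x) else x
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("Ct table: %d genes x %d samples, %d group(s)\n",
              nrow(x$ct), ncol(x$ct), nlevels(x$groups)))
  cat("groups:", paste(sprintf("%s (n=%d)", levels(x$groups),
                               tabulate(x$groups)), collapse = ", "), "\n")
  e <- unique(x$efficiencies)
  cat("efficiency E:",
      if (length(e) == 1) format(e) else "per-gene (see $efficiencies)", "\n")
  invisible(x)
}

#' @export
dim.ct_table <- function(x) dim(x$ct)

#' Subset a Ct table by gene and/or sample
#'
#' @param x a `ct_table`.
#' @param genes,samples character or index selections; `NULL` keeps all.
#' @return A `ct_table` restricted to the selection.
#' @export
subset_ct <- function(x, genes = NULL, samples = NULL) {
  ct <- x$ct
  if (!is.null(genes)) ct <- ct[genes, , drop = FALSE]
  if (!is.null(samples)) ct <- ct[, samples, drop = FALSE]
  ct_table(ct, droplevels(x$groups[colnames(ct)]),
           x$efficiencies[rownames(ct)], x$ct_band, validate = FALSE)
}

#' Validate completeness and plausibility of a Ct table
#'
#' The stability algorithms all assume a complete matrix: a silently dropped
#' well would change the geNorm/NormFinder estimates. Missing or out-of-band
#' Ct values are therefore a hard error listing every offending cell;
#' `drop_incomplete_genes = TRUE` instead removes the offending genes.
#'
#' @param x a `ct_table`.
#' @param drop_incomplete_genes drop genes with any bad cell instead of
#'   erroring.
#' @return The validated (possibly gene-reduced) `ct_table`.
#' @export
validate_complete <- function(x, drop_incomplete_genes = FALSE) {
  stopifnot(inherits(x, "ct_table"))
  band <- x$ct_band
  bad <- !is.finite(x$ct) | x$ct <= band[1] | x$ct >= band[2]
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    cells <- paste0("(", rownames(x$ct)[idx[, 1]], ", ",
                    colnames(x$ct)[idx[, 2]], ")")
    if (drop_incomplete_genes) {
      keep <- setdiff(rownames(x$ct), unique(rownames(x$ct)[idx[, 1]]))
      if (!length(keep)) stop("all genes have missing/out-of-band Ct values")
      return(subset_ct(x, genes = keep))
    }
    stop("missing or out-of-band Ct value(s) at: ",
         paste(cells, collapse = ", "))
  }
  x
}

#' Read a Ct table from a wide or long delimited file
#'
#' Wide files carry genes in rows (first column = gene id) and samples in
#' columns; long files carry one measurement per row with columns
#' `gene`, `sample`, `ct` and an optional `replicate` column. Long rows that
#' duplicate a (gene, sample) cell are averaged only when a `replicate`
#' column marks them as technical replicates; otherwise duplication is an
#' error. Group labels are joined from a metadata table with columns
#' `sample` and `group`; an optional `efficiency` column in a gene metadata
#' sense is not supported here -- pass `efficiencies` directly.
#'
#' @param path delimited file (.tsv/.txt tab, .csv comma).
#' @param metadata_path sample metadata file with columns `sample`, `group`.
#' @param format `"wide"` (canonical) or `"long"`.
#' @param efficiencies per-gene efficiency passed to [ct_table()].
#' @param ct_band passed to [ct_table()].
#' @return A validated `ct_table`; row/column order follows input order.
#' @export
read_ct_table <- function(path, metadata_path, format = c("wide", "long"),
                          efficiencies = 2, ct_band = c(0, 45)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("Ct file not found: ", path)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  meta <- utils::read.table(metadata_path, header = TRUE,
                            sep = infer_sep(metadata_path),
                            colClasses = "character", check.names = FALSE)
  if (!all(c("sample", "group") %in% names(meta)))
    stop("metadata must have columns `sample` and `group`")
  groups <- stats::setNames(meta$group, meta$sample)

  if (format == "wide") {
    tab <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                             check.names = FALSE, colClasses = "character")
    gene_ids <- tab[[1]]
    if (anyDuplicated(gene_ids))
      stop("duplicate gene row(s) in wide file: ",
           paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    blank <- tab[, -1, drop = FALSE] == "" | is.na(m)
    if (any(blank)) {
      idx <- which(as.matrix(blank), arr.ind = TRUE)
      stop("empty or non-numeric Ct at: ",
           paste0("(", gene_ids[idx[, 1]], ", ",
                  colnames(m)[idx[, 2]], ")", collapse = ", "))
    }
    rownames(m) <- gene_ids
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                             check.names = FALSE)
    if (!all(c("gene", "sample", "ct") %in% names(tab)))
      stop("long format requires columns `gene`, `sample`, `ct`")
    if (!is.numeric(tab$ct)) stop("non-numeric Ct values in long file")
    key <- paste(tab$gene, tab$sample, sep = "\r")
    if (anyDuplicated(key) && !("replicate" %in% names(tab)))
      stop("duplicate (gene, sample) rows without a `replicate` column: ",
           paste(unique(paste0("(", tab$gene, ", ", tab$sample, ")")[duplicated(key)]),
                 collapse = ", "))
    m <- average_replicate_frame(tab)
  }
  ct_table(m, groups, efficiencies, ct_band)
}

# long triples -> genes x samples matrix of per-cell means, input order kept
average_replicate_frame <- function(tab) {
  genes <- unique(as.character(tab$gene))
  samples <- unique(as.character(tab$sample))
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  agg <- stats::aggregate(ct ~ gene + sample, data = tab, FUN = mean)
  m[cbind(as.character(agg$gene), as.character(agg$sample))] <- agg$ct
  m
}

#' Average technical replicates into a Ct table
#'
#' qPCR wells are run in technical duplicates (or more); the per-cell
#' arithmetic mean Ct is what enters the stability analysis.
#'
#' @param measurements data frame with columns `gene`, `sample`, `ct`, one
#'   row per well.
#' @param groups sample group labels (named by sample id).
#' @param ... passed to [ct_table()].
#' @return A `ct_table` whose cell values are replicate means.
#' @export
average_technical_replicates <- function(measurements, groups, ...) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(measurements)))
  ct_table(average_replicate_frame(measurements), groups, ...)
}

#' Write a Ct table to a wide delimited file
#'
#' Deterministic output: input gene/sample order, fixed 6-decimal formatting.
#'
#' @param x a `ct_table`.
#' @param path output path (.tsv/.csv).
#' @param metadata_path optional path for the matching sample metadata file.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, metadata_path = NULL) {
  sep <- infer_sep(path)
  out <- data.frame(gene = rownames(x$ct),
                    apply(x$ct, 2, fmt6),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    meta <- data.frame(sample = names(x$groups),
                       group = as.character(x$groups))
    utils::write.table(meta, metadata_path, sep = infer_sep(metadata_path),
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Construct an expression matrix (counts or TPM)
#'
#' Holds the small-RNA sequencing abundances that feed candidate
#' preselection: either raw read counts or transcripts-per-million (TPM).
#'
#' @param values nonnegative numeric matrix, genes x samples, with dimnames.
#' @param groups sample group labels as in [ct_table()].
#' @param unit `"count"` or `"tpm"`. A TPM matrix must have columns summing
#'   to 1e6 (relative tolerance 1e-6).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups, unit = c("count", "tpm")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("gene and sample ids must be unique")
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (any(values < 0)) stop("expression values must be nonnegative")
  samples <- colnames(values)
  if (!is.null(names(groups))) {
    missing_grp <- setdiff(samples, names(groups))
    if (length(missing_grp))
      stop("no group label for sample(s): ", paste(missing_grp, collapse = ", "))
    groups <- groups[samples]
  }
  groups <- stats::setNames(factor(as.character(groups)), samples)
  if (unit == "tpm") {
    cs <- colSums(values)
    if (any(abs(cs - 1e6) > 1e-6 * 1e6))
      stop("TPM columns must sum to 1e6; offending sample(s): ",
           paste(samples[abs(cs - 1e6) > 1], collapse = ", "))
  }
  structure(list(values = values, groups = groups, unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix [%s]: %d genes x %d samples, %d group(s)\n",
              x$unit, nrow(x$values), ncol(x$values), nlevels(x$groups)))
  invisible(x)
}

#' Read an expression matrix from a wide delimited file
#'
#' @inheritParams read_ct_table
#' @param unit `"count"` or `"tpm"`.
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, metadata_path,
                                   unit = c("count", "tpm")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  tab <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  meta <- utils::read.table(metadata_path, header = TRUE,
                            sep = infer_sep(metadata_path),
                            colClasses = "character", check.names = FALSE)
  expression_matrix(m, stats::setNames(meta$group, meta$sample), unit)
}

#' Write an expression matrix to a wide delimited file
#'
#' @param x an `expression_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  out <- data.frame(gene = rownames(x$values), apply(x$values, 2, fmt6),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = infer_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Normalize raw counts to transcripts per million
#'
#' TPM = (count / library total) x 1e6, per sample, so every column of the
#' result sums to one million and between-sample library-size differences
#' cancel.
#'
#' @param m an `expression_matrix` with `unit = "count"`.
#' @return An `expression_matrix` with `unit = "tpm"`.
#' @export
tpm_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != "count") stop("tpm_normalize() expects a count matrix")
  totals <- colSums(m$values)
  if (any(totals <= 0))
    stop("zero total counts in sample(s): ",
         paste(colnames(m$values)[totals <= 0], collapse = ", "))
  tpm <- sweep(m$values, 2, totals, "/") * 1e6
  expression_matrix(tpm, m$groups, "tpm")
}
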