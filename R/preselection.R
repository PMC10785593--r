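#' Coefficient of variation, in percent
#'
#' CV = (SD / mean) x 100, with the sample (n-1) standard deviation by
#' default. Used to screen sequencing abundances for genes whose expression
#' barely moves across the study.
#'
#' @param values numeric vector (>= 2 values).
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return CV as a percentage; `NA` (with a warning) when the mean is zero,
#'   so that such genes are flagged and excluded from ranking.
#' @export
coefficient_of_variation <- function(values, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  if (length(values) < 2) stop("CV requires at least two values")
  m <- mean(values)
  if (m == 0) {
    warning("CV undefined for zero-mean gene; returning NA")
    return(NA_real_)
  }
  100 * sd_denom(values, sd_denominator) / m
}

#' Abundance gate for candidate reference genes
#'
#' A gene passes when its mean expression across all samples strictly
#' exceeds the threshold: 8000 on the raw-count basis, 5000 on the TPM
#' basis by default.
#'
#' @param m an `expression_matrix`.
#' @param basis `"count"` or `"tpm"`; must match `m$unit`.
#' @param threshold override the basis default.
#' @return Character vector of passing gene ids (input order).
#' @export
abundance_filter <- function(m, basis = c("count", "tpm"), threshold = NULL) {
  basis <- match.arg(basis)
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != basis)
    stop("matrix unit `", m$unit, "` does not match basis `", basis, "`")
  threshold <- threshold %||% if (basis == "count") 8000 else 5000
  means <- rowMeans(m$values)
  rownames(m$values)[means > threshold]
}

# ascending-CV order among eligible genes; ties broken by higher mean
# abundance, then lexicographic gene id
cv_order <- function(cv, means, eligible) {
  g <- eligible[order(cv[eligible], -means[eligible], eligible)]
  g[!is.na(cv[g])]
}

#' Preselect candidate reference genes from a count matrix
#'
#' Emulates dual-basis screening of sequencing data: genes passing the
#' abundance gate are ranked by ascending CV separately on the raw-count
#' and the TPM basis; the top `k` of each basis are taken and their union
#' returned with provenance (a gene low-CV on both bases carries both
#' tags). TPM is computed internally from the counts.
#'
#' @param counts an `expression_matrix` with `unit = "count"`.
#' @param k genes to take per basis (default 5).
#' @param count_threshold,tpm_threshold abundance gates (strict `>`).
#' @param cv_scope `"samples"` pools all samples into one CV (default);
#'   `"group_means"` computes the CV of per-group mean expression.
#' @param sd_denominator SD convention for the CV, see
#'   [coefficient_of_variation()].
#' @return An object of class `candidate_selection`: a data frame with one
#'   row per gene (input order) and columns `gene`, `cv_count`, `cv_tpm`,
#'   `mean_count`, `mean_tpm`, `passed_abundance_count`,
#'   `passed_abundance_tpm`, `selected_by` (comma-joined subset of
#'   `count,tpm`, empty when not selected). The union of selected genes is
#'   in `attr(, "selected")`.
#' @export
select_candidates <- function(counts, k = 5, count_threshold = 8000,
                              tpm_threshold = 5000,
                              cv_scope = c("samples", "group_means"),
                              sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "count") stop("select_candidates() expects raw counts")
  cv_scope <- match.arg(cv_scope)
  sd_denominator <- match.arg(sd_denominator)
  tpm <- tpm_normalize(counts)
  genes <- rownames(counts$values)

  cv_basis <- function(values) {
    if (cv_scope == "group_means") {
      grp <- counts$groups
      values <- t(apply(values, 1, function(v) tapply(v, grp, mean)))
    }
    apply(values, 1, function(v) {
      if (mean(v) == 0) NA_real_
      else 100 * sd_denom(v, sd_denominator) / mean(v)
    })
  }
  cv_count <- cv_basis(counts$values)
  cv_tpm <- cv_basis(tpm$values)
  mean_count <- rowMeans(counts$values)
  mean_tpm <- rowMeans(tpm$values)

  pass_count <- genes[mean_count > count_threshold]
  pass_tpm <- genes[mean_tpm > tpm_threshold]
  ok_count <- pass_count[!is.na(cv_count[pass_count])]
  ok_tpm <- pass_tpm[!is.na(cv_tpm[pass_tpm])]
  if (length(ok_count) < k || length(ok_tpm) < k)
    stop(sprintf(paste0("fewer than k = %d eligible genes: %d passed the ",
                        "count gate, %d the TPM gate"),
                 k, length(ok_count), length(ok_tpm)))

  top_count <- cv_order(cv_count, mean_count, ok_count)[seq_len(k)]
  top_tpm <- cv_order(cv_tpm, mean_tpm, ok_tpm)[seq_len(k)]

  selected_by <- vapply(genes, function(g) {
    paste(c(if (g %in% top_count) "count", if (g %in% top_tpm) "tpm"),
          collapse = ",")
  }, character(1))

  out <- data.frame(gene = genes,
                    cv_count = cv_count, cv_tpm = cv_tpm,
                    mean_count = mean_count, mean_tpm = mean_tpm,
                    passed_abundance_count = genes %in% pass_count,
                    passed_abundance_tpm = genes %in% pass_tpm,
                    selected_by = selected_by,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "selected") <- genes[selected_by != ""]
  attr(out, "top_count") <- top_count
  attr(out, "top_tpm") <- top_tpm
  class(out) <- c("candidate_selection", "data.frame")
  out
}

#' @export
print.candidate_selection <- function(x, ...) {
  sel <- attr(x, "selected")
  cat(sprintf("Candidate selection: %d of %d genes (union of two bases)\n",
              length(sel), nrow(x)))
  cat("count-basis top:", paste(attr(x, "top_count"), collapse = ", "), "\n")
  cat("tpm-basis top:  ", paste(attr(x, "top_tpm"), collapse = ", "), "\n")
  invisible(x)
}

#' Write a candidate selection table
#'
#' @param x a `candidate_selection`.
#' @param path output TSV/CSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(x, path) {
  out <- x
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], fmt6)
  utils::write.table(out, path, sep = infer_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
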