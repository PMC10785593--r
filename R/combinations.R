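#' Build a multi-gene pseudo-reference
#'
#' Aggregates a set of reference genes into one per-sample normalizer Ct:
#' the geometric mean of the member Ct values (the arithmetic mean is
#' available as an option). A singleton returns the member's Ct
#' unchanged.
#'
#' @param ct a `ct_table`.
#' @param members nonempty character vector of member gene ids.
#' @param mean_type `"geometric"` (default) or `"arithmetic"`.
#' @return Named numeric vector of pseudo-Ct values, one per sample.
#' @export
make_pseudo_gene <- function(ct, members,
                             mean_type = c("geometric", "arithmetic")) {
  stopifnot(inherits(ct, "ct_table"))
  mean_type <- match.arg(mean_type)
  if (!length(members)) stop("`members` must be a nonempty gene set")
  missing_g <- setdiff(members, rownames(ct$ct))
  if (length(missing_g))
    stop("gene(s) not in the Ct table: ", paste(missing_g, collapse = ", "))
  y <- ct$ct[members, , drop = FALSE]
  if (mean_type == "geometric") apply(y, 2, geo_mean) else colMeans(y)
}

#' Evaluate reference-gene combinations as normalizers
#'
#' Enumerates every nonempty subset (up to `max_size` members) of the
#' selected reference genes, builds each subset's pseudo-reference
#' (per-sample geometric mean of Ct), then treats the pseudo-references as
#' genes: all four stability algorithms are run over them and the
#' combinations are ranked by the consensus geometric-mean-of-ranks. With
#' the default trio this is the 7-combination assessment (3 singles, 3
#' pairs, 1 triple). Overlapping membership makes pseudo-references
#' correlated by construction; no correction is applied, the comparison is
#' between combinations only.
#'
#' @param ct a `ct_table`.
#' @param genes the selected reference genes (typically the consensus top
#'   3).
#' @param max_size largest combination size (default 3).
#' @param mean_type pseudo-reference aggregation, see [make_pseudo_gene()].
#' @param ... passed to [rg_stability()].
#' @return An object of class `combination_result`: list with `members`
#'   (named list of gene sets), `pseudo_ct` (the pseudo-gene `ct_table`),
#'   `fit` (the `rg_stability` over combinations) and `ranking` (the
#'   consensus restricted to combinations).
#' @export
evaluate_combinations <- function(ct, genes, max_size = 3,
                                  mean_type = c("geometric", "arithmetic"),
                                  ...) {
  stopifnot(inherits(ct, "ct_table"))
  mean_type <- match.arg(mean_type)
  missing_g <- setdiff(genes, rownames(ct$ct))
  if (length(missing_g))
    stop("gene(s) not in the Ct table: ", paste(missing_g, collapse = ", "))
  sets <- list()
  for (size in seq_len(min(max_size, length(genes)))) {
    cmb <- utils::combn(genes, size, simplify = FALSE)
    names(cmb) <- vapply(cmb, paste, character(1), collapse = "+")
    sets <- c(sets, cmb)
  }
  if (length(sets) < 2)
    stop("need >= 2 combinations to rank; got ", length(sets))
  pseudo <- t(vapply(sets, function(m) make_pseudo_gene(ct, m, mean_type),
                     numeric(ncol(ct$ct))))
  rownames(pseudo) <- names(sets)
  pct <- ct_table(pseudo, ct$groups, efficiencies = 2, ct_band = ct$ct_band,
                  validate = FALSE)
  fit <- rg_stability(pct, ...)
  structure(list(members = sets, pseudo_ct = pct, fit = fit,
                 ranking = fit$consensus),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("Combination assessment: %d combinations of {%s}\n",
              length(x$members),
              paste(unique(unlist(x$members)), collapse = ", ")))
  print(x$ranking)
  invisible(x)
}

#' Write a combination assessment table
#'
#' @param x a `combination_result`.
#' @param path output TSV/CSV path.
#' @return `path`, invisibly.
#' @export
write_combinations <- function(x, path) {
  stopifnot(inherits(x, "combination_result"))
  tab <- x$ranking
  tab$n_members <- lengths(x$members)[tab$gene]
  num <- vapply(tab, is.numeric, logical(1))
  int <- vapply(tab, is.integer, logical(1))
  tab[num & !int] <- lapply(tab[num & !int], fmt6)
  names(tab)[names(tab) == "gene"] <- "combination"
  utils::write.table(tab, path, sep = infer_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
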