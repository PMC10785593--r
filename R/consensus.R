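#' Rank genes by a stability score
#'
#' Ascending-score ranks (1 = most stable); ties share the average rank.
#'
#' @param scores a `stability_scores` object or a named numeric vector.
#' @return Named numeric vector of ranks.
#' @export
rank_by_algorithm <- function(scores) {
  if (inherits(scores, "stability_scores")) return(scores$ranks)
  rank_ascending(scores)
}

#' Consensus ranking by the geometric mean of ranks
#'
#' Aggregates the per-algorithm rankings into a comprehensive ranking: per
#' gene the geometric mean of its ranks across algorithms, then the final
#' rank by ascending geometric mean. Ties on the geometric mean are broken
#' by the best single-algorithm rank, then lexicographic gene id.
#'
#' @param rankings named list of per-algorithm rank vectors (all over the
#'   same gene set, taken as ranks as supplied), or of `stability_scores`
#'   objects (their ranks are used).
#' @return An object of class `consensus_ranking`: a data frame with one
#'   row per gene, a `rank_<algorithm>` column per input, `geomean_rank`
#'   and integer `final_rank` (a permutation of 1..N).
#' @export
geometric_mean_ranking <- function(rankings) {
  stopifnot(is.list(rankings), length(rankings) >= 2)
  rankings <- lapply(rankings, function(r)
    if (inherits(r, "stability_scores")) r$ranks else r)
  if (is.null(names(rankings)))
    names(rankings) <- paste0("algorithm", seq_along(rankings))
  genes <- names(rankings[[1]])
  for (nm in names(rankings)) {
    diff <- c(setdiff(genes, names(rankings[[nm]])),
              setdiff(names(rankings[[nm]]), genes))
    if (length(diff))
      stop("gene sets differ across rankings; symmetric difference: ",
           paste(unique(diff), collapse = ", "))
  }
  rmat <- vapply(rankings, function(r) r[genes], numeric(length(genes)))
  geomean <- apply(rmat, 1, geo_mean)
  best <- apply(rmat, 1, min)
  ord <- order(geomean, best, genes, method = "radix")
  final <- integer(length(genes))
  final[ord] <- seq_along(genes)
  out <- data.frame(gene = genes, rmat, geomean_rank = geomean,
                    final_rank = final, row.names = NULL,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[1 + seq_along(rankings)] <- paste0("rank_", names(rankings))
  class(out) <- c("consensus_ranking", "data.frame")
  out
}

#' @export
print.consensus_ranking <- function(x, ...) {
  ord <- order(x$final_rank)
  y <- x[ord, , drop = FALSE]
  y$geomean_rank <- signif(y$geomean_rank, 4)
  cat("Consensus ranking (geometric mean of per-algorithm ranks):\n")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Optimal number of reference genes
#'
#' Reads the pairwise-variation series: the smallest n whose `V_{n,n+1}`
#' falls below the threshold is the number of reference genes needed for
#' adequate normalization. When no V is below the threshold, all N genes
#' are returned with a warning flag (`attr(, "warning_flag")`).
#'
#' @param v a `pairwise_variation` object.
#' @return Integer n, with attribute `warning_flag`.
#' @export
optimal_rg_count <- function(v) {
  stopifnot(inherits(v, "pairwise_variation"))
  structure(v$recommended_n, warning_flag = v$warning_flag)
}

#' Fit the reference-gene stability analysis
#'
#' The central fitting function: runs the requested stability algorithms on
#' a Ct table, aggregates their rankings into the consensus (geometric mean
#' of ranks) and, when geNorm is included, computes the pairwise-variation
#' series deciding how many reference genes to use.
#'
#' @param ct a `ct_table`.
#' @param algorithms subset of `c("genorm", "normfinder", "bestkeeper",
#'   "delta_ct")` (all four by default).
#' @param use_groups NormFinder grouping: use the metadata group labels
#'   (default when >= 2 groups each with >= 2 samples); `FALSE` selects the
#'   single-group variant.
#' @param bestkeeper_dispersion `"sd"` (default) or `"mad"`.
#' @param v_threshold pairwise-variation acceptance threshold (default
#'   0.15).
#' @param sd_denominator global SD convention, `"n-1"` (default) or `"n"`.
#' @return An object of class `rg_stability`: list with `scores` (named
#'   list of `stability_scores`), `consensus` (a `consensus_ranking`),
#'   `pairwise_variation`, `optimal_n`, `ct` and `call`. Methods:
#'   `print`, `summary`, `plot`.
#' @examples
#' cfg <- sim_config_pti(seed = 7)
#' fit <- rg_stability(simulate_ct_table(cfg))
#' fit
#' optimal_rg_count(fit$pairwise_variation)
#' @export
rg_stability <- function(ct,
                         algorithms = c("genorm", "normfinder",
                                        "bestkeeper", "delta_ct"),
                         use_groups = NULL,
                         bestkeeper_dispersion = c("sd", "mad"),
                         v_threshold = 0.15,
                         sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(ct, "ct_table"))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  bestkeeper_dispersion <- match.arg(bestkeeper_dispersion)
  sd_denominator <- match.arg(sd_denominator)
  sizes <- table(droplevels(ct$groups))
  use_groups <- use_groups %||% (length(sizes) >= 2 && all(sizes >= 2))

  scores <- list()
  if ("genorm" %in% algorithms)
    scores$genorm <- genorm_rank(ct, sd_denominator)
  if ("normfinder" %in% algorithms)
    scores$normfinder <- normfinder_stability(ct, use_groups = use_groups)
  if ("bestkeeper" %in% algorithms)
    scores$bestkeeper <- bestkeeper_stats(ct, bestkeeper_dispersion,
                                          sd_denominator)
  if ("delta_ct" %in% algorithms)
    scores$delta_ct <- delta_ct_stability(ct, sd_denominator)

  consensus <- if (length(scores) >= 2) geometric_mean_ranking(scores)
               else NULL
  pv <- NULL
  if ("genorm" %in% algorithms && nrow(ct$ct) >= 3)
    pv <- genorm_pairwise_variation(ct, v_threshold,
                                    ranking = scores$genorm$details$ranking,
                                    sd_denominator = sd_denominator)
  structure(list(scores = scores, consensus = consensus,
                 pairwise_variation = pv,
                 optimal_n = if (!is.null(pv)) optimal_rg_count(pv) else NULL,
                 ct = ct, use_groups = use_groups,
                 call = match.call()),
            class = "rg_stability")
}

#' @export
print.rg_stability <- function(x, ...) {
  cat("Reference-gene stability analysis\n")
  cat(sprintf("  %d genes, %d samples, %d group(s); algorithms: %s\n",
              nrow(x$ct$ct), ncol(x$ct$ct), nlevels(x$ct$groups),
              paste(names(x$scores), collapse = ", ")))
  if (!is.null(x$consensus)) {
    top <- x$consensus$gene[order(x$consensus$final_rank)]
    cat("  consensus (most to least stable):",
        paste(utils::head(top, 5), collapse = ", "),
        if (length(top) > 5) "..." else "", "\n")
  }
  if (!is.null(x$optimal_n))
    cat(sprintf("  recommended number of reference genes: %d%s\n",
                as.integer(x$optimal_n),
                if (isTRUE(attr(x$optimal_n, "warning_flag")))
                  " (no V below threshold)" else ""))
  invisible(x)
}

#' @export
summary.rg_stability <- function(object, ...) {
  cat("Per-algorithm scores (lower = more stable):\n")
  tab <- data.frame(gene = names(object$scores[[1]]$scores))
  for (nm in names(object$scores)) {
    tab[[paste0(nm, "_score")]] <- signif(object$scores[[nm]]$scores[tab$gene], 4)
    tab[[paste0(nm, "_rank")]] <- object$scores[[nm]]$ranks[tab$gene]
  }
  print.data.frame(tab, row.names = FALSE)
  if (!is.null(object$consensus)) print(object$consensus)
  if (!is.null(object$pairwise_variation)) print(object$pairwise_variation)
  invisible(object)
}

#' @export
plot.rg_stability <- function(x, ...) {
  n_panel <- length(x$scores) + as.integer(!is.null(x$pairwise_variation))
  old <- graphics::par(mfrow = c(ceiling(n_panel / 2), 2),
                       mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(x$scores)) {
    s <- sort(x$scores[[nm]]$scores)
    graphics::barplot(s, las = 2, main = nm, ylab = "stability score",
                      cex.names = 0.7)
  }
  if (!is.null(x$pairwise_variation)) {
    v <- x$pairwise_variation$v
    graphics::barplot(v, names.arg = paste0("V", names(v), "/",
                                            as.integer(names(v)) + 1),
                      main = "pairwise variation", ylab = "V", las = 2)
    graphics::abline(h = x$pairwise_variation$threshold, lty = 2)
  }
  invisible(x)
}

#' Write the per-algorithm scores and consensus of a fit
#'
#' Emits one wide TSV with per-algorithm scores and ranks plus the
#' consensus columns, and (optionally) the geNorm detail files.
#'
#' @param x an `rg_stability` fit.
#' @param path output TSV path.
#' @param genorm_trace_path,v_series_path optional detail paths (geNorm
#'   exclusion trace; V series).
#' @return `path`, invisibly.
#' @export
write_stability <- function(x, path, genorm_trace_path = NULL,
                            v_series_path = NULL) {
  stopifnot(inherits(x, "rg_stability"))
  tab <- data.frame(gene = names(x$scores[[1]]$scores),
                    stringsAsFactors = FALSE)
  for (nm in names(x$scores)) {
    tab[[paste0(nm, "_score")]] <- fmt6(x$scores[[nm]]$scores[tab$gene])
    tab[[paste0(nm, "_rank")]] <- x$scores[[nm]]$ranks[tab$gene]
  }
  if (!is.null(x$consensus)) {
    idx <- match(tab$gene, x$consensus$gene)
    tab$geomean_rank <- fmt6(x$consensus$geomean_rank[idx])
    tab$final_rank <- x$consensus$final_rank[idx]
  }
  utils::write.table(tab, path, sep = infer_sep(path), quote = FALSE,
                     row.names = FALSE)
  if (!is.null(genorm_trace_path) && !is.null(x$scores$genorm)) {
    d <- x$scores$genorm$details
    trace <- data.frame(step = seq_along(d$exclusion_order),
                        excluded = d$exclusion_order,
                        m_at_exclusion = fmt6(d$m_trace))
    utils::write.table(trace, genorm_trace_path,
                       sep = infer_sep(genorm_trace_path),
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(v_series_path) && !is.null(x$pairwise_variation)) {
    pv <- x$pairwise_variation
    vt <- data.frame(n = as.integer(names(pv$v)), v = fmt6(pv$v),
                     threshold = pv$threshold)
    utils::write.table(vt, v_series_path, sep = infer_sep(v_series_path),
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
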