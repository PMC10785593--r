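#' Stability score container
#'
#' Each stability algorithm returns its per-gene score (lower = more
#' stable), the within-algorithm average ranks and algorithm-specific
#' details.
#'
#' @param algorithm one of `"genorm"`, `"normfinder"`, `"bestkeeper"`,
#'   `"delta_ct"`.
#' @param scores named nonnegative numeric vector, gene -> score.
#' @param details list of algorithm-specific extras.
#' @param ranks optional precomputed ranks (geNorm's tied top pair);
#'   defaults to ascending average ranks of `scores`.
#' @return An object of class `stability_scores`.
#' @export
stability_scores <- function(algorithm, scores, details = list(),
                             ranks = NULL) {
  structure(list(algorithm = algorithm, scores = scores,
                 ranks = ranks %||% rank_ascending(scores),
                 details = details),
            class = "stability_scores")
}

#' @export
print.stability_scores <- function(x, ...) {
  ord <- order(x$ranks, names(x$scores), method = "radix")
  cat(sprintf("%s stability (lower = more stable):\n", x$algorithm))
  print(data.frame(gene = names(x$scores)[ord],
                   score = signif(x$scores[ord], 4),
                   rank = x$ranks[ord], row.names = NULL))
  invisible(x)
}

#' Relative quantities from Ct values
#'
#' Converts Ct to the expression scale used by geNorm:
#' `Q_ij = E_i^(min_j Ct_ij - Ct_ij)`, so each gene's best-expressed sample
#' has Q = 1 and every extra cycle divides Q by the efficiency E.
#'
#' @param ct a `ct_table`.
#' @return Numeric matrix of Q in (0, 1], genes x samples.
#' @export
relative_quantities <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  d <- apply(ct$ct, 1, min) - ct$ct        # min Ct - Ct, per gene
  ct$efficiencies ^ d
}

# log2 Q; pairwise SD of log-ratios is computed on this scale
log2_quantities <- function(ct) {
  (apply(ct$ct, 1, min) - ct$ct) * log2(ct$efficiencies)
}

# SD of per-sample differences logq[j,] - logq[k,] for all gene pairs
pairwise_logratio_sd <- function(logq, sd_denominator = "n-1") {
  n <- nrow(logq)
  v <- matrix(0, n, n, dimnames = list(rownames(logq), rownames(logq)))
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      s <- sd_denom(logq[j, ] - logq[k, ], sd_denominator)
      v[j, k] <- v[k, j] <- s
    }
  }
  v
}

#' geNorm M values
#'
#' For every gene pair (j, k) the pairwise variation `V_jk` is the sample
#' SD of the per-sample log2 expression ratio `log2(Q_j/Q_k)`; a gene's
#' stability measure M is the mean of its `V_jk` over all other genes.
#' Genes that track each other across samples (whatever their absolute
#' level) have small M.
#'
#' @param ct a `ct_table`.
#' @param genes optional gene subset (>= 2 genes).
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return Named numeric vector of M values.
#' @export
genorm_m_values <- function(ct, genes = NULL, sd_denominator = "n-1") {
  stopifnot(inherits(ct, "ct_table"))
  logq <- log2_quantities(ct)
  if (!is.null(genes)) logq <- logq[genes, , drop = FALSE]
  if (nrow(logq) < 2) stop("geNorm M needs at least 2 genes")
  v <- pairwise_logratio_sd(logq, sd_denominator)
  m <- rowSums(v) / (nrow(v) - 1)
  names(m) <- rownames(logq)
  m
}

#' geNorm stepwise ranking
#'
#' Iteratively removes the gene with the highest M and recomputes, until
#' two genes remain; that final pair is the most stable combination and is
#' reported with a tied rank (1.5 each). Each gene's score is its M at the
#' step of its exclusion; the final pair carries its pairwise M. Ties on
#' the maximal M are resolved by excluding the lexicographically last gene
#' id (deterministic).
#'
#' @inheritParams genorm_m_values
#' @return A `stability_scores` whose details carry `exclusion_order`
#'   (first excluded first), `m_trace` (M at exclusion), `full_m` (M on the
#'   complete set), `final_pair` and `ranking` (best to worst; the pair
#'   first, in lexicographic order).
#' @export
genorm_rank <- function(ct, sd_denominator = "n-1") {
  stopifnot(inherits(ct, "ct_table"))
  genes <- rownames(ct$ct)
  if (length(genes) < 3)
    stop("geNorm stepwise ranking needs >= 3 genes; ",
         "use genorm_m_values() for a pair")
  full_m <- genorm_m_values(ct, sd_denominator = sd_denominator)
  remaining <- genes
  exclusion <- character(0)
  m_trace <- numeric(0)
  while (length(remaining) > 2) {
    m <- genorm_m_values(ct, remaining, sd_denominator)
    worst_set <- names(m)[m >= max(m) - 1e-12]
    worst <- worst_set[order(worst_set, method = "radix")][length(worst_set)]
    exclusion <- c(exclusion, worst)
    m_trace <- c(m_trace, stats::setNames(m[[worst]], worst))
    remaining <- setdiff(remaining, worst)
  }
  pair <- remaining[order(remaining, method = "radix")]
  pair_m <- genorm_m_values(ct, pair, sd_denominator)

  scores <- c(stats::setNames(rep(pair_m[[1]], 2), pair), rev(m_trace))
  scores <- scores[genes]                     # input gene order
  ranks <- stats::setNames(numeric(length(genes)), genes)
  ranks[pair] <- 1.5
  ranks[rev(exclusion)] <- seq(3, length.out = length(exclusion))
  stability_scores("genorm", scores,
                   details = list(exclusion_order = exclusion,
                                  m_trace = m_trace,
                                  full_m = full_m,
                                  final_pair = pair,
                                  ranking = c(pair, rev(exclusion))),
                   ranks = ranks)
}

#' Pairwise variation series
#'
#' @param v named numeric vector `V_{n,n+1}` for n = 2..N-1 (names = n).
#' @param threshold acceptance threshold for V (default 0.15).
#' @return An object of class `pairwise_variation` with elements `v`,
#'   `threshold`, `recommended_n` (smallest n with V below threshold, or N
#'   with `warning_flag = TRUE` when none is).
#' @export
pairwise_variation <- function(v, threshold = 0.15) {
  below <- which(v < threshold)
  n_total <- as.integer(names(v)[length(v)]) + 1L
  if (length(below)) {
    rec <- as.integer(names(v)[below[1]])
    warn <- FALSE
  } else {
    rec <- n_total
    warn <- TRUE
  }
  structure(list(v = v, threshold = threshold, recommended_n = rec,
                 warning_flag = warn),
            class = "pairwise_variation")
}

#' @export
print.pairwise_variation <- function(x, ...) {
  cat("Pairwise variation V(n, n+1):\n")
  print(signif(x$v, 4))
  cat(sprintf("recommended number of reference genes: %d%s\n",
              x$recommended_n,
              if (x$warning_flag)
                sprintf(" (no V below %.3g; using all genes)", x$threshold)
              else ""))
  invisible(x)
}

#' geNorm pairwise variation V(n, n+1)
#'
#' Builds normalization factors `NF_n` (per-sample geometric mean of the
#' relative quantities Q of the n most stable genes, in geNorm order) and
#' measures how much adding the (n+1)-th gene changes them:
#' `V_{n,n+1} = SD over samples of log2(NF_n / NF_{n+1})`. The smallest n
#' with V below the threshold is the recommended number of reference
#' genes.
#'
#' @inheritParams genorm_m_values
#' @param threshold V acceptance threshold (default 0.15).
#' @param ranking optional gene ordering (best first); defaults to the
#'   [genorm_rank()] ordering.
#' @return A `pairwise_variation` object.
#' @export
genorm_pairwise_variation <- function(ct, threshold = 0.15, ranking = NULL,
                                      sd_denominator = "n-1") {
  stopifnot(inherits(ct, "ct_table"))
  if (nrow(ct$ct) < 3) stop("pairwise variation needs >= 3 genes")
  ranking <- ranking %||% genorm_rank(ct, sd_denominator)$details$ranking
  q <- relative_quantities(ct)[ranking, , drop = FALSE]
  logq <- log2(q)
  n_max <- nrow(q) - 1
  v <- stats::setNames(numeric(n_max - 1), 2:n_max)
  for (n in 2:n_max) {
    log_nf_n <- colMeans(logq[seq_len(n), , drop = FALSE])
    log_nf_n1 <- colMeans(logq[seq_len(n + 1), , drop = FALSE])
    v[as.character(n)] <- sd_denom(log_nf_n - log_nf_n1, sd_denominator)
  }
  pairwise_variation(v, threshold)
}

#' NormFinder model-based stability
#'
#' Implements the model-based variance-decomposition estimator of Andersen
#' and colleagues on Ct values (Ct is already a log2 scale, so no further
#' transform is applied). Per sample the across-gene mean is subtracted,
#' removing sample-specific scaling; gene-specific within-group variances
#' are then estimated from two-way residuals with a small-sample bias
#' correction, and between-group deviations are shrunken toward zero in
#' proportion to their sampling noise. The stability value of a gene is
#' the average over groups of (|shrunken intergroup deviation| + the
#' corresponding intragroup-variation term); lower = more stable.
#'
#' All estimator constants sit in this function: with I genes, G groups and
#' group sizes n_g, writing z for sample-centered Ct, r for the two-way
#' within-group residuals and `u_ig = RSS_ig / (n_g - 1)`:
#' `sigma2_ig = max(0, I/(I-2) * (u_ig - sum_k u_kg / (I (I-1))))`;
#' `d_ig = mean_z_ig - mean_g(mean_z_ig)` (per gene, across groups);
#' `gamma2 = max(0, sum(d^2) / ((I-1)(G-1)) - mean_g(avg_i sigma2_ig / n_g))`;
#' `d~_ig = d_ig * gamma2 / (gamma2 + sigma2_ig / n_g)`;
#' `stab_ig = |d~_ig| + sqrt((sigma2_ig / n_g) * gamma2 / (gamma2 + sigma2_ig / n_g))`.
#' Without groups the measure reduces to `sqrt(sigma2_i)` of the
#' sample-centered values.
#'
#' @param ct a `ct_table` (>= 3 genes).
#' @param use_groups use the metadata group labels (default); `FALSE` gives
#'   the single-group variant.
#' @return A `stability_scores` whose details carry the intragroup variance
#'   matrix, the raw and shrunken intergroup deviations and `gamma2`.
#' @export
normfinder_stability <- function(ct, use_groups = TRUE) {
  stopifnot(inherits(ct, "ct_table"))
  y <- ct$ct
  I <- nrow(y)
  if (I < 3) stop("NormFinder needs >= 3 genes")
  z <- sweep(y, 2, colMeans(y))                   # remove sample effects
  groups <- if (use_groups) droplevels(ct$groups) else
    factor(rep("all", ncol(y)))
  sizes <- table(groups)
  if (use_groups) {
    if (nlevels(groups) < 2)
      stop("use_groups = TRUE needs >= 2 groups")
    if (any(sizes < 2))
      stop("group(s) with a single sample: ",
           paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  G <- nlevels(groups)

  sigma2 <- matrix(0, I, G, dimnames = list(rownames(y), levels(groups)))
  zbar <- sigma2
  for (g in levels(groups)) {
    zg <- z[, groups == g, drop = FALSE]
    ng <- ncol(zg)
    zbar[, g] <- rowMeans(zg)
    r <- zg - rowMeans(zg)                        # col means are 0 already
    u <- rowSums(r^2) / (ng - 1)
    sigma2[, g] <- pmax(0, I / (I - 2) * (u - sum(u) / (I * (I - 1))))
  }

  if (!use_groups) {
    scores <- sqrt(sigma2[, 1])
    return(stability_scores("normfinder", scores,
                            details = list(intragroup = sigma2,
                                           use_groups = FALSE)))
  }

  d <- zbar - rowMeans(zbar)
  n_g <- as.numeric(sizes[colnames(sigma2)])
  gamma2 <- max(0, sum(d^2) / ((I - 1) * (G - 1)) -
                  mean(colMeans(sigma2) / n_g))
  noise <- sweep(sigma2, 2, n_g, "/")             # sigma2_ig / n_g
  shrink <- gamma2 / (gamma2 + noise)
  shrink[!is.finite(shrink)] <- 0                 # gamma2 = 0, noise = 0
  d_shrunk <- d * shrink
  stab <- abs(d_shrunk) + sqrt(noise * shrink)
  scores <- rowMeans(stab)
  stability_scores("normfinder", scores,
                   details = list(intragroup = sigma2, intergroup = d,
                                  intergroup_shrunk = d_shrunk,
                                  gamma2 = gamma2, group_sizes = n_g,
                                  use_groups = TRUE))
}

#' BestKeeper descriptive stability
#'
#' Ranks genes by the dispersion of their raw Ct values across samples:
#' the sample SD by default, or the mean absolute deviation about the mean
#' (the dispersion the original BestKeeper spreadsheet reports) with
#' `dispersion = "mad"`. Details carry per-gene descriptive statistics and,
#' with >= 3 samples, each gene's Pearson correlation against the
#' BestKeeper index.
#'
#' @param ct a `ct_table` (>= 2 samples).
#' @param dispersion `"sd"` (default) or `"mad"`.
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return A `stability_scores`.
#' @export
bestkeeper_stats <- function(ct, dispersion = c("sd", "mad"),
                             sd_denominator = "n-1") {
  stopifnot(inherits(ct, "ct_table"))
  dispersion <- match.arg(dispersion)
  y <- ct$ct
  if (ncol(y) < 2) stop("BestKeeper needs >= 2 samples")
  disp <- apply(y, 1, function(v)
    if (dispersion == "sd") sd_denom(v, sd_denominator) else mean_abs_dev(v))
  desc <- data.frame(gene = rownames(y),
                     n = ncol(y),
                     min = apply(y, 1, min),
                     max = apply(y, 1, max),
                     mean = rowMeans(y),
                     geo_mean = apply(y, 1, geo_mean),
                     sd = apply(y, 1, sd_denom, sd_denominator),
                     mad = apply(y, 1, mean_abs_dev),
                     row.names = NULL, stringsAsFactors = FALSE)
  details <- list(descriptives = desc, dispersion = dispersion)
  if (ncol(y) >= 3)
    details$index_correlations <- bestkeeper_index_correlations(ct)
  stability_scores("bestkeeper", disp, details = details)
}

#' BestKeeper index correlations
#'
#' The BestKeeper index is the per-sample geometric mean of the Ct values
#' of all candidate genes; each gene's Pearson correlation (and two-sided
#' p value) against that index measures how well it follows the common
#' signal. Reported as details only -- the ranking criterion is the
#' dispersion.
#'
#' @param ct a `ct_table` (>= 3 samples).
#' @return Data frame with columns `gene`, `r`, `p`, `flagged` (`TRUE` for
#'   zero-variance genes, whose correlation is undefined and returned as
#'   `NA`).
#' @export
bestkeeper_index_correlations <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  y <- ct$ct
  if (ncol(y) < 3) stop("index correlations need >= 3 samples")
  index <- apply(y, 2, geo_mean)
  res <- lapply(rownames(y), function(g) {
    v <- y[g, ]
    if (stats::sd(v) == 0 || stats::sd(index) == 0)
      return(data.frame(gene = g, r = NA_real_, p = NA_real_, flagged = TRUE))
    ctest <- stats::cor.test(v, index, method = "pearson")
    data.frame(gene = g, r = unname(ctest$estimate), p = ctest$p.value,
               flagged = FALSE)
  })
  do.call(rbind, res)
}

#' Comparative Delta Ct stability
#'
#' For every gene pair the per-sample Ct difference is computed; a stable
#' pair keeps a repeatable difference, so the SD of the differences across
#' samples is small. A gene's score is the mean of these pairwise SDs over
#' all pairs containing it.
#'
#' @param ct a `ct_table` (>= 2 genes).
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return A `stability_scores` whose details carry the full pairwise SD
#'   matrix.
#' @export
delta_ct_stability <- function(ct, sd_denominator = "n-1") {
  stopifnot(inherits(ct, "ct_table"))
  y <- ct$ct
  if (nrow(y) < 2) stop("comparative Delta Ct needs >= 2 genes")
  v <- pairwise_logratio_sd(y, sd_denominator)   # SD of Ct_a - Ct_b
  scores <- rowSums(v) / (nrow(v) - 1)
  names(scores) <- rownames(y)
  stability_scores("delta_ct", scores, details = list(pair_sd = v))
}
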