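# Naive, loop-based reference implementations of every algorithm, coded
# directly from their definitions and kept independent of the package's
# vectorized code paths. Used to freeze expected values and for the
# equivalence property on small random tables.

oracle_sd <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

oracle_relative_quantities <- function(ct_mat, eff) {
  q <- ct_mat
  for (i in seq_len(nrow(ct_mat))) {
    for (j in seq_len(ncol(ct_mat))) {
      q[i, j] <- eff[i]^(min(ct_mat[i, ]) - ct_mat[i, j])
    }
  }
  q
}

oracle_genorm_m <- function(ct_mat, eff = rep(2, nrow(ct_mat))) {
  q <- oracle_relative_quantities(ct_mat, eff)
  genes <- rownames(ct_mat)
  m <- numeric(length(genes))
  names(m) <- genes
  for (j in seq_along(genes)) {
    vs <- c()
    for (k in seq_along(genes)) {
      if (k == j) next
      a <- log2(q[j, ] / q[k, ])
      vs <- c(vs, oracle_sd(a))
    }
    m[j] <- mean(vs)
  }
  m
}

# stepwise exclusion; ties on max M resolved by lexicographically last id
oracle_genorm_exclusion <- function(ct_mat, eff = rep(2, nrow(ct_mat))) {
  names(eff) <- rownames(ct_mat)
  remaining <- rownames(ct_mat)
  excluded <- character(0)
  while (length(remaining) > 2) {
    m <- oracle_genorm_m(ct_mat[remaining, , drop = FALSE], eff[remaining])
    worst <- names(m)[m >= max(m) - 1e-12]
    worst <- sort(worst, method = "radix")[length(worst)]
    excluded <- c(excluded, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(excluded = excluded, pair = sort(remaining, method = "radix"))
}

oracle_pairwise_variation <- function(ct_mat, ranking,
                                      eff = rep(2, nrow(ct_mat))) {
  names(eff) <- rownames(ct_mat)
  q <- oracle_relative_quantities(ct_mat[ranking, , drop = FALSE],
                                  eff[ranking])
  v <- c()
  for (n in 2:(nrow(q) - 1)) {
    nf_n <- apply(q[1:n, , drop = FALSE], 2,
                  function(x) prod(x)^(1 / length(x)))
    nf_n1 <- apply(q[1:(n + 1), , drop = FALSE], 2,
                   function(x) prod(x)^(1 / length(x)))
    v <- c(v, oracle_sd(log2(nf_n / nf_n1)))
  }
  names(v) <- 2:(nrow(q) - 1)
  v
}

oracle_delta_ct <- function(ct_mat) {
  genes <- rownames(ct_mat)
  scores <- numeric(length(genes))
  names(scores) <- genes
  for (a in seq_along(genes)) {
    sds <- c()
    for (b in seq_along(genes)) {
      if (b == a) next
      sds <- c(sds, oracle_sd(ct_mat[a, ] - ct_mat[b, ]))
    }
    scores[a] <- mean(sds)
  }
  scores
}

oracle_bestkeeper_sd <- function(ct_mat) {
  apply(ct_mat, 1, oracle_sd)
}

oracle_bestkeeper_r <- function(ct_mat) {
  index <- apply(ct_mat, 2, function(x) prod(x)^(1 / length(x)))
  apply(ct_mat, 1, function(v) stats::cor(v, index))
}

# direct transcription of the model-based estimator, scalar loops only
oracle_normfinder <- function(ct_mat, groups) {
  groups <- factor(groups)
  I <- nrow(ct_mat)
  G <- nlevels(groups)
  z <- ct_mat
  for (j in seq_len(ncol(ct_mat))) z[, j] <- ct_mat[, j] - mean(ct_mat[, j])
  sigma2 <- matrix(0, I, G)
  zbar <- matrix(0, I, G)
  n_g <- numeric(G)
  for (g in seq_len(G)) {
    zg <- z[, groups == levels(groups)[g], drop = FALSE]
    n_g[g] <- ncol(zg)
    u <- numeric(I)
    for (i in seq_len(I)) {
      zbar[i, g] <- mean(zg[i, ])
      u[i] <- sum((zg[i, ] - mean(zg[i, ]))^2) / (n_g[g] - 1)
    }
    for (i in seq_len(I)) {
      sigma2[i, g] <- max(0, I / (I - 2) * (u[i] - sum(u) / (I * (I - 1))))
    }
  }
  d <- zbar - rowMeans(zbar)
  gamma2 <- max(0, sum(d^2) / ((I - 1) * (G - 1)) -
                  mean(colMeans(sigma2) / n_g))
  stab <- matrix(0, I, G)
  for (i in seq_len(I)) {
    for (g in seq_len(G)) {
      noise <- sigma2[i, g] / n_g[g]
      w <- if (gamma2 + noise == 0) 0 else gamma2 / (gamma2 + noise)
      stab[i, g] <- abs(d[i, g] * w) + sqrt(noise * w)
    }
  }
  stats::setNames(rowMeans(stab), rownames(ct_mat))
}

oracle_geomean_rank <- function(...) {
  ranks <- cbind(...)
  apply(ranks, 1, function(r) prod(r)^(1 / length(r)))
}
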