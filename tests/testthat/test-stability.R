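pair_ct <- function() {
  m <- rbind(A = c(10, 11), B = c(12, 14))
  colnames(m) <- c("s1", "s2")
  ct_table(m, c(s1 = "a", s2 = "a"))
}

test_that("relative quantities follow the efficiency transform", {
  m <- rbind(g1 = c(10, 11), g2 = c(20, 20), g3 = c(10, 20))
  colnames(m) <- c("s1", "s2")
  ct <- ct_table(m, c(s1 = "a", s2 = "a"))
  q <- relative_quantities(ct)
  expect_equal(unname(q["g1", ]), c(1, 0.5))
  expect_equal(unname(q["g2", ]), c(1, 1))     # constant gene -> all 1
  expect_equal(q["g3", "s1"] / q["g3", "s2"], 1024)  # 10 cycles, E = 2
  expect_true(all(q > 0 & q <= 1))
  # per gene the best-expressed sample has Q = 1
  expect_equal(unname(apply(q, 1, max)), c(1, 1, 1))
})

test_that("pair M value matches the hand-computed log-ratio SD", {
  m <- genorm_m_values(pair_ct())
  expect_equal(unname(m), rep(sqrt(0.5), 2), tolerance = 1e-9)
  # two genes identical up to a constant shift are perfectly co-regulated
  m2 <- rbind(A = c(10, 12, 11), B = c(13, 15, 14))
  colnames(m2) <- paste0("s", 1:3)
  expect_equal(unname(genorm_m_values(ct_table(m2, rep("a", 3)))), c(0, 0))
})

test_that("geNorm stepwise ranking excludes the noisy gene first and ties
           the final pair", {
  ct <- toy3x6()
  res <- genorm_rank(ct)
  expect_equal(res$details$exclusion_order, "g3")
  expect_setequal(res$details$final_pair, c("g1", "g2"))
  expect_equal(unname(res$ranks[c("g1", "g2", "g3")]), c(1.5, 1.5, 3))
  # scores: pair carries its pairwise M, excluded gene its M at exclusion
  expect_equal(unname(res$scores["g1"]), unname(res$scores["g2"]))
  expect_equal(unname(res$scores["g1"]),
               unname(genorm_m_values(ct, c("g1", "g2"))[1]))
  expect_equal(unname(res$scores["g3"]),
               unname(genorm_m_values(ct)["g3"]))
  expect_error(genorm_rank(pair_ct()), "genorm_m_values")
})

test_that("degenerate all-identical profiles give M = 0 and the documented
           tie-break", {
  m <- matrix(rep(c(20, 21, 19, 22), each = 4), 4, 4, byrow = FALSE)
  m <- t(m); dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:4))
  ct <- ct_table(m, rep("a", 4))
  res <- genorm_rank(ct)
  expect_equal(unname(res$scores), rep(0, 4))
  # lexicographically last ids are excluded first
  expect_equal(res$details$exclusion_order, c("g4", "g3"))
})

test_that("pairwise variation matches a direct NF-ratio oracle and flags
           co-regulated panels", {
  set.seed(31)
  ct <- random_ct(4, 6, seed = 31)
  pv <- genorm_pairwise_variation(ct)
  ranking <- genorm_rank(ct)$details$ranking
  expect_equal(pv$v, oracle_pairwise_variation(ct$ct, ranking),
               tolerance = 1e-9)
  # perfectly co-regulated genes: all V = 0, two genes suffice
  s <- c(0, 1, -1, 2, 0.5, -0.5)
  m <- rbind(g1 = 20 + s, g2 = 22 + s, g3 = 24 + s, g4 = 18 + s)
  colnames(m) <- paste0("s", 1:6)
  pv0 <- genorm_pairwise_variation(ct_table(m, rep("a", 6)))
  expect_equal(unname(pv0$v), rep(0, 2))
  expect_equal(pv0$recommended_n, 2L)
})

test_that("NormFinder zero identity: pure sample effects give stability 0", {
  s <- c(0, 1, -1, 2, 0.5, -0.5, 1.5, -1.5)
  m <- rbind(g1 = 20 + s, g2 = 22 + s, g3 = 24 + s, g4 = 18 + s)
  colnames(m) <- paste0("s", 1:8)
  ct <- ct_table(m, rep(c("a", "b"), each = 4))
  nf <- normfinder_stability(ct)
  expect_equal(unname(nf$scores), rep(0, 4))
  nf1 <- normfinder_stability(ct, use_groups = FALSE)
  expect_equal(unname(nf1$scores), rep(0, 4))
})

test_that("NormFinder stability grows with injected group shift and with
           within-group noise", {
  mean_stab <- function(delta, sigma, reps = 40) {
    vals <- vapply(seq_len(reps), function(r) {
      cfg <- sim_config(paste0("g", 1:6),
                        c(a = 6L, b = 6L),
                        gene_mean_ct = 20,
                        sample_effect_sd = 0.4,
                        group_effect = rbind(
                          g1 = c(a = 0, b = delta),
                          g2 = c(a = 0, b = 0), g3 = c(a = 0, b = 0),
                          g4 = c(a = 0, b = 0), g5 = c(a = 0, b = 0),
                          g6 = c(a = 0, b = 0)),
                        noise_sd = c(g1 = sigma, g2 = 0.3, g3 = 0.3,
                                     g4 = 0.3, g5 = 0.3, g6 = 0.3),
                        seed = 1000 + r)
      normfinder_stability(simulate_ct_table(cfg))$scores[["g1"]]
    }, numeric(1))
    mean(vals)
  }
  base <- mean_stab(0, 0.3)
  expect_gt(mean_stab(1.5, 0.3), base)
  expect_gt(mean_stab(0, 1.2), base)
  # large-sample limit: with noise shrunk away, the ranking recovers the
  # generative order (shifted gene last)
  cfg <- sim_config(paste0("g", 1:6), c(a = 60L, b = 60L),
                    gene_mean_ct = 20, sample_effect_sd = 0.4,
                    group_effect = rbind(g1 = c(a = 0, b = 2), g2 = 0,
                                         g3 = 0, g4 = 0, g5 = 0, g6 = 0),
                    noise_sd = 0.3, seed = 123)
  nf <- normfinder_stability(simulate_ct_table(cfg))
  expect_equal(names(which.max(nf$ranks)), "g1")
})

test_that("NormFinder preconditions", {
  ct <- random_ct(2, 6, seed = 5)
  expect_error(normfinder_stability(ct), ">= 3 genes")
  m <- rbind(g1 = 1:4 + 20, g2 = c(21, 22, 20, 23), g3 = c(25, 24, 26, 23))
  colnames(m) <- paste0("s", 1:4)
  ct2 <- ct_table(m, c("a", "a", "a", "b"))
  expect_error(normfinder_stability(ct2), "single sample")
})

test_that("BestKeeper dispersion, descriptives and index correlations", {
  m <- rbind(flat = c(20, 20, 20), g2 = c(19, 21, 20), g3 = c(25, 23, 27))
  colnames(m) <- paste0("s", 1:3)
  ct <- ct_table(m, rep("a", 3))
  bk <- bestkeeper_stats(ct)
  expect_equal(unname(bk$scores["flat"]), 0)
  expect_equal(unname(bk$ranks["flat"]), 1)
  # sd vs mad on a two-sample gene documents the denominator gap
  m2 <- rbind(g1 = c(19, 21), g2 = c(20, 24))
  colnames(m2) <- c("s1", "s2")
  ct2 <- ct_table(m2, c("a", "a"))
  expect_equal(unname(bestkeeper_stats(ct2)$scores["g1"]), sqrt(2),
               tolerance = 1e-12)
  expect_equal(unname(bestkeeper_stats(ct2, dispersion = "mad")$scores["g1"]),
               1)
  # descriptives carry geometric and arithmetic means
  desc <- bk$details$descriptives
  expect_equal(desc$geo_mean[desc$gene == "flat"], 20)
  # index correlations: a zero-variance gene is flagged
  ic <- bestkeeper_index_correlations(ct)
  expect_true(ic$flagged[ic$gene == "flat"])
  expect_false(any(ic$flagged[ic$gene != "flat"]))
})

test_that("index correlation decreases with independent noise and matches
           a direct oracle", {
  set.seed(77)
  base <- stats::rnorm(12, 22, 2)
  r_at_noise <- function(sd) {
    mean(vapply(1:20, function(r) {
      set.seed(100 * sd + r)
      m <- rbind(idx1 = base, idx2 = base + stats::rnorm(12, 0, 0.1),
                 noisy = base + stats::rnorm(12, 0, sd))
      colnames(m) <- paste0("s", 1:12)
      ct <- ct_table(m, rep("a", 12))
      ic <- bestkeeper_index_correlations(ct)
      ic$r[ic$gene == "noisy"]
    }, numeric(1)))
  }
  expect_gt(r_at_noise(0.5), r_at_noise(4))
  # oracle equivalence on a small table
  ct <- random_ct(3, 6, seed = 13)
  ic <- bestkeeper_index_correlations(ct)
  expect_equal(ic$r, unname(oracle_bestkeeper_r(ct$ct)), tolerance = 1e-9)
})

test_that("comparative Delta Ct matches hand computation and the shift
           property", {
  dc <- delta_ct_stability(pair_ct())
  expect_equal(unname(dc$scores), rep(sqrt(0.5), 2), tolerance = 1e-9)
  # a gene shifted by a constant from another gives pair SD 0
  m <- rbind(A = c(20, 21, 19), B = c(23, 24, 22), C = c(20, 25, 22))
  colnames(m) <- paste0("s", 1:3)
  dc2 <- delta_ct_stability(ct_table(m, rep("a", 3)))
  expect_equal(dc2$details$pair_sd["A", "B"], 0)
})

test_that("shift invariance: adding a constant to one gene's row", {
  ct <- random_ct(5, 8, seed = 21)
  shifted <- ct
  shifted$ct["g2", ] <- shifted$ct["g2", ] + 3
  expect_equal(genorm_m_values(shifted), genorm_m_values(ct),
               tolerance = 1e-9)
  expect_equal(delta_ct_stability(shifted)$scores,
               delta_ct_stability(ct)$scores, tolerance = 1e-9)
  expect_equal(normfinder_stability(shifted)$scores,
               normfinder_stability(ct)$scores, tolerance = 1e-9)
  expect_equal(bestkeeper_stats(shifted)$scores, bestkeeper_stats(ct)$scores,
               tolerance = 1e-9)
  # BestKeeper means shift by the constant
  d1 <- bestkeeper_stats(shifted)$details$descriptives
  d0 <- bestkeeper_stats(ct)$details$descriptives
  expect_equal(d1$mean[d1$gene == "g2"], d0$mean[d0$gene == "g2"] + 3)
})

test_that("sample-effect invariance: a per-sample constant added to all
           genes", {
  ct <- random_ct(5, 8, seed = 22)
  off <- seq(-1.4, 1.4, length.out = 8)
  shifted <- ct
  shifted$ct <- sweep(shifted$ct, 2, off, "+")
  expect_equal(genorm_m_values(shifted), genorm_m_values(ct),
               tolerance = 1e-9)
  expect_equal(delta_ct_stability(shifted)$scores,
               delta_ct_stability(ct)$scores, tolerance = 1e-9)
  expect_equal(normfinder_stability(shifted)$scores,
               normfinder_stability(ct)$scores, tolerance = 1e-9)
  # BestKeeper dispersion does change
  expect_false(isTRUE(all.equal(bestkeeper_stats(shifted)$scores,
                                bestkeeper_stats(ct)$scores)))
})

test_that("permutation of samples or genes leaves all scores unchanged", {
  ct <- random_ct(5, 8, seed = 23)
  set.seed(99)
  perm_s <- sample(colnames(ct$ct))
  perm_g <- sample(rownames(ct$ct))
  ct_p <- subset_ct(ct, genes = perm_g, samples = perm_s)
  for (fit_fun in list(function(x) genorm_rank(x)$scores,
                       function(x) normfinder_stability(x)$scores,
                       function(x) bestkeeper_stats(x)$scores,
                       function(x) delta_ct_stability(x)$scores)) {
    a <- fit_fun(ct); b <- fit_fun(ct_p)
    expect_equal(b[names(a)], a, tolerance = 1e-9)
  }
})

test_that("bridge identity: at E = 2 the geNorm pairwise V equals the
           Delta Ct pair SD exactly", {
  ct <- random_ct(5, 8, seed = 24)
  m_pair <- genorm_m_values(ct, c("g1", "g4"))
  dc <- delta_ct_stability(ct)$details$pair_sd["g1", "g4"]
  expect_equal(unname(m_pair[1]), dc, tolerance = 1e-9)
  # and M over the full set equals the Delta Ct score per gene
  expect_equal(genorm_m_values(ct), delta_ct_stability(ct)$scores,
               tolerance = 1e-9)
})

test_that("all four algorithms match naive oracles on random small tables", {
  for (seed in 1:8) {
    set.seed(seed)
    n_g <- sample(3:5, 1)
    n_s <- sample(4:8, 1)
    ct <- random_ct(n_g, n_s, n_groups = 2, seed = seed * 100)
    expect_equal(genorm_m_values(ct), oracle_genorm_m(ct$ct),
                 tolerance = 1e-9)
    gr <- genorm_rank(ct)
    orc <- oracle_genorm_exclusion(ct$ct)
    expect_equal(gr$details$exclusion_order, orc$excluded)
    expect_setequal(gr$details$final_pair, orc$pair)
    expect_equal(genorm_pairwise_variation(ct)$v,
                 oracle_pairwise_variation(ct$ct, gr$details$ranking),
                 tolerance = 1e-9)
    expect_equal(delta_ct_stability(ct)$scores, oracle_delta_ct(ct$ct),
                 tolerance = 1e-9)
    expect_equal(unname(bestkeeper_stats(ct)$scores),
                 unname(oracle_bestkeeper_sd(ct$ct)), tolerance = 1e-9)
    expect_equal(normfinder_stability(ct)$scores,
                 oracle_normfinder(ct$ct, ct$groups), tolerance = 1e-9)
  }
})

test_that("non-default efficiencies flow through the geNorm transform", {
  m <- rbind(g1 = c(10, 11, 12), g2 = c(12, 14, 13), g3 = c(20, 21, 22))
  colnames(m) <- paste0("s", 1:3)
  eff <- c(g1 = 1.9, g2 = 2, g3 = 1.8)
  ct <- ct_table(m, rep("a", 3), efficiencies = eff)
  expect_equal(genorm_m_values(ct), oracle_genorm_m(m, eff),
               tolerance = 1e-9)
})
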