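test_that("identical seed and config give bit-identical output", {
  cfg <- sim_config_pti(seed = 42)
  expect_identical(simulate_ct_table(cfg)$ct, simulate_ct_table(cfg)$ct)
  expect_identical(simulate_count_matrix(cfg)$values,
                   simulate_count_matrix(cfg)$values)
  cfg2 <- sim_config_pti(seed = 43)
  expect_false(identical(simulate_ct_table(cfg)$ct,
                         simulate_ct_table(cfg2)$ct))
})

test_that("all effects and SDs zero give constant genes and zero
           stability everywhere", {
  cfg <- sim_config(paste0("g", 1:4), c(a = 3L, b = 3L),
                    gene_mean_ct = c(g1 = 18, g2 = 20, g3 = 22, g4 = 24),
                    sample_effect_sd = 0, noise_sd = 0, seed = 1)
  ct <- simulate_ct_table(cfg)
  expect_equal(unname(ct$ct["g1", ]), rep(18, 6))
  expect_equal(unname(genorm_m_values(ct)), rep(0, 4))
  expect_equal(unname(delta_ct_stability(ct)$scores), rep(0, 4))
  expect_equal(unname(bestkeeper_stats(ct)$scores), rep(0, 4))
  expect_equal(unname(normfinder_stability(ct)$scores), rep(0, 4))
})

test_that("the generative model is additive: group effect and degradation
           shift expected Ct as configured", {
  cfg <- sim_config(c("g1", "g2"), c(a = 4L, b = 4L),
                    gene_mean_ct = c(g1 = 20, g2 = 22),
                    sample_effect_sd = 0, noise_sd = 0,
                    group_effect = rbind(g1 = c(a = 0, b = 2),
                                         g2 = c(a = 0, b = 0)),
                    degradation_slope = c(g1 = 0, g2 = 0.5),
                    degradation_onset = c(g1 = 0, g2 = 1),
                    group_times = c(a = 0, b = 3), seed = 1)
  ct <- simulate_ct_table(cfg)
  expect_equal(unname(ct$ct["g1", ct$groups == "b"]), rep(22, 4))
  # slope 0.5/day past onset day 1 at time 3 -> +1 cycle
  expect_equal(unname(ct$ct["g2", ct$groups == "b"]), rep(23, 4))
})

test_that("count simulation: equal-abundance symmetry and the Poisson
           small-dispersion limit", {
  cfg <- sim_config(paste0("g", 1:3), c(a = 40L),
                    gene_mean_ct = c(g1 = 20, g2 = 20, g3 = 25),
                    sample_effect_sd = 0, noise_sd = 0, seed = 5)
  cm <- simulate_count_matrix(cfg, library_sizes = 1e5, dispersion = 0.05)
  m1 <- mean(cm$values["g1", ]); m2 <- mean(cm$values["g2", ])
  expect_lt(abs(m1 - m2) / m1, 0.1)           # equal expected TPM
  expect_gt(m1, mean(cm$values["g3", ]))      # lower Ct -> more reads
  # dispersion = 0 draws Poisson: variance about equal to the mean
  cm0 <- simulate_count_matrix(cfg, library_sizes = 1e5, dispersion = 0)
  v <- stats::var(cm0$values["g1", ]); mu <- mean(cm0$values["g1", ])
  expect_lt(abs(v / mu - 1), 0.6)
  # per-gene CV of TPM shrinks as library size grows
  cv_tpm <- function(L, disp) {
    tpm <- tpm_normalize(simulate_count_matrix(cfg, library_sizes = L,
                                               dispersion = disp))
    coefficient_of_variation(tpm$values["g3", ])
  }
  expect_gt(cv_tpm(1e3, 0), cv_tpm(1e6, 0))
})

test_that("a gene configured above the count threshold passes the
           abundance gate", {
  passes <- vapply(1:50, function(r) {
    cfg <- sim_config(paste0("g", 1:5), c(a = 6L),
                      gene_mean_ct = c(g1 = 18, g2 = 20, g3 = 21,
                                       g4 = 22, g5 = 23),
                      noise_sd = 0.2, seed = r)
    cm <- simulate_count_matrix(cfg, library_sizes = 2e5,
                                dispersion = 0.01)
    "g1" %in% abundance_filter(cm, "count")
  }, logical(1))
  # g1 holds ~76% of the library at 2e5 reads: far above 8000 counts
  expect_gte(mean(passes), 0.99)
})

test_that("a planted unstable gene (3-cycle group drift) is ranked last
           by every algorithm", {
  ranked_last <- vapply(1:40, function(r) {
    cfg <- sim_config(paste0("g", 1:6), c(a = 5L, b = 5L, c = 5L),
                      gene_mean_ct = stats::setNames(seq(18, 23, 1),
                                                     paste0("g", 1:6)),
                      sample_effect_sd = 0.5,
                      group_effect = rbind(g1 = c(a = 0, b = 1.5, c = 3),
                                           g2 = 0, g3 = 0, g4 = 0,
                                           g5 = 0, g6 = 0),
                      noise_sd = 0.3, seed = 20000 + r)
    ct <- simulate_ct_table(cfg)
    all(vapply(list(genorm_rank(ct)$ranks,
                    normfinder_stability(ct)$ranks,
                    bestkeeper_stats(ct)$ranks,
                    delta_ct_stability(ct)$ranks),
               function(rk) names(which.max(rk)) == "g1", logical(1)))
  }, logical(1))
  expect_gte(mean(ranked_last), 0.99)
})

test_that("PTI and PMI presets encode the study design", {
  pti <- sim_config_pti(seed = 1)
  expect_length(pti$genes, 15)
  expect_equal(unname(pti$groups), rep(5L, 11))
  expect_equal(sum(pti$groups), 55)
  expect_equal(unname(pti$gene_mean_ct["18S"]), 8.60)
  expect_equal(unname(pti$gene_mean_ct["miR-26a-5p"]), 19.41)
  # miRNA candidates carry no group trend; comRGs do
  expect_true(all(pti$group_effect[grep("^miR", pti$genes), ] == 0))
  expect_true(any(pti$group_effect["ACTB", ] != 0))

  pmi <- sim_config_pmi(seed = 1)
  expect_length(pmi$genes, 11)
  expect_equal(unname(pmi$groups), rep(5L, 6))
  expect_equal(unname(pmi$group_times), c(0, 1.5, 3, 4.5, 6, 7.5))
  # long RNAs degrade faster than miRNAs
  expect_gt(min(pmi$degradation_slope[c("U6", "GAPDH", "18S", "LC-Ogdh")]),
            max(pmi$degradation_slope[grep("^miR", pmi$genes)]))
})

test_that("config validation rejects bad designs", {
  expect_error(sim_config(c("g1", "g1"), c(a = 2L), 20), "unique")
  expect_error(sim_config("g1", c(a = 0L), 20), ">= 1 replicate")
  expect_error(sim_config("g1", c(a = 2L), 20, noise_sd = -1), ">= 0")
  expect_error(sim_config(c("g1", "g2"), c(a = 2L),
                          gene_mean_ct = c(g1 = 20)), "g2")
})
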