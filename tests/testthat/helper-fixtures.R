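# Fixtures built in code: small random Ct tables and a deterministic toy
# table used across test files.

random_ct <- function(n_genes, n_samples, n_groups = 2, seed = 1,
                      base = 20, spread = 3, noise = 1) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  samples <- paste0("s", seq_len(n_samples))
  groups <- rep_len(paste0("grp", seq_len(n_groups)), n_samples)
  m <- matrix(stats::runif(n_genes, base - spread, base + spread) +
                stats::rnorm(n_genes * n_samples, 0, noise),
              n_genes, n_samples, dimnames = list(genes, samples))
  ct_table(m, stats::setNames(groups, samples))
}

# 3 genes x 6 samples: g1 and g2 co-vary (shared sample signal), g3 has
# large independent noise -> geNorm must exclude g3 first
toy3x6 <- function() {
  s <- c(0.0, 0.4, -0.3, 0.2, -0.1, 0.5)          # shared sample signal
  m <- rbind(g1 = 20 + s + c(0.05, -0.02, 0.03, -0.04, 0.01, -0.03),
             g2 = 22 + s + c(-0.03, 0.04, -0.02, 0.05, -0.01, 0.02),
             g3 = 24 + s + c(1.2, -0.8, 0.9, -1.1, 0.7, -1.3))
  colnames(m) <- paste0("s", 1:6)
  ct_table(m, stats::setNames(rep(c("a", "b"), each = 3), colnames(m)))
}

tmp_path <- function(ext) tempfile(fileext = ext)
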