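#' Simulation configuration
#'
#' Describes a grouped qPCR study design for the generators: the gene
#' panel, the group structure (replicates per group, optionally a time in
#' days per group), per-gene baseline Ct, a shared per-sample scaling
#' effect, per-gene x per-group systematic shifts (wound-healing trends),
#' per-gene linear post-mortem degradation (cycles per day past an onset
#' day) and per-gene measurement noise. All effects are additive on the Ct
#' (log2) scale.
#'
#' @param genes character vector of unique gene ids.
#' @param groups named integer vector, group label -> number of replicate
#'   samples (>= 1).
#' @param gene_mean_ct per-gene baseline Ct (cycles); scalar or vector
#'   named by gene.
#' @param sample_effect_sd SD (cycles) of the per-sample offset shared by
#'   all genes (pipetting/input scaling); default 0.5.
#' @param group_effect genes x groups matrix of systematic Ct shifts
#'   (cycles); 0 for stable genes. Default all zero.
#' @param noise_sd per-gene residual SD (cycles); scalar or named vector.
#' @param degradation_slope per-gene Ct increase per day past the onset
#'   (cycles/day); scalar or named vector. Default 0.
#' @param degradation_onset per-gene onset day of degradation; scalar or
#'   named vector. Default 0.
#' @param group_times named numeric vector, group label -> time in days
#'   (drives the degradation term). Default all 0.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output. The Ct generator seeds the RNG with `seed`; the count
#'   generator with `seed + 1` (documented derived substream).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genes, groups, gene_mean_ct,
                       sample_effect_sd = 0.5, group_effect = NULL,
                       noise_sd = 0.3, degradation_slope = 0,
                       degradation_onset = 0, group_times = NULL,
                       seed = 1) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene ids must be unique")
  if (is.null(names(groups))) stop("`groups` must be named by group label")
  if (anyDuplicated(names(groups))) stop("group labels must be unique")
  groups <- stats::setNames(as.integer(groups), names(groups))
  if (any(groups < 1)) stop("every group needs >= 1 replicate")

  per_gene <- function(x, what, default = NULL) {
    if (length(x) == 1 && is.null(names(x)))
      return(stats::setNames(rep(as.numeric(x), length(genes)), genes))
    missing_g <- setdiff(genes, names(x))
    if (length(missing_g))
      stop("`", what, "` missing for gene(s): ",
           paste(missing_g, collapse = ", "))
    stats::setNames(as.numeric(x[genes]), genes)
  }
  gene_mean_ct <- per_gene(gene_mean_ct, "gene_mean_ct")
  noise_sd <- per_gene(noise_sd, "noise_sd")
  degradation_slope <- per_gene(degradation_slope, "degradation_slope")
  degradation_onset <- per_gene(degradation_onset, "degradation_onset")
  if (any(noise_sd < 0) || sample_effect_sd < 0)
    stop("noise and sample-effect SDs must be >= 0")

  if (is.null(group_effect)) {
    group_effect <- matrix(0, length(genes), length(groups),
                           dimnames = list(genes, names(groups)))
  } else {
    group_effect <- as.matrix(group_effect)
    if (!setequal(rownames(group_effect), genes) ||
        !setequal(colnames(group_effect), names(groups)))
      stop("`group_effect` must be a genes x groups matrix with matching names")
    group_effect <- group_effect[genes, names(groups), drop = FALSE]
  }
  if (is.null(group_times))
    group_times <- stats::setNames(rep(0, length(groups)), names(groups))
  group_times <- group_times[names(groups)]
  if (anyNA(group_times)) stop("`group_times` must cover every group")

  structure(list(genes = genes, groups = groups,
                 gene_mean_ct = gene_mean_ct,
                 sample_effect_sd = sample_effect_sd,
                 group_effect = group_effect, noise_sd = noise_sd,
                 degradation_slope = degradation_slope,
                 degradation_onset = degradation_onset,
                 group_times = group_times, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d genes, %d groups (%d samples), seed %d\n",
              length(x$genes), length(x$groups), sum(x$groups), x$seed))
  invisible(x)
}

# per-gene x per-group deterministic expected Ct (no sample effect, no noise)
expected_ct <- function(cfg) {
  drift <- outer(seq_along(cfg$genes), seq_along(cfg$groups),
                 function(i, g) cfg$degradation_slope[i] *
                   pmax(0, cfg$group_times[g] - cfg$degradation_onset[i]))
  m <- cfg$gene_mean_ct + cfg$group_effect + drift
  dimnames(m) <- list(cfg$genes, names(cfg$groups))
  m
}

#' Simulate a grouped Ct table
#'
#' Draws `Ct_ij = mean_i + sample_j + group_effect_{i,g(j)} +
#' slope_i * max(0, time_{g(j)} - onset_i) + eps_ij`, with
#' `sample_j ~ N(0, sample_effect_sd)` shared by all genes of a sample and
#' `eps_ij ~ N(0, noise_sd_i)`. This additive structure is exactly what
#' the stability algorithms decompose: the sample effect is the part a
#' good normalizer must absorb, group effects and degradation are what
#' makes a gene a bad reference.
#'
#' @param cfg a `sim_config`.
#' @return A `ct_table` with samples named `<group>_<replicate>`.
#' @export
simulate_ct_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  glabs <- rep(names(cfg$groups), cfg$groups)
  sample_ids <- paste(glabs, unlist(lapply(cfg$groups, seq_len)), sep = "_")
  n_s <- length(sample_ids)
  n_g <- length(cfg$genes)
  sample_eff <- stats::rnorm(n_s, 0, cfg$sample_effect_sd)
  eps <- matrix(stats::rnorm(n_g * n_s, 0, rep(cfg$noise_sd, n_s)),
                n_g, n_s)
  base <- expected_ct(cfg)[, glabs, drop = FALSE]
  ct <- base + rep(sample_eff, each = n_g) + eps
  dimnames(ct) <- list(cfg$genes, sample_ids)
  band_hi <- max(45, ceiling(max(ct)) + 1)
  ct_table(ct, stats::setNames(glabs, sample_ids),
           ct_band = c(0, band_hi))
}

#' Simulate a negative-binomial count matrix
#'
#' Per-gene relative abundance is derived from the configured Ct surface
#' (one cycle less = twice the abundance, `2^-Ct` proportionality,
#' including group effects and degradation), scaled to the per-sample
#' library size and drawn negative-binomially with the given dispersion;
#' `dispersion = 0` draws Poisson counts.
#'
#' @param cfg a `sim_config`.
#' @param library_sizes per-sample total read count; scalar or vector of
#'   length `sum(cfg$groups)`. Default 2e6.
#' @param dispersion negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2). Default 0.05.
#' @return An `expression_matrix` with `unit = "count"`.
#' @export
simulate_count_matrix <- function(cfg, library_sizes = 2e6,
                                  dispersion = 0.05) {
  stopifnot(inherits(cfg, "sim_config"), dispersion >= 0)
  set.seed(cfg$seed + 1L)
  glabs <- rep(names(cfg$groups), cfg$groups)
  sample_ids <- paste(glabs, unlist(lapply(cfg$groups, seq_len)), sep = "_")
  n_s <- length(sample_ids)
  library_sizes <- rep_len(library_sizes, n_s)
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  w <- 2^(-expected_ct(cfg))[, glabs, drop = FALSE]
  p <- sweep(w, 2, colSums(w), "/")
  mu <- sweep(p, 2, library_sizes, "*")
  counts <- if (dispersion == 0)
    stats::rpois(length(mu), mu)
  else
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  counts <- matrix(as.numeric(counts), nrow(mu), ncol(mu),
                   dimnames = list(cfg$genes, sample_ids))
  expression_matrix(counts, stats::setNames(glabs, sample_ids), "count")
}

# healing-course profiles (unitless, scaled by per-gene amplitude). Each
# trend-carrying comRG gets its own temporal shape -- different cellular
# programs dominate different phases of repair, so their expression
# excursions neither coincide nor share a sign.
pti_groups <- c("NC", "12h", "1d", "3d", "5d", "7d", "9d", "11d", "13d",
                "17d", "21d")
pti_profiles <- rbind(
  ACTB    = c(0, 0.2, 0.5, 0.9, 1, 0.9, 0.7, 0.5, 0.3, 0.1, 0),
  U6      = c(0, 1, 0.8, 0.5, 0.3, 0.2, 0.1, 0, 0, 0, 0),
  GAPDH   = c(0, 0, 0.1, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1),
  `5S`    = c(0, -0.3, -0.6, -1, -0.8, -0.6, -0.4, -0.3, -0.2, -0.1, 0),
  `18S`   = c(0, 0.1, 0.2, 0.3, 0.35, 0.4, 0.4, 0.35, 0.3, 0.2, 0.1),
  `LC-Ogdh` = c(0, -0.5, -0.8, -0.6, -0.3, 0, 0.2, 0.3, 0.3, 0.2, 0.1))
colnames(pti_profiles) <- pti_groups

#' Preset: wound-healing (PTI) study design
#'
#' Fifteen genes -- nine stably expressed miRNA candidates and six
#' commonly used reference genes (comRGs) -- over eleven groups (uninjured
#' control plus ten post-injury time points, five replicate animals each).
#' Baseline Ct values follow the abundance spectrum typical of such
#' panels (18S near 8.6 cycles up to the rarest miRNA near 25.8). The
#' miRNA candidates carry no systematic group shift, reflecting that the
#' sequencing screen already removed trend-carrying miRNAs; each comRG is
#' given its own wound-healing trend (amplitude 0.6-1.2 cycles, distinct
#' phase-specific profiles of mixed sign) and larger noise. The planted
#' most-stable trio (miR-26a-5p, miR-30d-5p, miR-152-3p) has the smallest
#' residual noise.
#'
#' @param seed integer seed.
#' @return A `sim_config`.
#' @export
sim_config_pti <- function(seed = 1) {
  genes <- c("miR-26a-5p", "miR-30d-5p", "miR-152-3p", "miR-27a-3p",
             "miR-148a-3p", "miR-192-5p", "miR-409-5p", "miR-434-3p",
             "miR-541-5p", "U6", "ACTB", "GAPDH", "5S", "18S", "LC-Ogdh")
  mean_ct <- c(`miR-26a-5p` = 19.41, `miR-30d-5p` = 20.76,
               `miR-152-3p` = 21.50, `miR-27a-3p` = 20.04,
               `miR-148a-3p` = 21.00, `miR-192-5p` = 22.50,
               `miR-409-5p` = 25.77, `miR-434-3p` = 24.50,
               `miR-541-5p` = 24.00, U6 = 20.70, ACTB = 18.50,
               GAPDH = 15.87, `5S` = 10.01, `18S` = 8.60,
               `LC-Ogdh` = 23.00)
  noise <- c(`miR-26a-5p` = 0.25, `miR-30d-5p` = 0.25, `miR-152-3p` = 0.28,
             `miR-27a-3p` = 0.50, `miR-148a-3p` = 0.48, `miR-192-5p` = 0.55,
             `miR-409-5p` = 0.60, `miR-434-3p` = 0.65, `miR-541-5p` = 0.55,
             U6 = 0.90, ACTB = 0.80, GAPDH = 0.70, `5S` = 0.85,
             `18S` = 0.55, `LC-Ogdh` = 0.75)
  amp <- c(U6 = 0.8, ACTB = 1.2, GAPDH = 0.8, `5S` = 1.0, `18S` = 0.6,
           `LC-Ogdh` = 0.9)
  group_effect <- matrix(0, length(genes), length(pti_groups),
                         dimnames = list(genes, pti_groups))
  group_effect[names(amp), ] <- amp * pti_profiles[names(amp), ]
  groups <- stats::setNames(rep(5L, length(pti_groups)), pti_groups)
  sim_config(genes, groups, mean_ct,
             sample_effect_sd = 0.5,
             group_effect = group_effect,
             noise_sd = noise, seed = seed)
}

#' Preset: post-mortem (PMI) study design
#'
#' Eleven genes (the seven miRNA candidates kept after the wound-healing
#' screen plus four comRGs) over six post-mortem intervals (0 to 7.5 days,
#' five replicate animals each). Degradation is a per-gene linear Ct rise
#' past an onset day: an early-rising set (LC-Ogdh, miR-26a-5p,
#' miR-30d-5p, miR-192-5p, onset day 1.5, detectable by day 3) and a
#' late-rising set (onset day 3, detectable by day 4.5); slopes are
#' bimodal -- large for the long RNAs (0.35-0.6 cycles/day), uniformly
#' small for the short miRNAs (0.08 cycles/day) -- encoding the far
#' greater and roughly class-uniform post-mortem robustness of miRNAs,
#' which differ in onset rather than rate.
#'
#' @param seed integer seed.
#' @return A `sim_config`.
#' @export
sim_config_pmi <- function(seed = 1) {
  genes <- c("miR-26a-5p", "miR-30d-5p", "miR-152-3p", "miR-27a-3p",
             "miR-148a-3p", "miR-192-5p", "miR-541-5p",
             "U6", "GAPDH", "18S", "LC-Ogdh")
  mean_ct <- c(`miR-26a-5p` = 19.41, `miR-30d-5p` = 20.76,
               `miR-152-3p` = 21.50, `miR-27a-3p` = 20.04,
               `miR-148a-3p` = 21.00, `miR-192-5p` = 22.50,
               `miR-541-5p` = 24.00, U6 = 20.70, GAPDH = 15.87,
               `18S` = 8.60, `LC-Ogdh` = 23.00)
  noise <- c(`miR-26a-5p` = 0.25, `miR-30d-5p` = 0.25, `miR-152-3p` = 0.25,
             `miR-27a-3p` = 0.50, `miR-148a-3p` = 0.50, `miR-192-5p` = 0.48,
             `miR-541-5p` = 0.52, U6 = 0.60, GAPDH = 0.70, `18S` = 0.75,
             `LC-Ogdh` = 0.65)
  slope <- c(`miR-26a-5p` = 0.08, `miR-30d-5p` = 0.08, `miR-152-3p` = 0.08,
             `miR-27a-3p` = 0.08, `miR-148a-3p` = 0.08, `miR-192-5p` = 0.08,
             `miR-541-5p` = 0.08, U6 = 0.35, GAPDH = 0.45, `18S` = 0.50,
             `LC-Ogdh` = 0.60)
  onset <- c(`miR-26a-5p` = 1.5, `miR-30d-5p` = 1.5, `miR-152-3p` = 3,
             `miR-27a-3p` = 3, `miR-148a-3p` = 3, `miR-192-5p` = 1.5,
             `miR-541-5p` = 3, U6 = 3, GAPDH = 3, `18S` = 3,
             `LC-Ogdh` = 1.5)
  times <- c(`0d` = 0, `1.5d` = 1.5, `3d` = 3, `4.5d` = 4.5, `6d` = 6,
             `7.5d` = 7.5)
  groups <- stats::setNames(rep(5L, length(times)), names(times))
  sim_config(genes, groups, mean_ct, sample_effect_sd = 0.5,
             noise_sd = noise, degradation_slope = slope,
             degradation_onset = onset, group_times = times, seed = seed)
}

#' Preset: small-RNA sequencing screen design
#'
#' A count-matrix design emulating an NGS preselection screen: `n_genes`
#' miRNAs over five groups (uninjured control plus four post-injury time
#' points, three replicate libraries each). Baseline Ct-scale abundances
#' span 13-26 cycles; a planted block of twelve abundant genes contains
#' six with no group trend (the stable candidates a screen should find)
#' and six trend-carrying competitors; the remaining genes get random
#' wound-responsive trends (amplitude up to 2 cycles, drawn once from the
#' config seed).
#'
#' @param seed integer seed.
#' @param n_genes panel size (default 150).
#' @return A `sim_config`.
#' @export
sim_config_ngs <- function(seed = 1, n_genes = 150) {
  genes <- sprintf("mir-%03d", seq_len(n_genes))
  mean_ct <- stats::setNames(seq(13, 26, length.out = n_genes), genes)
  groups <- c(NC = 3L, `12h` = 3L, `3d` = 3L, `7d` = 3L, `14d` = 3L)
  shape <- c(NC = 0, `12h` = 0.5, `3d` = 1, `7d` = 0.7, `14d` = 0.2)
  set.seed(seed)
  amp <- stats::setNames(stats::runif(n_genes, 0.3, 2), genes)
  amp[1:12] <- 0
  amp[7:12] <- stats::runif(6, 0.5, 1.5)   # abundant but trend-carrying
  sim_config(genes, groups, mean_ct, sample_effect_sd = 0.3,
             group_effect = outer(amp, shape), noise_sd = 0.2,
             seed = seed)
}
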