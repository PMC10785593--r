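`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values first.
#' @return The geometric mean `exp(mean(log(x)))`.
#' @export
geo_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geo_mean() requires strictly positive values")
  exp(mean(log(x)))
}

# Sample SD with selectable denominator. The n-1 (unbiased) form is the
# package-wide default; "n" rescales to the population form.
sd_denom <- function(x, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  n <- length(x)
  s <- stats::sd(x)
  if (denom == "n") s * sqrt((n - 1) / n) else s
}

# Mean absolute deviation about the arithmetic mean (the dispersion used by
# the original BestKeeper spreadsheet; distinct from stats::mad).
mean_abs_dev <- function(x) mean(abs(x - mean(x)))

# Average ranks, ascending (1 = smallest), ties share the average rank.
rank_ascending <- function(scores) {
  r <- rank(scores, ties.method = "average")
  names(r) <- names(scores)
  r
}

# Deterministic field separator from a file extension.
infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

fmt6 <- function(x) formatC(x, digits = 6, format = "f")
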