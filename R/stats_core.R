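#' Pearson correlation with degenerate-input checks
#'
#' Thin wrapper over [stats::cor()] that refuses silently undefined
#' results: both vectors must have length >= 3 and nonzero variance.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The sample Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 observations for a correlation")
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input")
  if (stats::var(x) == 0) stop("degenerate input: 'x' has zero variance")
  if (stats::var(y) == 0) stop("degenerate input: 'y' has zero variance")
  stats::cor(x, y)
}

#' Two-sample Student's t test
#'
#' Classical pooled-variance (equal-variance) two-sample t test with
#' `df = n_a + n_b - 2` and a two-sided p value; this is the textbook
#' "Student's t test". Welch's unequal-variance variant is available
#' behind `var_equal = FALSE` but is not the default.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance test (default `TRUE`).
#' @return A list with `statistic`, `p_value` and `df`.
#' @export
student_t_two_sample <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 observations")
  if (anyNA(a) || anyNA(b)) stop("missing values in t-test input")
  if (var_equal && stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate input: zero pooled variance")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values in the input order, capped at 1.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Log-log ordinary least squares fit of a degree distribution
#'
#' Regresses `log10(count of nodes with degree k)` on `log10(k)` over the
#' degrees with nonzero count -- the scale-free check conventional in
#' network viewers. Raw counts are used (no log-binning, no CCDF);
#' zero-count degrees never enter because the table is built from the
#' observed sequence.
#'
#' @param degrees Vector of positive integer node degrees.
#' @return A list with `slope`, `intercept`, `r_squared`.
#' @export
log_log_fit <- function(degrees) {
  if (!length(degrees)) stop("empty degree sequence")
  if (anyNA(degrees) || any(degrees < 1) || any(degrees != round(degrees))) {
    stop("degrees must be positive integers")
  }
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  if (length(k) < 2) stop("need >= 2 distinct degree values for a log-log fit")
  lx <- log10(k)
  ly <- log10(cnt)
  fit <- stats::lm(ly ~ lx)
  coefs <- stats::coef(fit)
  tss <- sum((ly - mean(ly))^2)
  rss <- sum(stats::residuals(fit)^2)
  # constant counts fit a horizontal line exactly; define R^2 = 1 there
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  list(slope = unname(coefs[2]), intercept = unname(coefs[1]),
       r_squared = max(0, min(1, r2)))
}

# Deterministic string/seed hash onto [0, 2^31 - 2]; used to derive
# per-motif permutation seeds from (master seed, site, tf, gene) so that
# results do not depend on motif iteration order.
stable_hash <- function(...) {
  s <- paste(vapply(list(...), as.character, ""), collapse = "\x1f")
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}
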