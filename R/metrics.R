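# Rate-coding metrics: activity-fraction selectivity, total and noise
# entropy of the binned rate distribution, mutual information and coding
# efficiency; plus the thin statistical layer used for model comparisons.

#' Activity-fraction selectivity
#'
#' Nonparametric lifetime-sparseness index
#' `A = (1 - (sum(r_i)/N)^2 / (sum(r_i^2)/N)) / (1 - 1/N)`
#' over the across-trial mean rate `r_i` of each of the `N` syllable
#' classes. `A = 0` for perfectly uniform responses and `A = 1` when only
#' one class drives the neuron; invariant to overall rate scaling.
#'
#' @param mean_rates across-trial mean rate per syllable class (Hz)
#' @return selectivity in \[0, 1\]; `NA` when every rate is zero
#' @export
activity_fraction <- function(mean_rates) {
  r <- as.numeric(mean_rates)
  N <- length(r)
  if (N < 2) stop("activity fraction requires at least 2 syllable classes")
  if (any(r < 0)) stop("rates must be non-negative")
  if (all(r == 0)) return(NA_real_)
  (1 - (sum(r) / N)^2 / (sum(r^2) / N)) / (1 - 1 / N)
}

#' Discretize rates into equal-width bins
#'
#' Bins span \[min, max\] of all rates of the model (every syllable and
#' trial); the top bin is right-closed so the maximum rate lands in bin
#' `n_bins`.
#'
#' @param rates numeric rates (Hz)
#' @param n_bins number of bins (>= 2); 15 is the default used throughout
#' @return integer bin index per rate (all 1 with attribute
#'   `degenerate = TRUE` when min == max)
#' @export
discretize_rates <- function(rates, n_bins = 15) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  r <- as.numeric(rates)
  lo <- min(r); hi <- max(r)
  if (hi - lo <= 0) {
    return(structure(rep(1L, length(r)), degenerate = TRUE))
  }
  idx <- pmin(as.integer(floor((r - lo) / (hi - lo) * n_bins)) + 1L,
              as.integer(n_bins))
  structure(idx, degenerate = FALSE)
}

#' Entropies and mutual information of a binned rate code
#'
#' Plug-in estimates from empirical frequencies, with no sample-size bias
#' correction: total entropy `H(R) = -sum p(r) log2 p(r)` over the binned
#' rate distribution; noise entropy
#' `H(R|S) = -sum_s p(s) sum_r p(r|s) log2 p(r|s)`; mutual information
#' `MI = H(R) - H(R|S)`; coding efficiency `1 - H(R|S)/H(R)`.
#'
#' @param bins integer bin index per response (from [discretize_rates()])
#' @param classes syllable class per response (same length)
#' @return list with `H_T`, `H_N`, `MI`, `efficiency` (all bits except
#'   the dimensionless efficiency; efficiency is `NA` when `H_T` is 0)
#' @export
entropies <- function(bins, classes) {
  if (length(bins) == 0) stop("empty response table")
  if (length(bins) != length(classes))
    stop("bins and classes must have equal length")
  plogp <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  H_T <- plogp(table(bins) / length(bins))
  cls <- unique(classes)
  p_s <- vapply(cls, function(s) mean(classes == s), numeric(1))
  H_cond <- vapply(cls, function(s) {
    b <- bins[classes == s]
    plogp(table(b) / length(b))
  }, numeric(1))
  H_N <- sum(p_s * H_cond)
  list(H_T = H_T, H_N = H_N, MI = H_T - H_N,
       efficiency = if (H_T > 0) 1 - H_N / H_T else NA_real_)
}

#' Rate-coding metrics of a model's response table
#'
#' Convenience wrapper computing selectivity (over across-trial mean
#' rates) and the entropy family (over 15-bin discretized single-trial
#' rates) from one [rate_table()].
#'
#' @param tbl a `rate_table`
#' @param n_bins discretization bins
#' @return one-row data.frame with `A`, `H_T`, `H_N`, `MI`, `efficiency`,
#'   `n_bins`, `N` (number of syllable classes) and `mean_rate` (Hz)
#' @export
response_metrics <- function(tbl, n_bins = 15) {
  mean_rates <- tapply(tbl$rate, tbl$class, mean)
  A <- activity_fraction(mean_rates)
  bins <- discretize_rates(tbl$rate, n_bins)
  e <- entropies(bins, tbl$class)
  data.frame(A = A, H_T = e$H_T, H_N = e$H_N, MI = e$MI,
             efficiency = e$efficiency, n_bins = n_bins,
             N = length(mean_rates), mean_rate = mean(tbl$rate))
}

#' Paired comparison of a metric between model variants
#'
#' Classical paired t test on the differences `x - y`, with the count of
#' pairs of each sign. Zero-variance differences are flagged degenerate
#' (t undefined).
#'
#' @param x,y equal-length paired samples (e.g. the phasic and tonic
#'   values of a metric across RF pairs)
#' @return list with `t`, `df`, `p`, `mean_diff`, `n_pos`, `n_neg`,
#'   `degenerate`
#' @export
paired_compare <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  d <- x - y
  out <- list(mean_diff = mean(d), n_pos = sum(d > 0), n_neg = sum(d < 0),
              n = length(d))
  if (sd(d) < 1e-12) {
    out$t <- if (abs(mean(d)) < 1e-12) 0 else NA_real_
    out$df <- length(d) - 1
    out$p <- NA_real_
    out$degenerate <- TRUE
  } else {
    tt <- t.test(x, y, paired = TRUE)
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p <- tt$p.value
    out$degenerate <- FALSE
  }
  out
}

#' Pearson correlation between two metrics
#'
#' @param x,y numeric vectors (pairs with missing values are dropped)
#' @return list with `r`, `p`, `n`; `r` is `NA` when either variable has
#'   zero variance
#' @export
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) < 1e-12 || sd(y) < 1e-12)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-sample Kolmogorov-Smirnov test on rate distributions
#'
#' @param rates_a,rates_b syllable-level rate samples
#' @return list with `D` and `p`
#' @export
rate_distribution_test <- function(rates_a, rates_b) {
  if (length(rates_a) == 0 || length(rates_b) == 0)
    stop("both samples must be non-empty")
  ks <- suppressWarnings(ks.test(rates_a, rates_b))
  list(D = unname(ks$statistic), p = ks$p.value)
}

#' Interaction F test: metric ~ dynamics x covariate
#'
#' Fits the two-factor linear model `metric ~ dynamics * covariate` and
#' tests the interaction term, i.e. whether the slope of the metric
#' against the continuous covariate differs between dynamics types.
#'
#' @param data data.frame
#' @param metric,dynamics,covariate column names
#' @return list with `F`, `df1`, `df2`, `p`
#' @export
interaction_test <- function(data, metric, dynamics, covariate) {
  df <- data.frame(y = data[[metric]],
                   g = factor(data[[dynamics]]),
                   x = as.numeric(data[[covariate]]))
  df <- df[stats::complete.cases(df), ]
  if (nlevels(droplevels(df$g)) < 2 || length(unique(df$x)) < 2)
    stop("rank-deficient design: need 2 dynamics levels and a varying covariate")
  fit <- lm(y ~ g * x, data = df)
  an <- anova(fit)
  row <- grep(":", rownames(an))
  list(F = an$`F value`[row], df1 = an$Df[row],
       df2 = an$Df[nrow(an)], p = an$`Pr(>F)`[row])
}
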