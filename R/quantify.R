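#' Bland-Altman agreement between two runs
#'
#' Paired-difference analysis of normalized counts from two independent
#' runs of the same samples: bias = mean(run1 - run2), sd = sample
#' standard deviation of the differences, and 95% limits of agreement
#' bias +/- 1.96 sd.
#'
#' @param run1,run2 Equal-length paired numeric vectors.
#' @return list: `bias`, `sd`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(run1, run2) {
  if (length(run1) != length(run2)) stop("runs must be paired")
  if (length(run1) < 2) stop("need at least 2 pairs")
  d <- run1 - run2
  bias <- mean(d); s <- sd(d)
  list(bias = bias, sd = s, loa_low = bias - 1.96 * s,
       loa_high = bias + 1.96 * s, n = length(d))
}

#' Pearson correlation with input validation
#'
#' @param x,y Numeric vectors, length >= 3, each with nonzero variance.
#' @return Product-moment correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired vectors of length >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  cor(x, y)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum U statistic with ties handled by midranks. The two-sided
#' p-value is exact by complete enumeration of group assignments when the
#' combined sample size is at most `exact_max` (default 10; ties
#' included), and otherwise uses the normal approximation with continuity
#' and tie correction.
#'
#' @param g1,g2 Numeric vectors.
#' @param exact_max Maximum combined n for the enumeration p-value.
#' @return list: `U` (for `g1`), `p`, `method`.
#' @export
mann_whitney_u <- function(g1, g2, exact_max = 10) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  pooled <- c(g1, g2)
  u_of <- function(idx1) {
    r <- rank(pooled)
    sum(r[idx1]) - n1 * (n1 + 1) / 2
  }
  U <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    r <- rank(pooled)
    combos <- combn(n1 + n2, n1)
    Us <- apply(combos, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}

#' Spike-in calibration regression
#'
#' Least-squares line of measured normalized counts against expected
#' spike-in percentage, inverted to convert measurements into calculated
#' percentages (classical calibration).
#'
#' @param expected_pct Expected spike-in percentages (>= 2 distinct).
#' @param values Measured normalized counts (paired).
#' @return list: `slope`, `intercept`, `r`, `calculated_pct`
#'   (per input sample) and the inverse function `pct_of(value)`.
#' @export
spikein_regression <- function(expected_pct, values) {
  if (length(unique(expected_pct)) < 2)
    stop("need at least 2 distinct expected fractions")
  fit <- lm(values ~ expected_pct)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (abs(slope) < 1e-12) stop("zero calibration slope; calculated % undefined")
  pct_of <- function(v) (v - intercept) / slope
  list(slope = slope, intercept = intercept,
       r = cor(expected_pct, values),
       calculated_pct = pct_of(values), pct_of = pct_of)
}

#' Limits of blank and detection (Armbruster)
#'
#' LOB = mean(blank) + 1.645 sd(blank); LOD = LOB + 1.645 sd(low-level
#' replicates); both on the measurement (normalized-count) scale, with
#' the corresponding methylation percentage obtained through the
#' calibration line of the dilution series.
#'
#' @param blank Replicate measurements of blank (0%-methylated) samples.
#' @param low Replicate measurements of a low-level sample.
#' @param calibration list with `slope` and `intercept` (e.g. from
#'   [spikein_regression()]) mapping methylation % to measurement.
#' @return list: `lob`, `lod`, `lod_methylation_pct`.
#' @export
lob_lod <- function(blank, low, calibration) {
  if (length(blank) < 2 || length(low) < 2)
    stop("need >= 2 replicates for blank and low-level samples")
  if (calibration$slope == 0) stop("degenerate calibration (zero slope)")
  lob <- mean(blank) + 1.645 * sd(blank)
  lod <- lob + 1.645 * sd(low)
  list(lob = lob, lod = lod,
       lod_methylation_pct = (lod - calibration$intercept) / calibration$slope)
}

#' Two-sample power, normal approximation, Bonferroni-corrected
#'
#' Power of a two-sided unequal-variance z-test at per-test level
#' alpha_family / n_tests:
#' power = Phi(delta - z) + Phi(-delta - z) with
#' delta = |mu1 - mu2| / sqrt(sd1^2/n1 + sd2^2/n2) and
#' z the 1 - alpha/2 normal quantile. Under the null (mu1 = mu2) this
#' reduces to the per-test alpha.
#'
#' @param n1,n2 Group sizes.
#' @param mu1,mu2 Group means (methylation levels).
#' @param sd1,sd2 Group standard deviations (> 0).
#' @param n_tests Number of tests for the Bonferroni correction.
#' @param alpha_family Family-wise alpha (default 0.05).
#' @return Power in (0, 1).
#' @export
power_two_sample <- function(n1, n2, mu1, sd1, mu2, sd2,
                             n_tests = 1, alpha_family = 0.05) {
  stopifnot(sd1 > 0, sd2 > 0, n_tests >= 1, n1 >= 2, n2 >= 2)
  alpha <- alpha_family / n_tests
  z <- qnorm(1 - alpha / 2)
  delta <- abs(mu1 - mu2) / sqrt(sd1^2 / n1 + sd2^2 / n2)
  pnorm(delta - z) + pnorm(-delta - z)
}

#' Undigested fraction from a qPCR delta-Ct
#'
#' With digested and undigested aliquots amplified over the same
#' recognition site, the surviving (undigested) fraction is
#' 2^-(Ct_digested - Ct_undigested); its reciprocal is the "1 in N"
#' molecules figure.
#'
#' @param ct_digested,ct_undigested Mean Ct values (>= 0).
#' @return list: `delta_ct`, `fraction`, `one_in_n`.
#' @export
undigested_fraction_from_dct <- function(ct_digested, ct_undigested) {
  stopifnot(ct_digested >= 0, ct_undigested >= 0)
  dct <- ct_digested - ct_undigested
  if (dct < 0)
    warning("digested sample amplifies earlier than undigested (negative delta-Ct)")
  list(delta_ct = dct, fraction = 2^(-dct), one_in_n = 2^dct)
}
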