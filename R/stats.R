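#' Paired two-tailed Student t-test
#'
#' Classical paired t-test on the per-subject differences
#' (\code{df = n - 1}), the test used for all before/after comparisons of
#' lung areas and signal levels in the cohort analysis.
#'
#' @param before,after numeric vectors of equal length (n >= 2), paired by
#'   subject.
#' @return List with \code{t}, \code{p} (two-tailed), \code{meanDiff}
#'   (after - before), \code{sdDiff}, \code{df} and \code{n}.
#' @export
pairedTTest <- function(before, after) {
  stopifnot(is.numeric(before), is.numeric(after),
            length(before) == length(after), length(before) >= 2)
  d <- after - before
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t-test undefined")
  ht <- stats::t.test(after, before, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       meanDiff = mean(d), sdDiff = stats::sd(d),
       df = unname(ht$parameter), n = length(d))
}

#' Power of the paired two-tailed t-test
#'
#' Exact two-sided power from the noncentral t distribution with
#' noncentrality \eqn{(\mu_d/\sigma_d)\sqrt{n}} and \eqn{n - 1} degrees of
#' freedom: the probability that \eqn{|T|} exceeds the two-sided critical
#' value under the alternative.
#'
#' @param muD mean paired difference under the alternative.
#' @param sdD standard deviation of the paired differences (> 0).
#' @param n number of pairs (>= 2).
#' @param alpha two-sided significance level, in (0, 1).
#' @return Power as a probability in (0, 1).
#' @examples
#' powerPairedTTest(1.933, 0.734, n = 6, alpha = 0.05)  # 0.999
#' @export
powerPairedTTest <- function(muD, sdD, n, alpha = 0.05) {
  stopifnot(sdD > 0, n >= 2, alpha > 0, alpha < 1)
  ncp <- (muD / sdD) * sqrt(n)
  df <- n - 1
  tcrit <- stats::qt(1 - alpha / 2, df)
  (1 - stats::pt(tcrit, df, ncp = ncp)) + stats::pt(-tcrit, df, ncp = ncp)
}

#' Organ dose from the dose area product
#'
#' Multiplies the dose area product of a scan (Gy cm2) by a dimensionless
#' organ weighting factor; by the convention used for lung dosimetry of the
#' scan protocol the product is read in mSv.
#'
#' @param dapGyCm2 dose area product in Gy cm2 (>= 0).
#' @param weightingFactor tissue weighting factor (>= 0), e.g. 0.16 for lung.
#' @return Organ-specific dose in mSv.
#' @examples
#' organDoseFromDap(0.5, 0.16)  # 0.08 mSv
#' @export
organDoseFromDap <- function(dapGyCm2, weightingFactor) {
  stopifnot(dapGyCm2 >= 0, weightingFactor >= 0)
  dapGyCm2 * weightingFactor
}
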