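# Chromosome-size regressions on PCVE and the migration-edge-count vs
# slope correlation.

#' Bayesian regression of tree-likeness (PCVE) on chromosome size
#'
#' Both variables are standardized (mean 0, SD 1) and a conjugate
#' normal-inverse-gamma linear model is fitted analytically (no sampler):
#' coefficients have prior `N(0, sigma^2 I)` -- a weakly informative
#' standard-normal prior on the standardized slope -- with
#' `sigma^2 ~ Inv-Gamma(2, 1)`.  The marginal posterior of the slope is a
#' scaled t distribution, from which the equal-tail interval and
#' `P(beta < 0)` are exact.
#'
#' @param pcveValues named numeric, per-chromosome PCVE (autosomes only; the
#'   caller excludes the Z).
#' @param sizes named numeric, chromosome sizes in bp.
#' @param level credible level for the equal-tail interval (default 0.95).
#' @return list with `beta` (posterior mean standardized slope), `etpi`
#'   (equal-tail probability interval), `probNegative`, `r2` (least-squares
#'   coefficient of determination), `n`, and `posterior` (location, scale,
#'   df of the slope's t posterior).
#' @export
pcveSizeRegression <- function(pcveValues, sizes, level = 0.95) {
  common <- intersect(names(pcveValues), names(sizes))
  if (length(common) >= 3L) {
    pcveValues <- pcveValues[common]
    sizes <- sizes[common]
  }
  n <- length(pcveValues)
  if (n < 3L) stop("need >= 3 chromosomes")
  if (sd(sizes) == 0)
    stop("regression undefined: zero variance in chromosome sizes")
  x <- as.vector(scale(sizes))
  # a constant response carries no signal: centered it is identically zero,
  # so the slope posterior is symmetric about 0 (flagged by message)
  y <- if (sd(pcveValues) == 0) {
    message("pcveSizeRegression: constant response; no signal")
    rep(0, n)
  } else as.vector(scale(pcveValues))
  X <- cbind(1, x)
  a0 <- 2; b0 <- 1                      # Inv-Gamma(2, 1) on sigma^2
  V0inv <- diag(2)                      # coefficients ~ N(0, sigma^2 I)
  Vn <- solve(V0inv + crossprod(X))
  mn <- Vn %*% crossprod(X, y)
  an <- a0 + n / 2
  bn <- b0 + (sum(y^2) - t(mn) %*% (V0inv + crossprod(X)) %*% mn)[1] / 2
  scaleB <- sqrt(bn / an * Vn[2, 2])
  df <- 2 * an
  alpha <- (1 - level) / 2
  etpi <- mn[2] + scaleB * qt(c(alpha, 1 - alpha), df)
  list(beta = mn[2],
       etpi = etpi,
       probNegative = pt((0 - mn[2]) / scaleB, df),
       r2 = if (all(y == 0)) 0 else summary(lm(y ~ x))$r.squared,
       n = n,
       posterior = list(location = mn[2], scale = scaleB, df = df))
}

#' Correlation between migration-edge count and size-PCVE slope
#'
#' Pearson correlation (Fisher-z 95 percent CI, two-sided t-test P) between
#' the number of migration edges `m` and the standardized slope of the
#' PCVE-vs-chromosome-size regression at each `m`.  A positive correlation
#' indicates that graphs with more migration edges explain relatively more
#' covariance on larger chromosomes.
#'
#' @param slopes numeric, standardized slope per edge count; `m` defaults to
#'   `0 : (length(slopes) - 1)`.
#' @param m migration-edge counts matching `slopes` (>= 3 values).
#' @return list with `r`, `conf.int`, `p.value`, `n`.
#' @export
slopeEdgeCorrelation <- function(slopes, m = seq_along(slopes) - 1) {
  if (length(slopes) < 3L) stop("need >= 3 edge counts")
  if (sd(slopes) == 0 || sd(m) == 0) stop("correlation undefined: zero variance")
  ct <- cor.test(m, slopes)
  list(r = unname(ct$estimate), conf.int = as.numeric(ct$conf.int),
       p.value = ct$p.value, n = length(slopes))
}
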