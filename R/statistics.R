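#' Standardize the joint male/female distribution
#'
#' Centres and scales the pooled 2N score values (males and females
#' concatenated) to mean 0 and sample standard deviation 1. Pairing and
#' species order are preserved. The transform is affine-invariant:
#' standardizing `a * x + b` gives the same result as standardizing `x`.
#'
#' @param tips a [tip_phenotypes()] data frame with >= 2 species.
#' @return the standardized `tip_phenotypes`.
#' @export
standardize_joint <- function(tips) {
  stopifnot(nrow(tips) >= 2)
  pooled <- c(tips$male, tips$female)
  s <- sd(pooled)
  if (s == 0) stop("zero pooled variance: cannot standardize")
  mu <- mean(pooled)
  tip_phenotypes(tips$species, (tips$male - mu) / s, (tips$female - mu) / s)
}

#' Difference of male and female standard deviations (DSD)
#'
#' `sd(male) - sd(female)`, with sample (n - 1) standard deviations. The
#' constrained sex diversifies less, so DSD tends to be positive when
#' females are constrained, negative when males are, and intermediate under
#' mutual constraint.
#'
#' @param tips a [tip_phenotypes()] data frame with >= 2 species.
#' @return a single number.
#' @export
dsd <- function(tips) {
  stopifnot(nrow(tips) >= 2)
  sd(tips$male) - sd(tips$female)
}

#' Normalized sample skewness Zg1 (D'Agostino)
#'
#' The D'Agostino (1970) normalizing transformation of the sample skewness
#' sqrt(b1) = m3 / m2^(3/2) (central moments with denominator n). Under
#' normality Zg1 is approximately standard normal, which is what makes the
#' pooled-skew statistic comparable across sample sizes. Requires n >= 8:
#' the transformation constants are undefined below that.
#'
#' @param values numeric vector, n >= 8, nonzero variance.
#' @return the Zg1 statistic (sign matches the sign of the raw skewness).
#' @export
skew_zg1 <- function(values) {
  n <- length(values)
  if (n < 8) stop("skew_zg1 requires n >= 8 (got ", n, ")")
  xc <- values - mean(values)
  m2 <- mean(xc^2)
  if (m2 == 0) stop("zero variance: skewness undefined")
  sqrtb1 <- mean(xc^3) / m2^1.5
  zg1_transform(sqrtb1, n)
}

# The normalizing transformation itself, vectorized over sqrtb1 for a fixed
# n (used on whole null distributions at once).
zg1_transform <- function(sqrtb1, n) {
  Y <- sqrtb1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
}

#' Difference of reciprocal regression slopes (DRS)
#'
#' OLS slope of female-on-male minus the OLS slope of male-on-female,
#' equal in closed form to `r * (sd_f / sd_m) - r * (sd_m / sd_f)`. Steeper
#' female-on-male slopes are expected when females are the independent sex,
#' shallower when males are, so the difference separates the one-sided
#' models in opposite directions.
#'
#' @param tips a [tip_phenotypes()] data frame with >= 3 species and
#'   nonzero variance in each sex.
#' @return a single number.
#' @export
drs <- function(tips) {
  stopifnot(nrow(tips) >= 3)
  vm <- var(tips$male); vf <- var(tips$female)
  if (vm == 0 || vf == 0) stop("zero variance in one sex: slopes undefined")
  cv <- stats::cov(tips$male, tips$female)
  cv / vm - cv / vf
}

#' The three summary statistics of a score table
#'
#' Standardizes the joint male/female distribution, then computes DSD, the
#' pooled Zg1 skew (SK) of the 2N standardized values, and DRS.
#'
#' @param tips a [tip_phenotypes()] data frame with >= 4 species (so the
#'   pooled sample has n >= 8 for Zg1).
#' @return a named list of class `summary_statistics` with elements `dsd`,
#'   `sk`, `drs` and `n_species`.
#' @export
compute_statistics <- function(tips) {
  stopifnot(nrow(tips) >= 4)
  std <- standardize_joint(tips)
  structure(
    list(
      dsd = dsd(std),
      sk = skew_zg1(c(std$male, std$female)),
      drs = drs(std),
      n_species = nrow(tips)
    ),
    class = "summary_statistics"
  )
}

# Vectorized statistics for a simulation batch: one (DSD, SK, DRS) triple
# per run, computed on the jointly standardized pooled values exactly as
# compute_statistics() does for a single table.
batch_statistics <- function(sim) {
  M <- sim$male; F_ <- sim$female
  n_tip <- nrow(M)
  P <- rbind(M, F_)
  n2 <- 2 * n_tip
  mu <- colMeans(P)
  Pc <- sweep(P, 2, mu)
  ss <- colSums(Pc^2)
  s_pool <- sqrt(ss / (n2 - 1))           # sample SD of the pooled values
  m2 <- ss / n2                           # denominator-n central moments
  m3 <- colMeans(Pc^3)
  sk <- zg1_transform(m3 / m2^1.5, n2)

  cm <- colMeans(M); cf <- colMeans(F_)
  Mc <- sweep(M, 2, cm); Fc <- sweep(F_, 2, cf)
  sm <- sqrt(colSums(Mc^2) / (n_tip - 1))
  sf <- sqrt(colSums(Fc^2) / (n_tip - 1))
  dsd <- (sm - sf) / s_pool
  cv <- colSums(Mc * Fc) / (n_tip - 1)
  drs <- cv / sm^2 - cv / sf^2
  data.frame(DSD = dsd, SK = sk, DRS = drs)
}
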