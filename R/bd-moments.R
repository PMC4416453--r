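# Closed-form quantities for the constant-rate birth-death process and the
# method-of-moments net diversification estimators built on them.
#
# Conventions (used throughout the package):
#   * logarithms are natural; rates are events per lineage per Myr
#   * epsilon = mu/lambda, the relative extinction fraction, must lie in [0, 1);
#     the critical process epsilon = 1 is rejected, never clamped
#   * stem basis conditions on >= 1 survivor from one founder lineage;
#     crown tail probabilities condition on BOTH crown lineages leaving
#     survivors (see the methods vignette for why the estimator's implied
#     conditioning differs)

.stop_domain <- function(...) {
  stop(errorCondition(sprintf(...), class = c("rf_domain_error", "error")))
}

.check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || anyNA(epsilon) ||
      any(epsilon < 0) || any(epsilon >= 1))
    .stop_domain("'epsilon' must lie in [0, 1); the critical case epsilon = 1 is unsupported")
  invisible(epsilon)
}

.check_age <- function(t, name = "t") {
  if (!is.numeric(t) || anyNA(t) || any(t <= 0))
    .stop_domain("'%s' must be a positive age in Myr", name)
  invisible(t)
}

.check_rate_nonneg <- function(r) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0))
    .stop_domain("'r' must be >= 0: the declining-diversity regime (r < 0) is unsupported")
  invisible(r)
}

# recycle arguments to a common length, erroring on incompatible lengths
.recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- vapply(args, function(a) n %% length(a) != 0L, logical(1))
  if (any(bad)) .stop_domain("argument lengths are not multiples of each other")
  lapply(args, rep_len, n)
}

#' Birth-death parameter set
#'
#' Bundles speciation and extinction rates with the derived net
#' diversification rate `r = lambda - mu` and extinction fraction
#' `epsilon = mu/lambda`.
#'
#' @param lambda Speciation rate, events per lineage per Myr (> 0).
#' @param mu Extinction rate, events per lineage per Myr (>= 0, < `lambda`).
#' @return An object of class `"bd_params"`: a list with elements `lambda`,
#'   `mu`, `r` and `epsilon`.
#' @examples
#' bd_params(0.3, 0.15)
#' @export
bd_params <- function(lambda, mu = 0) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda <= 0)
    .stop_domain("'lambda' must be a single positive rate")
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    .stop_domain("'mu' must be a single non-negative rate")
  epsilon <- mu / lambda
  .check_epsilon(epsilon)
  structure(list(lambda = lambda, mu = mu, r = lambda - mu, epsilon = epsilon),
            class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf("Birth-death parameters: lambda = %g, mu = %g (r = %g, epsilon = %g)\n",
              x$lambda, x$mu, x$r, x$epsilon))
  invisible(x)
}

#' Two-taxon diversity adjustment
#'
#' Crown-based rate estimation degenerates for clades of exactly two species
#' (the estimator returns zero regardless of age). Following standard practice
#' in method-of-moments meta-analyses, two-taxon clades are assigned a
#' diversity of 2.01, which yields a small positive rate. Any other clade
#' size passes through unchanged, so the adjustment is idempotent.
#'
#' @param n Clade size(s), real-valued, >= 1.
#' @return `n` with exact values of 2 replaced by 2.01.
#' @examples
#' two_taxon_adjustment(c(2, 3, 2.01))
#' @export
two_taxon_adjustment <- function(n) {
  if (!is.numeric(n) || anyNA(n) || any(n < 1))
    .stop_domain("'n' must be a clade size >= 1")
  n[n == 2] <- 2.01
  n
}

# beta = (e^{rt} - 1)/(e^{rt} - epsilon), computed stably at both extremes:
# expm1 keeps precision as r*t -> 0 (beta ~ r*t/(1-epsilon)); the e^{-rt}
# form avoids Inf/Inf overflow for very large r*t.
.beta_param <- function(r, epsilon, t) {
  x <- r * t
  ifelse(x < 350,
         expm1(x) / (expm1(x) + (1 - epsilon)),
         (1 - exp(-x)) / (1 - epsilon * exp(-x)))
}

#' Survival-conditioned geometric size law of the birth-death process
#'
#' Under a constant-rate birth-death process with net rate `r` and extinction
#' fraction `epsilon`, the number of extant descendants of a single lineage
#' that survives to time `t` is geometric with parameter
#' `beta = (e^(r t) - 1)/(e^(r t) - epsilon)`; `alpha = epsilon * beta` is the
#' probability that the lineage is wholly extinct by `t`.
#'
#' @param r Net diversification rate per Myr (>= 0; `r = 0` is handled as the
#'   zero-growth limit, `r < 0` is rejected).
#' @param epsilon Extinction fraction in `[0, 1)`.
#' @param t Time horizon in Myr (>= 0; `beta = alpha = 0` at `t = 0`).
#' @return An object of class `"geometric_law"`: list with (vectorised)
#'   elements `beta`, `alpha`, `r`, `epsilon`, `t`.
#' @examples
#' geometric_law(log(2), 0, 1)   # beta = 0.5
#' @export
geometric_law <- function(r, epsilon, t) {
  .check_rate_nonneg(r)
  .check_epsilon(epsilon)
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    .stop_domain("'t' must be a non-negative time in Myr")
  a <- .recycle(r = r, epsilon = epsilon, t = t)
  beta <- .beta_param(a$r, a$epsilon, a$t)
  structure(list(beta = beta, alpha = a$epsilon * beta,
                 r = a$r, epsilon = a$epsilon, t = a$t),
            class = "geometric_law")
}

#' @export
print.geometric_law <- function(x, ...) {
  cat("Survival-conditioned geometric size law\n")
  print(data.frame(r = x$r, epsilon = x$epsilon, t = x$t,
                   beta = x$beta, alpha = x$alpha))
  invisible(x)
}

.rate_estimate <- function(r_hat, basis, epsilon, n, t) {
  structure(data.frame(r_hat = r_hat, basis = basis, epsilon = epsilon,
                       n = n, t = t, stringsAsFactors = FALSE),
            class = c("rate_estimate", "data.frame"))
}

#' Stem-based method-of-moments net diversification rate
#'
#' Equates the observed clade size `n` to the expected size of a birth-death
#' process of stem age `t` conditioned on survival of the single stem founder,
#' giving `r_hat = ln(n (1 - epsilon) + epsilon) / t`.
#'
#' @param n Extant species count(s), real-valued, >= 1.
#' @param t Stem age(s), Myr, > 0.
#' @param epsilon Extinction fraction(s) in `[0, 1)`.
#' @return A `rate_estimate` data frame with columns `r_hat`, `basis`
#'   (`"stem"`), `epsilon`, `n`, `t`. Arguments are recycled.
#' @seealso [crown_rate()], [expected_stem_diversity()]
#' @examples
#' stem_rate(10, 10, 0)          # ln(10)/10
#' stem_rate(20, 5, 0.9)         # ln(2.9)/5
#' @export
stem_rate <- function(n, t, epsilon = 0) {
  if (!is.numeric(n) || anyNA(n) || any(n < 1))
    .stop_domain("'n' must be a clade size >= 1")
  .check_age(t)
  .check_epsilon(epsilon)
  a <- .recycle(n = n, t = t, epsilon = epsilon)
  r_hat <- log(a$n * (1 - a$epsilon) + a$epsilon) / a$t
  .rate_estimate(r_hat, "stem", a$epsilon, a$n, a$t)
}

#' Crown-based method-of-moments net diversification rate
#'
#' With no extinction the estimator is `(ln n - ln 2)/t`. For
#' `epsilon > 0` the estimator generalises to
#' \deqn{\hat r = t^{-1}\left[\ln\!\big(\tfrac{n}{2}(1-\epsilon^2) + 2\epsilon
#'   + \tfrac{1-\epsilon}{2}\sqrt{n(n\epsilon^2 - 8\epsilon + 2n\epsilon + n)}
#'   \big) - \ln 2\right]}
#' which reduces to the no-extinction form as `epsilon -> 0` and returns
#' exactly zero for `n = 2` at every `epsilon` (the two-taxon degeneracy; see
#' [two_taxon_adjustment()]).
#'
#' @param n Extant species count(s), real-valued, >= 2 (apply
#'   [two_taxon_adjustment()] first if you want a non-zero rate for `n = 2`).
#' @param t Crown age(s), Myr, > 0.
#' @param epsilon Extinction fraction(s) in `[0, 1)`.
#' @return A `rate_estimate` data frame (`basis = "crown"`).
#' @examples
#' crown_rate(8, 10, 0)                        # ln(4)/10
#' crown_rate(2, 5, 0)                         # exactly 0
#' crown_rate(two_taxon_adjustment(2), 10, 0)  # small positive rate
#' @export
crown_rate <- function(n, t, epsilon = 0) {
  if (!is.numeric(n) || anyNA(n))
    .stop_domain("'n' must be numeric")
  if (any(n < 2))
    .stop_domain("'n' must be >= 2 for crown-based rates; for two-taxon clades apply two_taxon_adjustment()")
  .check_age(t)
  .check_epsilon(epsilon)
  a <- .recycle(n = n, t = t, epsilon = epsilon)
  disc <- a$n * (a$n * a$epsilon^2 - 8 * a$epsilon + 2 * a$n * a$epsilon + a$n)
  bracket <- a$n / 2 * (1 - a$epsilon^2) + 2 * a$epsilon +
    (1 - a$epsilon) / 2 * sqrt(pmax(disc, 0))
  r_hat <- (log(bracket) - log(2)) / a$t
  r_hat[a$epsilon == 0] <- (log(a$n) - log(2))[a$epsilon == 0] / a$t[a$epsilon == 0]
  r_hat[a$n == 2] <- 0  # exact: the bracket collapses to 2 algebraically
  .rate_estimate(r_hat, "crown", a$epsilon, a$n, a$t)
}

#' Expected clade size under stem-survival conditioning
#'
#' Mean of the geometric size law: `(e^(r t) - epsilon)/(1 - epsilon)`.
#' Exact functional inverse of [stem_rate()] in `n`.
#'
#' @inheritParams geometric_law
#' @return Numeric vector of expected clade sizes (>= 1).
#' @examples
#' expected_stem_diversity(log(10)/10, 0, 10)  # 10
#' @export
expected_stem_diversity <- function(r, epsilon, t) {
  .check_rate_nonneg(r)
  .check_epsilon(epsilon)
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    .stop_domain("'t' must be a non-negative time in Myr")
  a <- .recycle(r = r, epsilon = epsilon, t = t)
  1 + expm1(a$r * a$t) / (1 - a$epsilon)
}

#' Expected clade size implied by the crown estimator
#'
#' The exact functional inverse of [crown_rate()] in `n`:
#' `2 e^(r t) / (1 - alpha^2)` with `alpha = epsilon * beta`. This is the
#' expected size of a clade founded by two lineages at `t` conditioned on the
#' pair not being entirely extinct, the conditioning implicit in the crown
#' method-of-moments estimator (for the stricter both-founders-survive
#' conditioning used by the tail probabilities, see [prob_geq_crown()]).
#'
#' @inheritParams geometric_law
#' @return Numeric vector of expected clade sizes (>= 2; exactly 2 at `r = 0`).
#' @examples
#' expected_crown_diversity(log(4)/10, 0, 10)  # 8
#' crown_rate(expected_crown_diversity(0.15, 0.5, 10), 10, 0.5)$r_hat  # 0.15
#' @export
expected_crown_diversity <- function(r, epsilon, t) {
  .check_rate_nonneg(r)
  .check_epsilon(epsilon)
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    .stop_domain("'t' must be a non-negative time in Myr")
  a <- .recycle(r = r, epsilon = epsilon, t = t)
  alpha <- a$epsilon * .beta_param(a$r, a$epsilon, a$t)
  2 * exp(a$r * a$t) / ((1 - alpha) * (1 + alpha))
}

#' Tail probability of clade size, stem conditioning
#'
#' `P(N(t) >= n | the stem founder has extant descendants) = beta^(n-1)`
#' under the geometric size law.
#'
#' @param n Integer clade size(s) >= 1 (tail probabilities are defined on
#'   integers; non-integer `n` is a domain error).
#' @inheritParams geometric_law
#' @return Numeric vector of probabilities.
#' @examples
#' prob_geq_stem(4, log(2), 0, 1)  # beta = 0.5 -> 0.125
#' @export
prob_geq_stem <- function(n, r, epsilon, t) {
  if (!is.numeric(n) || anyNA(n) || any(n < 1) || any(n %% 1 != 0))
    .stop_domain("'n' must be an integer clade size >= 1 for tail probabilities")
  law <- geometric_law(r, epsilon, t)
  a <- .recycle(n = n, beta = law$beta)
  a$beta^(a$n - 1)
}

# continuous-in-n crown tail, used both by prob_geq_crown (integer n) and by
# the continuous relaxation in diversity_limits
.crown_tail <- function(n, beta) {
  ifelse(beta == 0, as.numeric(n <= 2),
         beta^(n - 2) * ((n - 1) - (n - 2) * beta))
}

#' Tail probability of clade size, crown conditioning
#'
#' `P(N(t) >= n | both crown lineages leave survivors)`, the tail of the sum
#' of two independent survival-conditioned geometric sizes:
#' `beta^(n-2) * ((n-1) - (n-2) beta)`, with mass function
#' `P(N = k) = (k-1)(1-beta)^2 beta^(k-2)` for `k >= 2`.
#'
#' @param n Integer clade size(s) >= 2.
#' @inheritParams geometric_law
#' @return Numeric vector of probabilities (1 at `n = 2`).
#' @examples
#' prob_geq_crown(4, log(2), 0, 1)  # beta = 0.5 -> 0.5
#' @export
prob_geq_crown <- function(n, r, epsilon, t) {
  if (!is.numeric(n) || anyNA(n) || any(n < 2) || any(n %% 1 != 0))
    .stop_domain("'n' must be an integer clade size >= 2 for crown tail probabilities")
  law <- geometric_law(r, epsilon, t)
  a <- .recycle(n = n, beta = law$beta)
  .crown_tail(a$n, a$beta)
}

# invert tail(n) = q continuously in n for one beta; crown basis needs
# root-finding (monotone in n), stem basis has a closed form
.bound_one <- function(beta, q, basis) {
  if (basis == "stem") {
    if (beta == 0) return(1)
    return(1 + log(q) / log(beta))
  }
  if (beta == 0) return(2)
  f <- function(n) (n - 2) * log(beta) + log((n - 1) - (n - 2) * beta) - log(q)
  if (f(2) <= 0) return(2)
  hi <- 4
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 2
  stats::uniroot(f, c(2, hi), tol = 1e-10)$root
}

#' Expected-diversity confidence envelope through time
#'
#' For each time on a grid, solves the basis-appropriate clade-size tail for
#' the continuous relaxation of the lower and upper confidence bounds on
#' clade size: `lower` solves `P(N >= n) = (1 + conf)/2` and `upper` solves
#' `P(N >= n) = (1 - conf)/2`. The bounds are real-valued by construction
#' (the reference behaviour solves the tail expression continuously); the
#' clade-size law itself is of course integer-valued.
#'
#' @param r_ref Reference net diversification rate per Myr (>= 0).
#' @param epsilon Extinction fraction in `[0, 1)` (scalar).
#' @param times Increasing grid of non-negative times, Myr.
#' @param conf Confidence level in (0, 1); default 0.95.
#' @param basis `"crown"` (both founders survive) or `"stem"` (one founder
#'   survives).
#' @return A `diversity_envelope`: data frame with columns `time`, `lower`,
#'   `upper` and attributes `conf`, `epsilon`, `r_ref`, `basis`.
#' @examples
#' env <- diversity_limits(log(2), 0, times = 1, basis = "stem")
#' env$lower  # 1 + log(0.975)/log(0.5)
#' @export
diversity_limits <- function(r_ref, epsilon, times, conf = 0.95,
                             basis = c("crown", "stem")) {
  basis <- match.arg(basis)
  if (!is.numeric(conf) || length(conf) != 1L || is.na(conf) ||
      conf <= 0 || conf >= 1)
    .stop_domain("'conf' must be a confidence level strictly inside (0, 1)")
  if (!is.numeric(times) || length(times) == 0L || anyNA(times) ||
      any(times < 0) || is.unsorted(times))
    .stop_domain("'times' must be a non-empty increasing grid of non-negative ages")
  .check_rate_nonneg(r_ref)
  .check_epsilon(epsilon)
  if (length(epsilon) != 1L || length(r_ref) != 1L)
    .stop_domain("'r_ref' and 'epsilon' must be scalars")
  beta <- .beta_param(r_ref, epsilon, times)
  lower <- vapply(beta, .bound_one, numeric(1), q = (1 + conf) / 2, basis = basis)
  upper <- vapply(beta, .bound_one, numeric(1), q = (1 - conf) / 2, basis = basis)
  structure(data.frame(time = times, lower = lower, upper = upper),
            conf = conf, epsilon = epsilon, r_ref = r_ref, basis = basis,
            class = c("diversity_envelope", "data.frame"))
}

#' @export
print.diversity_envelope <- function(x, ...) {
  cat(sprintf(
    "Expected-diversity envelope (%s basis): conf = %g, r_ref = %.6g, epsilon = %g, %d time points\n",
    attr(x, "basis"), attr(x, "conf"), attr(x, "r_ref"), attr(x, "epsilon"), nrow(x)))
  NextMethod()
}
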