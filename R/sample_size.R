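# Two-proportion sample size and power with unequal allocation, for
# detecting a binary risk factor's relative risk in a cohort where the
# factor-negative outcome risk r0 is small. The exposed-group risk is
# p1 = r0 * rr, the unexposed p2 = r0, and the allocation ratio is
# k = n_unexposed / n_exposed = (1 - f) / f where f is the fraction of the
# population carrying the factor.

#' Specify a cohort design for power and sample-size calculations
#'
#' @param r0 Baseline outcome risk in factor-negative individuals, (0, 1).
#' @param rr Relative risk to detect (> 0; must differ from 1 for sizing).
#' @param f Fraction of the population with the risk factor, in (0, 1).
#' @param alpha Two-sided significance level; default 0.05.
#' @param power Target power; default 0.90.
#' @param variant Sizing formula: `"pooled"` (default; pooled-variance
#'   normal approximation, no continuity correction), `"unpooled"` (both
#'   variance terms unpooled) or `"pooled_cc"` (pooled with the standard
#'   continuity correction).
#' @return A validated `design_spec` list.
#' @examples
#' design_spec(r0 = 0.01, rr = 2, f = 0.5)
#' @export
design_spec <- function(r0, rr, f, alpha = 0.05, power = 0.90,
                        variant = c("pooled", "unpooled", "pooled_cc")) {
  variant <- match.arg(variant)
  check_prob(r0, "r0", open_lo = TRUE, open_hi = TRUE)
  check_number(rr, "rr")
  if (rr <= 0) stop_domain("rr must be > 0")
  if (r0 * rr > 1) {
    stop_domain("r0 * rr = %g exceeds 1: exposed-group risk is not a probability",
                r0 * rr)
  }
  check_prob(f, "f", open_lo = TRUE, open_hi = TRUE)
  check_prob(alpha, "alpha", open_lo = TRUE, open_hi = TRUE)
  check_prob(power, "power", open_lo = TRUE, open_hi = TRUE)
  structure(list(r0 = r0, rr = rr, f = f, alpha = alpha, power = power,
                 variant = variant),
            class = "design_spec")
}

as_design <- function(design) {
  if (inherits(design, "design_spec")) return(design)
  stop_domain("expected a design_spec object; see design_spec()")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Cohort design:",
      sprintf("r0 = %s, RR = %g, f = %s", format_prob(x$r0), x$rr,
              format_prob(x$f)), "\n")
  cat(sprintf("  alpha = %g (two-sided), power = %g, variant = %s\n",
              x$alpha, x$power, x$variant))
  invisible(x)
}

# Exposed-group size (continuous) under each formula variant.
n_exposed_exact <- function(design) {
  p1 <- design$r0 * design$rr
  p2 <- design$r0
  k <- (1 - design$f) / design$f
  delta <- abs(p1 - p2)
  za <- stats::qnorm(1 - design$alpha / 2)
  zb <- stats::qnorm(design$power)
  v_unpooled <- p1 * (1 - p1) + p2 * (1 - p2) / k
  pbar <- (p1 + k * p2) / (1 + k)
  n1 <- switch(design$variant,
    pooled = (za * sqrt((1 + 1 / k) * pbar * (1 - pbar)) +
                zb * sqrt(v_unpooled))^2 / delta^2,
    unpooled = (za + zb)^2 * v_unpooled / delta^2,
    pooled_cc = {
      n1p <- (za * sqrt((1 + 1 / k) * pbar * (1 - pbar)) +
                zb * sqrt(v_unpooled))^2 / delta^2
      # Fleiss continuity correction for unequal groups
      n1p / 4 * (1 + sqrt(1 + 2 * (k + 1) / (k * n1p * delta)))^2
    }
  )
  n1
}

#' Total sample size needed to detect a relative risk
#'
#' Two-proportion normal-approximation sample size comparing exposed risk
#' `p1 = r0 * rr` against unexposed risk `p2 = r0`, with allocation ratio
#' `k = (1 - f) / f` unexposed per exposed subject. The default pooled
#' variant sizes the exposed group as
#' \deqn{n_1 = \frac{\left[z_{1-\alpha/2}\sqrt{(1+1/k)\,\bar p(1-\bar p)}
#'   + z_{1-\beta}\sqrt{p_1(1-p_1) + p_2(1-p_2)/k}\right]^2}
#'   {(p_1-p_2)^2},}
#' with \eqn{\bar p = f p_1 + (1-f) p_2}, rounds it up, and derives the
#' unexposed group from the allocation ratio (also rounded up).
#'
#' At `r0` of 1\%, detecting a relative risk of 2 with 90\% power at the
#' two-sided 5\% level needs a total cohort above 5,000 when half the
#' population carries the factor, and above 14,000 when 10\% do.
#'
#' @param design A [design_spec()] with `rr != 1`.
#' @return A `sample_size_result` list: `n_exposed`, `n_unexposed`,
#'   `n_total`, `expected_events` (`n_exposed*r0*rr + n_unexposed*r0`),
#'   `variant` and the embedded `inputs`.
#' @examples
#' required_total_n(design_spec(r0 = 0.01, rr = 2, f = 0.5))
#' @export
required_total_n <- function(design) {
  design <- as_design(design)
  if (design$rr == 1) {
    stop_domain("rr = 1: a null effect needs an infinite sample size")
  }
  k <- (1 - design$f) / design$f
  n1 <- ceiling(n_exposed_exact(design))
  n2 <- ceiling(k * n1)
  structure(
    list(n_exposed = n1, n_unexposed = n2, n_total = n1 + n2,
         expected_events = n1 * design$r0 * design$rr + n2 * design$r0,
         variant = design$variant, inputs = design),
    class = "sample_size_result"
  )
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat("Required sample size (", x$variant, " variant)\n", sep = "")
  cat(sprintf("  exposed: %d   unexposed: %d   total: %d\n",
              x$n_exposed, x$n_unexposed, x$n_total))
  cat(sprintf("  expected outcome events: %.1f\n", x$expected_events))
  print(x$inputs)
  invisible(x)
}

#' Power achieved by a given total cohort size
#'
#' Power of the two-sided level-`alpha` pooled two-proportion z test (the
#' test [required_total_n()] sizes for, and the one [empirical_power()]
#' simulates) when `n_total` subjects are split `f` exposed / `1 - f`
#' unexposed. Both rejection tails are counted, so at `rr` near 1 the value
#' collapses to `alpha` rather than to `alpha / 2`.
#'
#' @param design A [design_spec()].
#' @param n_total Total cohort size (>= 2); the group split is treated
#'   continuously.
#' @return The approximate power, in (0, 1).
#' @examples
#' d <- design_spec(r0 = 0.01, rr = 2, f = 0.5)
#' achieved_power(d, required_total_n(d)$n_total) # >= 0.90
#' @export
achieved_power <- function(design, n_total) {
  design <- as_design(design)
  check_number(n_total, "n_total")
  if (any(n_total < 2)) stop_domain("n_total must be >= 2")
  p1 <- design$r0 * design$rr
  p2 <- design$r0
  n1 <- design$f * n_total
  n2 <- (1 - design$f) * n_total
  delta <- p1 - p2
  pbar <- design$f * p1 + (1 - design$f) * p2
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))     # null (pooled) SE
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)   # alternative SE
  za <- stats::qnorm(1 - design$alpha / 2)
  stats::pnorm((delta - za * se0) / se1) +
    stats::pnorm((-delta - za * se0) / se1)
}

#' Smallest detectable relative risk for a fixed cohort size
#'
#' Inverts [achieved_power()] by bisection over `rr` in
#' `(1 + 1e-6, cap]`: the smallest relative risk above 1 whose power at
#' `n_total` reaches the target. Useful for reading a sample-size curve
#' backwards ("what effect could this cohort find?").
#'
#' @inheritParams design_spec
#' @param n_total Total cohort size available.
#' @param cap Upper bracket for the search; relative risks beyond 100 are
#'   outside any plausible planning range. Default 100.
#' @param tol Relative bisection tolerance; default 1e-6.
#' @return A list with `rr` (NA if not achievable), `achievable`,
#'   `power_at_rr` and the inputs.
#' @examples
#' min_detectable_rr(r0 = 0.01, f = 0.1, n_total = 30000)
#' @export
min_detectable_rr <- function(r0, f, n_total, alpha = 0.05, power = 0.90,
                              cap = 100, tol = 1e-6) {
  check_count(n_total, "n_total", min = 2)
  hi <- min(cap, (1 - 1e-12) / r0)  # keep r0 * rr <= 1
  pow_at <- function(rr) {
    achieved_power(design_spec(r0, rr, f, alpha, power), n_total)
  }
  if (pow_at(hi) < power) {
    return(list(rr = NA_real_, achievable = FALSE, power_at_rr = pow_at(hi),
                r0 = r0, f = f, n_total = n_total, alpha = alpha,
                power = power, cap = cap))
  }
  lo <- 1 + 1e-6
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (pow_at(mid) >= power) hi <- mid else lo <- mid
  }
  list(rr = hi, achievable = TRUE, power_at_rr = pow_at(hi),
       r0 = r0, f = f, n_total = n_total, alpha = alpha, power = power,
       cap = cap)
}

#' Events-per-variable feasibility check
#'
#' The rule of thumb for prediction-model development: at least `epv`
#' (default 10) outcome events per candidate predictor, to limit
#' overfitting. Given an expected event count this caps the number of
#' predictors that can responsibly be examined; with a candidate count
#' supplied, a feasibility verdict is returned. A dataset with 222 events
#' supports at most 22 predictors — far short of, say, 2,978 candidates.
#'
#' @param n_events Number of outcome events (non-negative integer).
#' @param epv Required events per variable; default 10.
#' @param n_candidates Optional number of candidate predictors to judge.
#' @return An `epv_check` list: `max_predictors = floor(n_events / epv)`,
#'   plus `feasible` (logical) when `n_candidates` is given.
#' @examples
#' epv_limit(222, n_candidates = 2978) # max 22, infeasible
#' @export
epv_limit <- function(n_events, epv = 10, n_candidates = NULL) {
  check_count(n_events, "n_events", min = 0)
  check_count(epv, "epv", min = 1)
  out <- list(n_events = n_events, epv = epv,
              max_predictors = floor(n_events / epv),
              n_candidates = n_candidates, feasible = NA)
  if (!is.null(n_candidates)) {
    check_count(n_candidates, "n_candidates", min = 0)
    out$feasible <- n_candidates <= out$max_predictors
  }
  structure(out, class = "epv_check")
}

#' @export
print.epv_check <- function(x, ...) {
  cat(sprintf("Events-per-variable check: %d events / %d per variable -> at most %d predictors\n",
              x$n_events, x$epv, x$max_predictors))
  if (!is.null(x$n_candidates)) {
    cat(sprintf("  %d candidate predictors: %s\n", x$n_candidates,
                if (x$feasible) "feasible" else "INFEASIBLE"))
  }
  invisible(x)
}
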