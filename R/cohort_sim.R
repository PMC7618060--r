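# Monte-Carlo cohorts with a binary exposure and a binary outcome: the
# brute-force counterpart of every closed form in the package. A cohort of
# size n is sampled from the population (exposure indicator Bernoulli(f)),
# exposed subjects experience the outcome with risk r0 * rr and unexposed
# with r0. All draws come from R's seeded RNG stream, so results are
# bit-for-bit reproducible given the seed.

# Vectorized replicate draws: returns a data.frame of 2x2 counts, one row
# per replicate (a = exposed w/ outcome, b = exposed w/o, c = unexposed w/,
# d = unexposed w/o).
draw_cohorts <- function(design, n_total, replicates, fixed_margins = FALSE) {
  p1 <- design$r0 * design$rr
  p2 <- design$r0
  if (n_total <= .Machine$integer.max) n_total <- as.integer(n_total)
  n_exp <- if (fixed_margins) {
    rep.int(as.integer(round(design$f * n_total)), replicates)
  } else {
    stats::rbinom(replicates, n_total, design$f)
  }
  n_unexp <- n_total - n_exp
  a <- stats::rbinom(replicates, n_exp, p1)
  c_ <- stats::rbinom(replicates, n_unexp, p2)
  data.frame(a = a, b = n_exp - a, c = c_, d = n_unexp - c_)
}

#' Simulate one binary-exposure / binary-outcome cohort
#'
#' Draws the exposed-subject count binomially with probability `f` from
#' `n_total`, then outcome counts binomially with risks `r0 * rr` (exposed)
#' and `r0` (unexposed). Deterministic given `seed`.
#'
#' @param design A [design_spec()].
#' @param n_total Cohort size (>= 1).
#' @param seed Integer seed.
#' @param fixed_margins If `TRUE`, fix the exposed count at
#'   `round(f * n_total)` (the conditional design) instead of sampling it.
#' @return A `cohort_counts` list with the four 2x2 cells `a` (exposed,
#'   outcome), `b` (exposed, no outcome), `c` (unexposed, outcome), `d`
#'   (unexposed, no outcome).
#' @examples
#' simulate_cohort(design_spec(0.01, 2, 0.5), n_total = 10000, seed = 1)
#' @export
simulate_cohort <- function(design, n_total, seed, fixed_margins = FALSE) {
  design <- as_design(design)
  check_count(n_total, "n_total", min = 1)
  set.seed(seed)
  counts <- draw_cohorts(design, n_total, 1L, fixed_margins)
  structure(as.list(counts[1L, ]),
            n_total = n_total, seed = seed, class = "cohort_counts")
}

#' @export
print.cohort_counts <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("outcome", "no outcome")))
  print(m)
  invisible(x)
}

# Pooled two-proportion chi-square rejection (no continuity correction),
# the test the sizing formula targets. Replicates with a degenerate margin
# (empty group or no variation in outcome) cannot reject.
reject_pooled <- function(a, n_exp, c_, n_unexp, alpha) {
  n <- n_exp + n_unexp
  pbar <- (a + c_) / n
  ok <- n_exp > 0 & n_unexp > 0 & pbar > 0 & pbar < 1
  z2 <- rep(0, length(a))
  z2[ok] <- (a[ok] / n_exp[ok] - c_[ok] / n_unexp[ok])^2 /
    (pbar[ok] * (1 - pbar[ok]) * (1 / n_exp[ok] + 1 / n_unexp[ok]))
  list(reject = ok & z2 > stats::qchisq(1 - alpha, df = 1),
       degenerate = !ok)
}

new_sim_result <- function(estimate, mc_se, replicates, seed, design,
                           n_total, metric) {
  ci <- estimate + c(-1, 1) * stats::qnorm(0.975) * mc_se
  structure(list(estimate = estimate, mc_se = mc_se, ci95 = ci,
                 replicates = replicates, seed = seed, design = design,
                 n_total = n_total, metric = metric),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo %s: %.4f (MC SE %.4g, 95%% CI %.4f to %.4f)\n",
              x$metric, x$estimate, x$mc_se, x$ci95[1], x$ci95[2]))
  cat(sprintf("  %d replicates of n = %d, seed %d\n",
              x$replicates, x$n_total, x$seed))
  invisible(x)
}

#' Empirical power of the two-proportion chi-square test
#'
#' Simulates `replicates` cohorts under the design and reports the
#' fraction in which the two-sided pooled chi-square test (no continuity
#' correction — the exact test [required_total_n()] sizes for) rejects at
#' level `alpha`. Replicates with a degenerate margin count as
#' non-rejections and are reported via a message. Under `rr = 1` the
#' estimate is the empirical type-I error and should sit near `alpha`.
#'
#' @inheritParams simulate_cohort
#' @param replicates Number of Monte-Carlo replicates (>= 100).
#' @return A `sim_result` with the rejection fraction, its binomial
#'   Monte-Carlo standard error and a 95\% CI.
#' @examples
#' d <- design_spec(0.01, 2, 0.5)
#' empirical_power(d, n_total = 6206, replicates = 2000, seed = 42)
#' @export
empirical_power <- function(design, n_total, replicates, seed,
                            fixed_margins = FALSE) {
  design <- as_design(design)
  check_count(n_total, "n_total", min = 2)
  check_count(replicates, "replicates", min = 100)
  set.seed(seed)
  cc <- draw_cohorts(design, n_total, replicates, fixed_margins)
  res <- reject_pooled(cc$a, cc$a + cc$b, cc$c, cc$c + cc$d, design$alpha)
  n_degen <- sum(res$degenerate)
  if (n_degen > 0) {
    message(sprintf("%d of %d replicates had a degenerate margin (counted as non-rejections)",
                    n_degen, replicates))
  }
  est <- mean(res$reject)
  new_sim_result(est, sqrt(est * (1 - est) / replicates), replicates, seed,
                 design, n_total, metric = "power")
}

#' Empirical predictive metrics of the exposure marker
#'
#' Simulates cohorts and estimates sensitivity, specificity, PPV, NPV,
#' relative risk and the positive likelihood ratio of the "has the risk
#' factor" marker, pooling the 2x2 counts across replicates before forming
#' any ratio (per-replicate ratios are undefined or wildly skewed when the
#' outcome is rare). Each estimate should agree with the corresponding
#' closed form from [scenario_from_exposure()] to within Monte-Carlo error.
#'
#' @inheritParams empirical_power
#' @return An `empirical_predictive` object: a named list of `sim_result`s
#'   (`sensitivity`, `specificity`, `ppv`, `npv`, `rr`, `lr_pos`), plus the
#'   pooled 2x2 `counts`. A metric whose pooled denominator is zero is
#'   reported as `NA` with a message.
#' @examples
#' d <- design_spec(0.01, 2, 0.5)
#' emp <- empirical_predictive(d, n_total = 1e5, replicates = 50, seed = 7)
#' emp$ppv$estimate # close to scenario_from_exposure(0.01, 2, 0.5)$ppv
#' @export
empirical_predictive <- function(design, n_total, replicates, seed,
                                 fixed_margins = FALSE) {
  design <- as_design(design)
  check_count(n_total, "n_total", min = 1)
  check_count(replicates, "replicates", min = 100)
  set.seed(seed)
  cc <- draw_cohorts(design, n_total, replicates, fixed_margins)
  A <- sum(cc$a); B <- sum(cc$b); C <- sum(cc$c); D <- sum(cc$d)

  prop <- function(num, den, metric) {
    if (den == 0) {
      message(sprintf("pooled denominator for %s is zero; reported as NA",
                      metric))
      return(new_sim_result(NA_real_, NA_real_, replicates, seed, design,
                            n_total, metric))
    }
    est <- num / den
    new_sim_result(est, sqrt(est * (1 - est) / den), replicates, seed,
                   design, n_total, metric)
  }
  # ratio estimates: delta-method SE on the log scale, CI back-transformed
  log_ratio <- function(est, var_log, metric) {
    r <- new_sim_result(est, est * sqrt(var_log), replicates, seed, design,
                        n_total, metric)
    r$ci95 <- est * exp(c(-1, 1) * stats::qnorm(0.975) * sqrt(var_log))
    r
  }

  out <- list(
    sensitivity = prop(A, A + C, "sensitivity"),
    specificity = prop(D, B + D, "specificity"),
    ppv = prop(A, A + B, "ppv"),
    npv = prop(D, C + D, "npv")
  )
  out$rr <- if (min(A, C) == 0 || A + B == 0 || C + D == 0) {
    message("pooled 2x2 cannot support an RR estimate; reported as NA")
    new_sim_result(NA_real_, NA_real_, replicates, seed, design, n_total,
                   "rr")
  } else {
    log_ratio((A / (A + B)) / (C / (C + D)),
              1 / A - 1 / (A + B) + 1 / C - 1 / (C + D), "rr")
  }
  out$lr_pos <- if (min(A, B) == 0 || A + C == 0 || B + D == 0) {
    message("pooled 2x2 cannot support an LR+ estimate; reported as NA")
    new_sim_result(NA_real_, NA_real_, replicates, seed, design, n_total,
                   "lr_pos")
  } else {
    log_ratio((A / (A + C)) / (B / (B + D)),
              1 / A - 1 / (A + C) + 1 / B - 1 / (B + D), "lr_pos")
  }
  out$counts <- c(a = A, b = B, c = C, d = D)
  class(out) <- "empirical_predictive"
  out
}

#' @export
print.empirical_predictive <- function(x, ...) {
  cat("Pooled empirical predictive metrics\n")
  for (m in c("sensitivity", "specificity", "ppv", "npv", "rr", "lr_pos")) {
    cat(sprintf("  %-11s %s\n", m,
                if (is.na(x[[m]]$estimate)) "NA" else
                  sprintf("%.5g (MC SE %.3g)", x[[m]]$estimate,
                          x[[m]]$mc_se)))
  }
  invisible(x)
}
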