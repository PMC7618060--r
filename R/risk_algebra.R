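# Closed-form algebra for a dichotomized risk marker against a binary
# outcome. Everything here follows from the four-cell joint distribution of
# (marker, outcome); the central identity is
#
#   RR = (PPV - p S) / (p (1 - S))
#
# where p is outcome prevalence, S sensitivity and PPV the positive
# predictive value. The marker-positive fraction is f = S p / PPV and the
# baseline (marker-negative) risk is r0 = p (1 - S) / (1 - f).

#' Relative risk implied by prevalence, sensitivity and PPV
#'
#' For a binary marker with sensitivity `s` and positive predictive value
#' `ppv` against an outcome of prevalence `p`, the relative risk of the
#' outcome in marker-positive versus marker-negative individuals is
#' determined exactly:
#' \deqn{RR = \frac{PPV - pS}{p(1 - S)}.}
#'
#' As `s` approaches 0 the relative risk approaches its floor `ppv / p`;
#' this is why, at 1\% prevalence, a PPV of 50\% cannot be reached by any
#' marker with relative risk below 50.
#'
#' @param p Outcome prevalence, in (0, 1).
#' @param s Sensitivity of the marker, in \[0, 1).
#' @param ppv Positive predictive value, with `p * s < ppv <= 1`.
#' @return The relative risk (dimensionless, > 0).
#' @examples
#' rr_from_predictive(p = 0.01, s = 0.8, ppv = 0.50) # 246
#' rr_from_predictive(p = 0.01, s = 0, ppv = 0.50)   # the floor, 50
#' @seealso [ppv_from_rr()] for the inverse, [scenario_from_predictive()]
#'   for the full joint distribution.
#' @export
rr_from_predictive <- function(p, s, ppv) {
  check_prob(p, "p", open_lo = TRUE, open_hi = TRUE)
  check_prob(s, "s", open_hi = TRUE)
  check_prob(ppv, "ppv", open_lo = TRUE)
  if (any(ppv <= p * s)) {
    stop_domain(paste0("ppv must exceed p*s = %g: otherwise the ",
                       "marker-positive fraction f = s*p/ppv would be >= 1"),
                (p * s)[ppv <= p * s][1])
  }
  (ppv - p * s) / (p * (1 - s))
}

#' PPV implied by prevalence, sensitivity and relative risk
#'
#' Algebraic inverse of [rr_from_predictive()]:
#' `ppv = rr * p * (1 - s) + p * s`.
#'
#' @inheritParams rr_from_predictive
#' @param rr Relative risk, marker-positive vs marker-negative (>= 0).
#' @return The positive predictive value, in (0, 1\].
#' @examples
#' ppv_from_rr(p = 0.01, s = 0, rr = 50)    # 0.50
#' ppv_from_rr(p = 0.30, s = 0.7, rr = 1)   # the prevalence: null effect
#' @export
ppv_from_rr <- function(p, s, rr) {
  check_prob(p, "p", open_lo = TRUE, open_hi = TRUE)
  check_prob(s, "s")
  check_number(rr, "rr")
  if (any(rr < 0)) stop_domain("rr must be >= 0")
  ppv <- rr * p * (1 - s) + p * s
  if (any(ppv > 1 + .lp_abs_tol)) {
    stop_domain("implied ppv = %g exceeds 1: no scenario with prevalence %g supports rr = %g at sensitivity %g",
                max(ppv), p[which.max(ppv)][1], rr[which.max(ppv)][1],
                s[which.max(ppv)][1])
  }
  pmin(ppv, 1)
}

#' Positive likelihood ratio
#'
#' `LR+ = sensitivity / (1 - specificity)`: the factor by which a positive
#' marker result multiplies the pre-test odds of the outcome.
#'
#' @param s Sensitivity, in \[0, 1\].
#' @param spec Specificity, in \[0, 1). A specificity of exactly 1 is
#'   rejected rather than returning an infinite ratio.
#' @return The positive likelihood ratio (>= 0).
#' @examples
#' lr_positive(s = 0.8, spec = 0.9) # 8
#' @export
lr_positive <- function(s, spec) {
  check_prob(s, "s")
  check_prob(spec, "spec", open_hi = TRUE)
  s / (1 - spec)
}

#' Likelihood ratio needed for a given probability step-up
#'
#' The positive likelihood ratio a prediction tool must achieve to move a
#' pre-test probability (e.g. the population prevalence) to a target
#' post-test probability, via the odds form of Bayes' theorem:
#' \deqn{LR = \frac{post/(1-post)}{pre/(1-pre)}.}
#'
#' At 1\% prevalence, reaching post-test probabilities of 10\%, 25\% and
#' 50\% requires likelihood ratios of 11, 33 and 99 respectively —
#' magnitudes rarely observed for real prediction tools.
#'
#' @param pre_p Pre-test probability, in (0, 1).
#' @param post_p Target post-test probability, in (0, 1).
#' @return The required positive likelihood ratio.
#' @examples
#' required_lr(0.01, 0.10) # 11
#' required_lr(0.01, 0.50) # 99
#' @export
required_lr <- function(pre_p, post_p) {
  check_prob(pre_p, "pre_p", open_lo = TRUE, open_hi = TRUE)
  check_prob(post_p, "post_p", open_lo = TRUE, open_hi = TRUE)
  (post_p / (1 - post_p)) / (pre_p / (1 - pre_p))
}

#' Post-test probability after applying a likelihood ratio
#'
#' Inverse of [required_lr()]: updates pre-test odds by the likelihood
#' ratio and converts back to a probability.
#'
#' @inheritParams required_lr
#' @param lr Positive likelihood ratio (>= 0).
#' @return The post-test probability.
#' @examples
#' post_test_probability(0.01, 11) # 0.10
#' @export
post_test_probability <- function(pre_p, lr) {
  check_prob(pre_p, "pre_p", open_lo = TRUE, open_hi = TRUE)
  check_number(lr, "lr")
  if (any(lr < 0)) stop_domain("lr must be >= 0")
  odds <- lr * pre_p / (1 - pre_p)
  odds / (1 + odds)
}

# ---------------------------------------------------------------------------
# PredictiveScenario: a fully consistent joint distribution of binary
# marker x binary outcome.

new_predictive_scenario <- function(p, sensitivity, specificity, ppv, npv,
                                    f, rr, lr_pos) {
  structure(
    list(p = p, sensitivity = sensitivity, specificity = specificity,
         ppv = ppv, npv = npv, f = f, rr = rr, lr_pos = lr_pos),
    class = "predictive_scenario"
  )
}

#' Validate the internal consistency of a predictive scenario
#'
#' Re-derives every redundant field of a [scenario_from_predictive()] /
#' [scenario_from_exposure()] object from the minimal parameterization and
#' rejects the object, naming the violated constraint, if any identity
#' fails. The identities only hold for internally consistent 2x2 joint
#' distributions, so validation is strict.
#'
#' @param x A `predictive_scenario` object.
#' @return `x`, invisibly, if valid; otherwise an error naming the
#'   constraint that failed.
#' @export
validate_predictive_scenario <- function(x) {
  stopifnot(inherits(x, "predictive_scenario"))
  with(x, {
    for (nm in c("p", "sensitivity", "specificity", "ppv", "npv", "f")) {
      check_prob(x[[nm]], nm)
    }
    check_prob(f, "f", open_lo = TRUE, open_hi = TRUE)
    checks <- list(
      "f = sensitivity*p/ppv" = lp_near(f, sensitivity * p / ppv),
      "p = f*ppv + (1-f)*(1-npv)" =
        lp_near(p, f * ppv + (1 - f) * (1 - npv)),
      "specificity = 1 - f*(1-ppv)/(1-p)" =
        lp_near(specificity, 1 - f * (1 - ppv) / (1 - p)),
      "lr_pos = sensitivity/(1-specificity)" =
        lp_near(lr_pos, sensitivity / (1 - specificity)),
      "ppv/(1-ppv) = lr_pos * p/(1-p)" =
        lp_near(ppv / (1 - ppv), lr_pos * p / (1 - p)),
      "rr = ppv/r0 with r0 = p(1-sensitivity)/(1-f)" =
        lp_near(rr, ppv * (1 - f) / (p * (1 - sensitivity)))
    )
    bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
    if (length(bad)) {
      stop_domain("inconsistent scenario: constraint '%s' violated", bad[1])
    }
  })
  invisible(x)
}

#' Full marker/outcome scenario from prevalence, sensitivity and PPV
#'
#' Completes the joint 2x2 distribution behind the relative-risk identity:
#' given prevalence `p`, sensitivity `s` and positive predictive value
#' `ppv`, derives the marker-positive fraction `f = s*p/ppv`, the baseline
#' risk `r0 = p(1-s)/(1-f)`, specificity, NPV, the positive likelihood
#' ratio and the relative risk, and checks all of them for mutual
#' consistency before returning.
#'
#' @inheritParams rr_from_predictive
#' @return A `predictive_scenario` object: a list with fields `p`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `f`, `rr`, `lr_pos`.
#' @examples
#' sc <- scenario_from_predictive(p = 0.01, s = 0.8, ppv = 0.10)
#' sc$f  # 0.08
#' sc$rr # 46
#' @export
scenario_from_predictive <- function(p, s, ppv) {
  check_prob(p, "p", open_lo = TRUE, open_hi = TRUE)
  check_prob(s, "s", open_lo = TRUE, open_hi = TRUE)
  check_prob(ppv, "ppv", open_lo = TRUE, open_hi = TRUE)
  if (ppv <= p * s) {
    stop_domain(paste0("ppv must exceed p*s = %g: otherwise the ",
                       "marker-positive fraction f = s*p/ppv would be >= 1"),
                p * s)
  }
  f <- s * p / ppv
  r0 <- p * (1 - s) / (1 - f)
  spec <- 1 - f * (1 - ppv) / (1 - p)
  if (spec < 0) {
    stop_domain("implied specificity is negative: marker positives (f = %g) exceed the non-diseased population",
                f)
  }
  sc <- new_predictive_scenario(
    p = p, sensitivity = s, specificity = spec, ppv = ppv, npv = 1 - r0,
    f = f, rr = ppv / r0, lr_pos = s / (1 - spec)
  )
  validate_predictive_scenario(sc)
  sc
}

#' Full marker/outcome scenario from the exposure-side parameterization
#'
#' The cohort-design view of the same 2x2 distribution: a risk factor
#' present in a fraction `f` of the population multiplies a baseline
#' outcome risk `r0` by a relative risk `rr`. The implied prevalence is
#' `p = f*r0*rr + (1-f)*r0`, the PPV of "has the risk factor" is `r0*rr`,
#' and its sensitivity is `f*ppv/p`. Feeding the resulting `(p, s, ppv)`
#' back through [rr_from_predictive()] recovers `rr`, which is the
#' executable form of the identity's derivation.
#'
#' @param r0 Baseline outcome risk in factor-negative individuals, (0, 1).
#' @param rr Relative risk of the factor (>= 0, with `r0 * rr <= 1`).
#' @param f Fraction of the population carrying the factor, in (0, 1).
#' @return A `predictive_scenario` object.
#' @examples
#' sc <- scenario_from_exposure(r0 = 0.01, rr = 2, f = 0.5)
#' sc$p           # 0.015
#' sc$ppv         # 0.02
#' sc$sensitivity # 2/3
#' @export
scenario_from_exposure <- function(r0, rr, f) {
  check_prob(r0, "r0", open_lo = TRUE, open_hi = TRUE)
  check_number(rr, "rr")
  if (rr <= 0) stop_domain("rr must be > 0 for a non-degenerate scenario")
  check_prob(f, "f", open_lo = TRUE, open_hi = TRUE)
  p1 <- r0 * rr
  if (p1 > 1) {
    stop_domain("r0 * rr = %g exceeds 1: exposed-group risk is not a probability", p1)
  }
  if (p1 == 1) {
    stop_domain("r0 * rr = 1: PPV of 1 implies infinite likelihood ratio; use rr slightly smaller")
  }
  p <- f * p1 + (1 - f) * r0
  s <- f * p1 / p
  spec <- 1 - f * (1 - p1) / (1 - p)
  sc <- new_predictive_scenario(
    p = p, sensitivity = s, specificity = spec, ppv = p1, npv = 1 - r0,
    f = f, rr = rr, lr_pos = s / (1 - spec)
  )
  validate_predictive_scenario(sc)
  sc
}

#' @export
print.predictive_scenario <- function(x, ...) {
  cat("Predictive scenario (binary marker x binary outcome)\n")
  cat("  prevalence p :", format_prob(x$p), "\n")
  cat("  sensitivity  :", format_prob(x$sensitivity), "\n")
  cat("  specificity  :", format_prob(x$specificity), "\n")
  cat("  PPV          :", format_prob(x$ppv), "\n")
  cat("  NPV          :", format_prob(x$npv), "\n")
  cat("  marker+ f    :", format_prob(x$f), "\n")
  cat("  relative risk:", signif(x$rr, 6), "\n")
  cat("  LR+          :", signif(x$lr_pos, 6), "\n")
  invisible(x)
}

#' @export
as.data.frame.predictive_scenario <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Read or write a scenario as a flat record
#'
#' Scenarios are exchanged as flat key-value records — a single JSON object
#' or a one-row CSV — with field names `p`, `sensitivity`, `specificity`,
#' `ppv`, `npv`, `f`, `rr`, `lr_pos`. Reading re-validates all consistency
#' identities, so a hand-edited, internally inconsistent record is
#' rejected.
#'
#' @param x A `predictive_scenario`.
#' @param path File path; format chosen by extension (`.json` or `.csv`).
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a validated `predictive_scenario`.
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "predictive_scenario"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  rec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    as.list(utils::read.csv(path))
  }
  need <- c("p", "sensitivity", "specificity", "ppv", "npv", "f", "rr",
            "lr_pos")
  missing <- setdiff(need, names(rec))
  if (length(missing)) {
    stop_domain("scenario record lacks field(s): %s",
                paste(missing, collapse = ", "))
  }
  sc <- do.call(new_predictive_scenario, lapply(rec[need], as.numeric))
  validate_predictive_scenario(sc)
  sc
}
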