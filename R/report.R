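# The combined feasibility report: for one set of planning parameters it
# works through both low-prevalence problems — the likelihood ratio a tool
# would need to achieve useful post-test probabilities, and the cohort size
# needed to detect the risk factor at all — with optional Monte-Carlo
# confirmation. Every number in the report is recomputable from its
# provenance block alone.

#' Run a combined feasibility report
#'
#' Composes the package end to end for one planning question. The scenario
#' section gives the full marker/outcome distribution implied by the first
#' exposure fraction and the likelihood ratios required to reach each
#' post-test probability target from prevalence `p`. The sizing section
#' gives [required_total_n()] for every exposure fraction, plus the
#' events-per-variable verdict when an event and candidate count are
#' supplied. The simulation section (optional) confirms the sizing formula
#' with [empirical_power()]. Failures in any requested computation appear
#' as structured error entries, never as silent omissions.
#'
#' @param p Outcome prevalence used for the likelihood-ratio targets.
#' @param post_targets Post-test probability targets; default 10/25/50\%.
#' @param r0 Baseline risk in factor-negative individuals.
#' @param rr Relative risk of the risk factor.
#' @param f Exposure fraction(s); the sizing section covers each.
#' @param alpha,power,variant Passed to [design_spec()].
#' @param n_events,n_predictors Optional counts for the EPV verdict.
#' @param simulate If `TRUE`, run [empirical_power()] at the first design's
#'   required size.
#' @param replicates,seed Simulation controls.
#' @return A `feasibility_report` list with sections `scenario`, `sizing`,
#'   `simulation` and `provenance`; print it for the text rendering or use
#'   [report_to_json()].
#' @examples
#' rep <- run_report()
#' rep$scenario$required_lr
#' @export
run_report <- function(p = 0.01, post_targets = c(0.10, 0.25, 0.50),
                       r0 = 0.01, rr = 2, f = c(0.5, 0.1),
                       alpha = 0.05, power = 0.90, variant = "pooled",
                       n_events = NULL, n_predictors = NULL,
                       simulate = FALSE, replicates = 2000, seed = 1) {
  provenance <- list(
    p = p, post_targets = post_targets, r0 = r0, rr = rr, f = f,
    alpha = alpha, power = power, variant = variant,
    n_events = n_events, n_predictors = n_predictors,
    simulate = simulate, replicates = if (simulate) replicates else NULL,
    seed = if (simulate) seed else NULL,
    tool = "lowprev", version = as.character(utils::packageVersion("lowprev"))
  )

  as_entry <- function(expr) {
    tryCatch(expr, lowprev_domain_error = function(e) {
      list(error = TRUE, message = conditionMessage(e))
    })
  }

  scenario <- list(
    required_lr = data.frame(
      pre_p = p, post_p = post_targets,
      lr = vapply(post_targets, function(q) required_lr(p, q), numeric(1))
    ),
    marker = as_entry(scenario_from_exposure(r0, rr, f[1]))
  )

  sizing <- list(
    designs = lapply(f, function(fi) {
      as_entry(required_total_n(design_spec(r0, rr, fi, alpha, power,
                                            variant)))
    }),
    epv = if (!is.null(n_events)) {
      as_entry(epv_limit(n_events, n_candidates = n_predictors))
    }
  )

  simulation <- if (simulate) {
    as_entry({
      n <- required_total_n(design_spec(r0, rr, f[1], alpha, power,
                                        variant))$n_total
      empirical_power(design_spec(r0, rr, f[1], alpha, power, variant),
                      n, replicates, seed)
    })
  }

  structure(list(scenario = scenario, sizing = sizing,
                 simulation = simulation, provenance = provenance),
            class = "feasibility_report")
}

is_error_entry <- function(x) is.list(x) && isTRUE(x$error)

#' @export
print.feasibility_report <- function(x, ...) {
  pv <- x$provenance
  cat("=== Low-prevalence feasibility report (lowprev ", pv$version,
      ") ===\n\n", sep = "")
  cat("-- Predictive performance at prevalence", format_prob(pv$p), "--\n")
  lr <- x$scenario$required_lr
  for (i in seq_len(nrow(lr))) {
    cat(sprintf("  post-test target %s requires LR+ = %.4g\n",
                format_prob(lr$post_p[i]), lr$lr[i]))
  }
  cat("  Marker implied by the risk factor itself:\n")
  if (is_error_entry(x$scenario$marker)) {
    cat("    [error]", x$scenario$marker$message, "\n")
  } else {
    print(x$scenario$marker)
  }
  cat("\n-- Sample size to detect RR =", pv$rr, "--\n")
  for (i in seq_along(pv$f)) {
    d <- x$sizing$designs[[i]]
    if (is_error_entry(d)) {
      cat(sprintf("  f = %s: [error] %s\n", format_prob(pv$f[i]),
                  d$message))
    } else {
      cat(sprintf("  f = %s: total n = %d (%d exposed / %d unexposed, ~%.0f events)\n",
                  format_prob(pv$f[i]), d$n_total, d$n_exposed,
                  d$n_unexposed, d$expected_events))
    }
  }
  if (!is.null(x$sizing$epv)) {
    if (is_error_entry(x$sizing$epv)) {
      cat("  EPV check: [error]", x$sizing$epv$message, "\n")
    } else {
      cat("  "); print(x$sizing$epv)
    }
  }
  if (!is.null(x$simulation)) {
    cat("\n-- Monte-Carlo confirmation --\n")
    if (is_error_entry(x$simulation)) {
      cat("  [error]", x$simulation$message, "\n")
    } else {
      cat("  "); print(x$simulation)
    }
  }
  invisible(x)
}

#' Re-run a report from its embedded provenance
#'
#' Every reported number is recomputable from the provenance block alone;
#' this re-executes [run_report()] with exactly those inputs. The result
#' serializes identically to the original.
#'
#' @param x A `feasibility_report`.
#' @return A fresh `feasibility_report`.
#' @export
rerun_report <- function(x) {
  stopifnot(inherits(x, "feasibility_report"))
  pv <- x$provenance
  args <- pv[intersect(names(pv), names(formals(run_report)))]
  do.call(run_report, args[!vapply(args, is.null, logical(1))])
}

# Strip classes so jsonlite serializes plainly and reproducibly.
report_payload <- function(x) {
  declass <- function(v) {
    if (is.list(v)) lapply(unclass(v), declass) else v
  }
  declass(unclass(x))
}

#' Serialize a feasibility report to JSON
#'
#' Deterministic given the report: two reports produced by [run_report()]
#' from identical inputs (including seed) serialize byte-identically.
#'
#' @param x A `feasibility_report`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "feasibility_report"))
  js <- jsonlite::toJSON(report_payload(x), auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
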