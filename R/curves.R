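# Long-format curve tables backing the two standard planning figures:
# required total sample size against relative risk (one series per exposure
# fraction), and required relative risk against sensitivity (one series per
# PPV). Grid points that violate a domain constraint are skipped with a
# warning, never emitted as sentinel values, so every emitted row is
# independently recomputable from the single-point functions.

new_curve_table <- function(rows, metadata) {
  structure(rows, metadata = metadata,
            class = c("curve_table", "data.frame"))
}

#' Required sample size as a function of relative risk
#'
#' One series per exposure fraction: for each relative risk on the grid,
#' the total cohort size [required_total_n()] demands. Defaults follow the
#' canonical low-prevalence planning picture — baseline risk 1\%, 90\%
#' power at the two-sided 5\% level, exposure fractions of 5\%, 10\%, 20\%
#' and 50\%.
#'
#' @param rr_grid Increasing grid of relative risks > 1.
#' @param f_values Exposure fractions, one series each.
#' @param r0 Baseline risk in factor-negative individuals.
#' @param alpha,power,variant Passed to [design_spec()].
#' @return A `curve_table`: a data frame with columns `x` (relative risk),
#'   `series` (e.g. `"f=0.05"`) and `y` (total sample size), with the fixed
#'   parameters, grid specification and generation time in
#'   `attr(, "metadata")`.
#' @examples
#' tab <- sample_size_curve(rr_grid = c(2, 3, 4))
#' subset(tab, series == "f=0.5")
#' @export
sample_size_curve <- function(rr_grid = seq(1.5, 5, by = 0.1),
                              f_values = c(0.05, 0.10, 0.20, 0.50),
                              r0 = 0.01, alpha = 0.05, power = 0.90,
                              variant = "pooled") {
  check_number(rr_grid, "rr_grid")
  if (is.unsorted(rr_grid, strictly = TRUE)) {
    stop_domain("rr_grid must be strictly increasing")
  }
  rows <- list()
  skipped <- 0L
  for (f in f_values) {
    for (rr in rr_grid) {
      y <- tryCatch(
        required_total_n(design_spec(r0, rr, f, alpha, power,
                                     variant))$n_total,
        lowprev_domain_error = function(e) {
          warning(sprintf("skipping rr=%g, f=%g: %s", rr, f,
                          conditionMessage(e)), call. = FALSE)
          skipped <<- skipped + 1L
          NULL
        })
      if (!is.null(y)) {
        rows[[length(rows) + 1L]] <-
          data.frame(x = rr, series = sprintf("f=%g", f), y = y)
      }
    }
  }
  new_curve_table(
    do.call(rbind, rows),
    metadata = list(figure = "sample_size_vs_rr", r0 = r0, alpha = alpha,
                    power = power, variant = variant,
                    rr_grid = range(rr_grid), f_values = f_values,
                    n_skipped = skipped,
                    generated = format(Sys.time(), tz = "UTC"))
  )
}

#' Required relative risk as a function of sensitivity
#'
#' One series per target PPV: for each sensitivity on the grid, the
#' relative risk [rr_from_predictive()] implies at the given prevalence.
#' Defaults follow the canonical picture at 1\% prevalence with PPV targets
#' of 10\%, 20\% and 50\%. Within each series the curve rises with
#' sensitivity, and its infimum over sensitivities near 0 is `ppv / p` —
#' 50 for a 50\% PPV at 1\% prevalence, which is why such a PPV is out of
#' reach for any realistically sized effect.
#'
#' @param s_grid Grid of sensitivities in (0, 1).
#' @param ppv_values Target PPVs, one series each.
#' @param p Outcome prevalence.
#' @return A `curve_table` with `x` = sensitivity, `series` (e.g.
#'   `"PPV=0.5"`) and `y` = relative risk.
#' @examples
#' tab <- rr_sensitivity_curve(s_grid = c(0.2, 0.5, 0.8))
#' min(subset(tab, series == "PPV=0.5")$y) > 50
#' @export
rr_sensitivity_curve <- function(s_grid = seq(0.05, 0.95, by = 0.01),
                                 ppv_values = c(0.10, 0.20, 0.50),
                                 p = 0.01) {
  check_prob(s_grid, "s_grid", open_lo = TRUE, open_hi = TRUE)
  if (is.unsorted(s_grid, strictly = TRUE)) {
    stop_domain("s_grid must be strictly increasing")
  }
  rows <- list()
  skipped <- 0L
  for (ppv in ppv_values) {
    for (s in s_grid) {
      y <- tryCatch(
        rr_from_predictive(p, s, ppv),
        lowprev_domain_error = function(e) {
          warning(sprintf("skipping s=%g, ppv=%g: %s", s, ppv,
                          conditionMessage(e)), call. = FALSE)
          skipped <<- skipped + 1L
          NULL
        })
      if (!is.null(y)) {
        rows[[length(rows) + 1L]] <-
          data.frame(x = s, series = sprintf("PPV=%g", ppv), y = y)
      }
    }
  }
  new_curve_table(
    do.call(rbind, rows),
    metadata = list(figure = "rr_vs_sensitivity", p = p,
                    s_grid = range(s_grid), ppv_values = ppv_values,
                    n_skipped = skipped,
                    generated = format(Sys.time(), tz = "UTC"))
  )
}

#' @export
print.curve_table <- function(x, ...) {
  md <- attr(x, "metadata")
  cat("Curve table:", md$figure, "—", nrow(x), "rows,",
      length(unique(x$series)), "series\n")
  NextMethod()
}

#' Write a curve table as CSV plus a JSON metadata sidecar
#'
#' @param x A `curve_table`.
#' @param csv_path Output CSV path (header `x,series,y`).
#' @param meta_path Optional path for the JSON metadata sidecar.
#' @return `csv_path`, invisibly.
#' @export
write_curve_table <- function(x, csv_path, meta_path = NULL) {
  stopifnot(inherits(x, "curve_table"))
  utils::write.csv(as.data.frame(x), csv_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    jsonlite::write_json(attr(x, "metadata"), meta_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(csv_path)
}

#' Plot a curve table
#'
#' Base-graphics line plot, one line per series; sample-size curves are
#' drawn on a log y axis.
#'
#' @param x A `curve_table`.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.curve_table <- function(x, ...) {
  md <- attr(x, "metadata")
  series <- unique(x$series)
  xs <- sort(unique(x$x))
  ymat <- sapply(series, function(s) {
    x$y[match(paste(xs, s), paste(x$x, x$series))]
  })
  is_n <- identical(md$figure, "sample_size_vs_rr")
  graphics::matplot(xs, ymat, type = "l", lty = 1, col = seq_along(series),
                    log = if (is_n) "y" else "",
                    xlab = if (is_n) "relative risk" else "sensitivity",
                    ylab = if (is_n) "total sample size" else
                      "relative risk", ...)
  graphics::legend("topright", legend = series, lty = 1,
                   col = seq_along(series), bty = "n")
  invisible(x)
}
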