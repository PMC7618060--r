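# Shared validation helpers and tolerances.
#
# Consistency checks on scenarios compare ratios of well-conditioned O(1)
# expressions, so a tight relative tolerance with a small absolute floor is
# appropriate everywhere.

.lp_rel_tol <- 1e-9
.lp_abs_tol <- 1e-12

# Domain errors get their own condition class so the CLI can map them to
# exit code 2 while genuine bugs exit 1.
stop_domain <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c("lowprev_domain_error", "lowprev_error")))
}

is_domain_error <- function(e) inherits(e, "lowprev_domain_error")

# Numeric near-equality with the package-wide tolerances.
lp_near <- function(x, y, rel = .lp_rel_tol, abs_tol = .lp_abs_tol) {
  abs(x - y) <= pmax(abs_tol, rel * pmax(abs(x), abs(y)))
}

check_number <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_domain("%s must be a finite number", name)
  }
  invisible(x)
}

# Range check with per-end openness; errors name the violated constraint.
check_prob <- function(x, name, lo = 0, hi = 1,
                       open_lo = FALSE, open_hi = FALSE) {
  check_number(x, name)
  bad <- (if (open_lo) x <= lo else x < lo) |
         (if (open_hi) x >= hi else x > hi)
  if (any(bad)) {
    stop_domain("%s must be in %s%g, %g%s (got %s)", name,
                if (open_lo) "(" else "[", lo, hi,
                if (open_hi) ")" else "]",
                format(x[bad][1], digits = 6))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  check_number(x, name)
  if (any(x < min) || any(x != floor(x))) {
    stop_domain("%s must be an integer >= %d", name, min)
  }
  invisible(x)
}

# "1%" / "0.01" / 0.01 -> 0.01. Used by the CLI; package functions take
# proportions only.
parse_prob <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(x)
  pct <- grepl("%$", x)
  val <- suppressWarnings(as.numeric(sub("%$", "", x)))
  if (anyNA(val)) stop_domain("cannot parse '%s' as a probability", x)
  ifelse(pct, val / 100, val)
}

# Dual-scale formatting used in text output: proportion and percent.
format_prob <- function(x, digits = 3) {
  paste0(signif(x, digits), " (", signif(100 * x, digits), "%)")
}
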