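# Independent oracle: the explicit four-cell joint distribution of
# (marker/exposure E, outcome D). Every closed form in the package must
# agree with direct conditional-probability arithmetic on these cells.
# Cells: pED = P(E, D), pEnD = P(E, !D), pNED = P(!E, D), pNEnD = P(!E, !D).

joint_from_exposure <- function(r0, rr, f) {
  p1 <- r0 * rr
  c(pED = f * p1, pEnD = f * (1 - p1),
    pNED = (1 - f) * r0, pNEnD = (1 - f) * (1 - r0))
}

joint_from_predictive <- function(p, s, ppv) {
  pED <- p * s
  f <- pED / ppv
  c(pED = pED, pEnD = f - pED, pNED = p - pED, pNEnD = 1 - f - (p - pED))
}

# All metrics by brute-force conditioning on the four cells.
metrics_from_joint <- function(j) {
  p <- j[["pED"]] + j[["pNED"]]
  f <- j[["pED"]] + j[["pEnD"]]
  list(
    p = p,
    f = f,
    sensitivity = j[["pED"]] / p,
    specificity = j[["pNEnD"]] / (1 - p),
    ppv = j[["pED"]] / f,
    npv = j[["pNEnD"]] / (1 - f),
    rr = (j[["pED"]] / f) / (j[["pNED"]] / (1 - f)),
    lr_pos = (j[["pED"]] / p) / (j[["pEnD"]] / (1 - p))
  )
}

expect_scenario_matches_joint <- function(sc, j, tol = 1e-12) {
  m <- metrics_from_joint(j)
  for (nm in c("p", "f", "sensitivity", "specificity", "ppv", "npv",
               "rr", "lr_pos")) {
    expect_equal(sc[[nm]], m[[nm]], tolerance = tol,
                 label = sprintf("scenario field '%s'", nm))
  }
}

# Small deterministic grid of valid exposure-side parameterizations.
exposure_grid <- function(n_r0 = 10, n_rr = 10, n_f = 10) {
  g <- expand.grid(r0 = seq(0.001, 0.05, length.out = n_r0),
                   rr = seq(0.5, 10, length.out = n_rr),
                   f = seq(0.05, 0.95, length.out = n_f))
  g[g$r0 * g$rr < 1, ]
}
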