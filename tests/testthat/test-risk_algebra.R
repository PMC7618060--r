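# The RR / PPV / sensitivity / prevalence identity and its inverses,
# checked against brute-force enumeration of the four-cell joint
# distribution (helper-oracle.R).

test_that("rr_from_predictive matches the 2x2 oracle and its limits", {
  # s -> 0 floor: RR can never be below ppv / p
  expect_equal(rr_from_predictive(p = 0.01, s = 0, ppv = 0.50), 50)
  # uninformative marker: PPV equal to prevalence gives RR = 1
  expect_equal(rr_from_predictive(p = 0.01, s = 0.5, ppv = 0.01), 1)
  # frozen value, derived from the joint-distribution oracle
  expect_equal(rr_from_predictive(p = 0.01, s = 0.8, ppv = 0.50), 246)
  expect_equal(
    metrics_from_joint(joint_from_predictive(0.01, 0.8, 0.50))$rr, 246)

  # oracle equivalence on a grid of predictive-side inputs
  for (p in c(0.005, 0.01, 0.05, 0.2)) {
    for (s in c(0.05, 0.3, 0.7, 0.95)) {
      for (ppv in c(0.05, 0.1, 0.5, 0.9)) {
        if (ppv <= p * s) next
        j <- joint_from_predictive(p, s, ppv)
        if (any(j < 0)) next
        expect_equal(rr_from_predictive(p, s, ppv),
                     metrics_from_joint(j)$rr, tolerance = 1e-12)
      }
    }
  }
})

test_that("rr_from_predictive rejects degenerate and inconsistent inputs", {
  expect_error(rr_from_predictive(0.01, 1, 0.5), class = "lowprev_domain_error")
  expect_error(rr_from_predictive(0.01, 0.9, 0.009),
               class = "lowprev_domain_error")
  expect_error(rr_from_predictive(0, 0.5, 0.5), class = "lowprev_domain_error")
  expect_error(rr_from_predictive(1, 0.5, 0.5), class = "lowprev_domain_error")
})

test_that("ppv_from_rr inverts rr_from_predictive exactly", {
  expect_equal(ppv_from_rr(p = 0.01, s = 0, rr = 50), 0.50)
  expect_equal(ppv_from_rr(p = 0.3, s = 0.6, rr = 1), 0.3)  # null effect
  expect_equal(ppv_from_rr(p = 0.01, s = 0.8, rr = 246), 0.50)

  for (p in c(0.005, 0.01, 0.1)) {
    for (s in c(0.1, 0.5, 0.9)) {
      for (rr in c(1.5, 5, 20, 80)) {
        ppv <- tryCatch(ppv_from_rr(p, s, rr),
                        lowprev_domain_error = function(e) NULL)
        if (is.null(ppv)) next  # rr too large for this prevalence
        expect_equal(rr_from_predictive(p, s, ppv), rr, tolerance = 1e-12)
      }
    }
  }
  expect_error(ppv_from_rr(0.5, 0.1, 10), class = "lowprev_domain_error")
})

test_that("scenario constructors satisfy every invariant and match the oracle", {
  sc <- scenario_from_predictive(p = 0.01, s = 0.8, ppv = 0.10)
  expect_equal(sc$f, 0.08)
  expect_equal(sc$rr, 46)
  expect_scenario_matches_joint(sc, joint_from_predictive(0.01, 0.8, 0.10))

  coin <- scenario_from_predictive(p = 0.5, s = 0.5, ppv = 0.5)
  expect_equal(coin$f, 0.5)
  expect_equal(coin$rr, 1)
  expect_equal(coin$specificity, 0.5)

  expect_error(scenario_from_predictive(0.01, 0.9, 0.009),
               class = "lowprev_domain_error")

  sc2 <- scenario_from_exposure(r0 = 0.01, rr = 2, f = 0.5)
  expect_equal(sc2$p, 0.015)
  expect_equal(sc2$ppv, 0.02)
  expect_equal(sc2$sensitivity, 2 / 3)
  expect_scenario_matches_joint(sc2, joint_from_exposure(0.01, 2, 0.5))

  null_sc <- scenario_from_exposure(r0 = 0.01, rr = 1, f = 0.3)
  expect_equal(null_sc$p, 0.01)
  expect_equal(null_sc$sensitivity, 0.3)  # marker independent of outcome

  expect_error(scenario_from_exposure(0.6, 2, 0.5),
               class = "lowprev_domain_error")
})

test_that("exposure-side and predictive-side parameterizations are one identity", {
  # the executable derivation: exposure scenario -> (p, s, ppv) -> rr
  g <- exposure_grid()
  sc <- Map(scenario_from_exposure, g$r0, g$rr, g$f)
  rr_back <- vapply(sc, function(s) {
    rr_from_predictive(s$p, s$sensitivity, s$ppv)
  }, numeric(1))
  expect_equal(rr_back, g$rr, tolerance = 1e-12)
  # and each full scenario matches the brute-force joint table
  for (i in seq_len(nrow(g))[seq(1, nrow(g), by = 37)]) {
    expect_scenario_matches_joint(
      sc[[i]], joint_from_exposure(g$r0[i], g$rr[i], g$f[i]))
  }
})

test_that("likelihood-ratio algebra is exact and Bayes-consistent", {
  expect_equal(lr_positive(0.5, 0.5), 1)
  expect_equal(lr_positive(0.8, 0.9), 8)
  expect_equal(lr_positive(0, 0.5), 0)
  expect_error(lr_positive(0.8, 1), class = "lowprev_domain_error")

  expect_equal(required_lr(0.01, 0.10), 11)
  expect_equal(required_lr(0.01, 0.25), 33)
  expect_equal(required_lr(0.01, 0.50), 99)
  expect_equal(required_lr(0.37, 0.37), 1)
  expect_error(required_lr(0, 0.5), class = "lowprev_domain_error")

  expect_equal(post_test_probability(0.01, 11), 0.10)
  expect_equal(post_test_probability(0.01, 99), 0.50)
  expect_equal(post_test_probability(0.42, 1), 0.42)
  # inverse pair
  for (pre in c(0.01, 0.1, 0.6)) {
    for (lr in c(0.2, 1, 11, 99)) {
      expect_equal(required_lr(pre, post_test_probability(pre, lr)), lr,
                   tolerance = 1e-12)
    }
  }
  # Bayes consistency across the exposure grid: applying LR+ to the
  # prevalence odds reproduces the PPV
  g <- exposure_grid()
  for (i in seq_len(nrow(g))[seq(1, nrow(g), by = 13)]) {
    sc <- scenario_from_exposure(g$r0[i], g$rr[i], g$f[i])
    expect_equal(
      post_test_probability(sc$p, lr_positive(sc$sensitivity,
                                              sc$specificity)),
      sc$ppv, tolerance = 1e-12)
  }
})

test_that("rr_from_predictive is monotone: increasing in s, decreasing in p", {
  s_grid <- seq(0.05, 0.95, by = 0.05)
  rr_s <- rr_from_predictive(0.01, s_grid, 0.5)
  expect_true(all(diff(rr_s) > 0))

  p_grid <- seq(0.005, 0.09, by = 0.005)
  rr_p <- rr_from_predictive(p_grid, 0.4, 0.5)
  expect_true(all(diff(rr_p) < 0))
})

test_that("the RR floor at 1% prevalence is PPV/p, approached as s -> 0", {
  s_grid <- seq(0.01, 0.99, by = 0.01)
  rr50 <- rr_from_predictive(0.01, s_grid, 0.50)
  expect_true(all(rr50 > 50))
  expect_equal(rr_from_predictive(0.01, 1e-9, 0.50), 50, tolerance = 1e-6)

  rr10 <- rr_from_predictive(0.01, s_grid, 0.10)
  expect_true(all(rr10 > 10))
})

test_that("scenario records round-trip through JSON and CSV, and tampering is caught", {
  sc <- scenario_from_predictive(0.01, 0.8, 0.10)
  for (ext in c("json", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_scenario(sc, path)
    back <- read_scenario(path)
    expect_equal(unclass(back), unclass(sc), tolerance = 1e-12)
  }
  # an internally inconsistent record must be rejected by name
  path <- withr::local_tempfile(fileext = ".json")
  rec <- unclass(sc)
  rec$rr <- rec$rr * 2
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_scenario(path), "rr", class = "lowprev_domain_error")
})
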