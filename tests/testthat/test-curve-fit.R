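make_fit_stub <- function(ssr, n, p, model = "mono_assoc") {
  ## minimal exponential_fit carrier for F-test arithmetic tests
  bindkin:::new_exponential_fit(
    model, params = stats::setNames(rep(1, p), paste0("p", seq_len(p))),
    se = rep(NA_real_, p), residuals = c(sqrt(ssr), rep(0, n - 1)),
    fitted = rep(0, n), n_points = n)
}

test_that("mono association round-trips noiseless closed-form data", {
  ## k_on = 0.01/s, R_eq = 80, R_0 = 5
  t <- seq(0, 360, by = 0.5)
  y <- 5 + (80 - 5) * (1 - exp(-0.01 * t))
  sg <- sensorgram("association", t, y, analyte_concentration = 1e-7)
  f <- fit_mono_association(sg)
  expect_equal(f$params[["kon"]], 0.01, tolerance = 1e-6)
  expect_equal(f$params[["Req"]], 80, tolerance = 1e-6)
  expect_equal(f$params[["R0"]], 5, tolerance = 1e-4)
  expect_lt(f$ssr, 1e-12)
  expect_equal(f$dof, length(t) - 3)
})

test_that("flat association curves raise an unidentifiable-rate error", {
  t <- seq(0, 100, by = 1)
  sg <- sensorgram("association", t, rep(10, length(t)),
                   analyte_concentration = 1e-7)
  expect_error(fit_mono_association(sg), "unidentifiable")
})

test_that("mono fit k_on covers truth in its 95% CI across seeds", {
  sys <- ref_system()
  inst <- noisy(0.5, interval = 2)
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    sg <- simulate_association(sys, 6e-7, instrument = inst, seed = s)
    f <- fit_mono_association(sg)
    ci <- f$params[["kon"]] +
      c(-1, 1) * stats::qt(0.975, f$dof) * f$standard_errors[["kon"]]
    if (ci[1] <= 0.0271 && 0.0271 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("reported k_on standard error matches a Monte-Carlo oracle", {
  ## resampling oracle: SD of the estimate over independent noise draws
  sys <- ref_system()
  inst <- noisy(0.5, interval = 4)
  est <- se_rep <- numeric(500)
  for (s in seq_len(500)) {
    sg <- simulate_association(sys, 2e-7, instrument = inst, seed = 5000 + s)
    f <- fit_mono_association(sg)
    est[s] <- f$params[["kon"]]
    se_rep[s] <- f$standard_errors[["kon"]]
  }
  mc_sd <- stats::sd(est)
  expect_equal(mean(se_rep), mc_sd, tolerance = 0.25)
})

test_that("bi association round-trips two-component data and orders rates", {
  t <- seq(0, 600, by = 1)
  y <- 2 + 40 * (1 - exp(-0.005 * t)) + 40 * (1 - exp(-0.05 * t))
  sg <- sensorgram("association", t, y, analyte_concentration = 1e-7)
  f <- fit_bi_association(sg)
  expect_lt(f$params[["k1"]], f$params[["k2"]])  # canonical order
  expect_equal(f$params[["k1"]], 0.005, tolerance = 1e-4)
  expect_equal(f$params[["k2"]], 0.05, tolerance = 1e-4)
  expect_equal(f$params[["A1"]], 40, tolerance = 1e-4)
  expect_equal(f$params[["A2"]], 40, tolerance = 1e-4)
})

test_that("bi fit of mono-truth data degenerates but never fits worse", {
  t <- seq(0, 360, by = 1)
  y <- 10 + 70 * (1 - exp(-0.02 * t))
  sg <- sensorgram("association", t, y, analyte_concentration = 1e-7)
  mono <- fit_mono_association(sg)
  bi <- fit_bi_association(sg)
  expect_lte(bi$ssr, mono$ssr * (1 + 1e-9))  # nested dominance
  degenerate <- "degenerate" %in% bi$flags ||
    bi$params[["k2"]] / bi$params[["k1"]] < 1.5 ||
    min(bi$params[["A1"]], bi$params[["A2"]]) <
      0.02 * (bi$params[["A1"]] + bi$params[["A2"]])
  expect_true(degenerate)
})

test_that("nested dominance holds on noisy curves", {
  sys <- ref_system()
  for (s in 1:10) {
    sg <- simulate_association(sys, 3e-7, instrument = noisy(1, 2),
                               seed = 100 + s)
    mono <- fit_mono_association(sg)
    bi <- fit_bi_association(sg)
    expect_lte(bi$ssr, mono$ssr * (1 + 1e-9))
  }
})

test_that("dissociation fit round-trips and flags misspecification", {
  t <- seq(0, 600, by = 1)
  sg <- sensorgram("dissociation", t, 100 * exp(-2.5e-3 * t))
  f <- fit_dissociation(sg)
  expect_equal(f$params[["A"]], 100, tolerance = 1e-6)
  expect_equal(f$params[["kdiss"]], 2.5e-3, tolerance = 1e-6)

  ## offset recovered when enabled
  sg_off <- sensorgram("dissociation", t, 80 * exp(-4e-3 * t) + 20)
  f_off <- fit_dissociation(sg_off, with_offset = TRUE)
  expect_equal(f_off$params[["offset"]], 20, tolerance = 1e-4)
  expect_equal(f_off$params[["kdiss"]], 4e-3, tolerance = 1e-5)

  ## offset data fitted without offset: systematic positive tail residual
  f_mis <- fit_dissociation(sg_off, with_offset = FALSE)
  expect_gt(f_mis$diagnostics$tail_mean_residual, 0.1)

  ## wrong phase and flat traces are rejected
  up <- sensorgram("dissociation", t, 10 + 0.05 * t)
  expect_error(fit_dissociation(up), "wrong phase")
  flat <- sensorgram("dissociation", t, rep(50, length(t)))
  expect_error(fit_dissociation(flat, with_offset = TRUE),
               "unidentifiable")
})

test_that("F statistic and verdict follow the nested F-test formula", {
  ## frozen oracle: F = ((ssr_m - ssr_b)/2) / (ssr_b/(360 - 5))
  sel1 <- select_model_f_test(make_fit_stub(100, 360, 3),
                              make_fit_stub(99, 360, 5, "bi_assoc"))
  expect_equal(sel1$f_statistic, 1.792929, tolerance = 1e-6)
  expect_equal(sel1$p_value, 0.167976, tolerance = 1e-5)
  expect_identical(sel1$chosen, "mono")

  sel2 <- select_model_f_test(make_fit_stub(100, 360, 3),
                              make_fit_stub(50, 360, 5, "bi_assoc"))
  expect_equal(sel2$f_statistic, 177.5, tolerance = 1e-9)
  expect_identical(sel2$chosen, "bi")

  ## equal SSR: F = 0, parsimony wins
  sel3 <- select_model_f_test(make_fit_stub(80, 200, 3),
                              make_fit_stub(80, 200, 5, "bi_assoc"))
  expect_equal(sel3$f_statistic, 0)
  expect_identical(sel3$chosen, "mono")

  ## ssr_bi > ssr_mono clamps F at zero rather than going negative
  sel4 <- select_model_f_test(make_fit_stub(80, 200, 3),
                              make_fit_stub(90, 200, 5, "bi_assoc"))
  expect_equal(sel4$f_statistic, 0)

  expect_error(select_model_f_test(make_fit_stub(80, 200, 3),
                                   make_fit_stub(70, 300, 5, "bi_assoc")),
               "point counts")
})
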