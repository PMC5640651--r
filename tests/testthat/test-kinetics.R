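test_that("kon series collects one point per accepted mono fit", {
  sys <- ref_system()
  ser <- simulate_titration(sys, instrument = noiseless(2))
  fits <- lapply(ser$sensorgrams, fit_mono_association)
  pts <- build_kon_series(ser, fits)
  expect_equal(nrow(pts), 6)
  expect_true(all(diff(pts$concentration) > 0))
  expect_error(build_kon_series(ser, list()), "no fits")
  expect_error(build_kon_series(ser, fits[1:3]), "one fit per")
})

test_that("bi-selected curves are excluded from the kon series with warning", {
  sys <- ref_system()
  ser <- simulate_titration(sys, instrument = noiseless(2))
  fits <- lapply(ser$sensorgrams, function(sg) {
    fit_mono_association(sg)
  })
  ## forge a selection verdict preferring bi for the first curve
  mono <- fits[[1]]
  sel <- structure(list(f_statistic = 50, p_value = 1e-10,
                        confidence = 0.95, df = c(2, 100), chosen = "bi",
                        fits = list(mono = mono, bi = mono)),
                   class = "model_selection")
  fits[[1]] <- sel
  expect_warning(pts <- build_kon_series(ser, fits), "excluded")
  expect_equal(nrow(pts), 5)
})

test_that("kon regression recovers slope k_ass and intercept k_diss exactly", {
  sys <- binding_system(43000, 1e-4)
  conc <- default_concentration_grid()
  pts <- data.frame(concentration = conc,
                    k_on = vapply(conc, function(C) kon_observed(sys, C),
                                  numeric(1)))
  reg <- regress_kon(pts)
  expect_equal(reg$k_ass, 43000, tolerance = 1e-9)
  expect_equal(reg$k_diss, 1e-4, tolerance = 1e-9)
  ## two exact points: interpolating line, no SEs
  reg2 <- regress_kon(pts[c(1, 6), ])
  expect_equal(reg2$k_ass, 43000, tolerance = 1e-9)
  expect_true(is.na(reg2$k_ass_se))
  expect_error(regress_kon(pts[1, ]), "distinct")
})

test_that("kon regression SEs give ~95% coverage over noisy replicates", {
  ## 95% t-based intervals (4 residual dof with 6 points) should cover
  ## the truth in about 95% of replicates, with binomial slack
  sys <- ref_system()
  conc <- default_concentration_grid()
  truth <- vapply(conc, function(C) kon_observed(sys, C), numeric(1))
  crit <- stats::qt(0.975, length(conc) - 2)
  hit_a <- hit_d <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    k_noisy <- with_seed_test(s, truth + stats::rnorm(6, 0, 5e-4))
    reg <- regress_kon(data.frame(concentration = conc, k_on = k_noisy))
    if (abs(reg$k_ass - sys$k_ass) <= crit * reg$k_ass_se)
      hit_a <- hit_a + 1L
    if (abs(reg$k_diss - sys$k_diss) <= crit * reg$k_diss_se)
      hit_d <- hit_d + 1L
  }
  expect_gte(hit_a / n_rep, 0.90)
  expect_gte(hit_d / n_rep, 0.90)
})

test_that("negative fitted intercept is flagged, not clamped", {
  pts <- data.frame(concentration = c(1e-8, 1e-7, 3e-7),
                    k_on = c(4e-4, 4e-3, 1.2e-2) - 1e-3)
  reg <- regress_kon(pts)
  expect_lt(reg$k_diss, 0)
  expect_true("negative_intercept" %in% reg$flags)
})

test_that("K_D by the kinetic ratio reproduces printed constants", {
  expect_equal(signif(kd_from_kinetics(41000, 0.0025)$K_D, 2), 6.1e-8)
  expect_equal(signif(kd_from_kinetics(43000, 0.0001)$K_D, 2), 2.3e-9)
  kd <- kd_from_kinetics(4.1e4, 2.5e-3, 0.6e4, 0.6e-3)
  expect_equal(signif(kd$K_D_sd, 2), 1.7e-8)
  expect_error(kd_from_kinetics(0, 1e-3), "k_ass")
})

test_that("quadrature propagation matches a Monte-Carlo oracle on all rows", {
  rows <- rbind(
    ionic_strength_reference()[, c("k_ass", "k_ass_sd", "k_diss",
                                   "k_diss_sd")],
    ligand_comparison_reference()[, c("k_ass", "k_ass_sd", "k_diss",
                                      "k_diss_sd")])
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    quad <- kd_from_kinetics(r$k_ass, r$k_diss, r$k_ass_sd,
                             r$k_diss_sd)$K_D_sd
    mc <- with_seed_test(400 + i, {
      ka <- stats::rnorm(10000, r$k_ass, r$k_ass_sd)
      kd <- stats::rnorm(10000, r$k_diss, r$k_diss_sd)
      keep <- ka > 0 & kd > 0
      stats::sd(kd[keep] / ka[keep])
    })
    expect_equal(quad, mc, tolerance = 0.10)
  }
})

test_that("isotherm fit round-trips exact hyperbola points", {
  KD <- 3.6e-8; Rmax <- 100
  conc <- c(1e-8, 5e-8, 3e-7)
  ext <- data.frame(concentration = conc,
                    R_eq = Rmax * conc / (KD + conc))
  iso <- fit_isotherm(ext)
  expect_equal(iso$K_D, KD, tolerance = 1e-6)
  expect_equal(iso$R_max, Rmax, tolerance = 1e-6)
  expect_error(fit_isotherm(ext[1, , drop = FALSE]), "underdetermined")
})

test_that("isotherm flags the slope-only regime (all C << K_D)", {
  KD <- 1e-6; Rmax <- 100
  conc <- c(1e-9, 3e-9, 1e-8)  # two decades below K_D
  ext <- data.frame(concentration = conc,
                    R_eq = Rmax * conc / (KD + conc))
  iso <- fit_isotherm(ext)
  expect_true("poorly_constrained" %in% iso$flags)
})

test_that("kinetic and equilibrium K_D routes agree on simulated data", {
  ## self-consistency: the two routes should agree within combined 95% CIs
  sys <- ref_system()
  inst <- noisy(1, interval = 4)
  agree <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    ser <- simulate_titration(sys, instrument = inst, seed = 2000 + s)
    p <- analyze_titration(ser, confidence = NA)
    if (!is.finite(p$K_D_ext) || !is.finite(p$K_D_kin)) next
    gap <- abs(p$K_D_kin - p$K_D_ext)
    band <- 1.96 * sqrt(p$K_D_kin_sd^2 + p$K_D_ext_sd^2)
    if (gap <= band) agree <- agree + 1L
  }
  expect_gte(agree / n_rep, 0.90)
})

test_that("surface density and molar conversions follow the calibration", {
  cal <- surface_calibration()  # 600 arcsec per ng/mm2, 132 nm, 161 kDa
  expect_equal(surface_density_from_shift(0, cal), 0)
  expect_equal(surface_density_from_shift(600, cal), 1)
  d <- surface_density_from_shift(750, cal)
  expect_equal(d, 1.25)
  conv <- molar_surface_concentration(d, cal)
  expect_gt(conv$mass_concentration, 9)
  expect_lt(conv$mass_concentration, 10)
  expect_equal(conv$molar_concentration, 1000 * conv$mass_concentration /
                 161)
  expect_equal(molar_surface_concentration(0, cal)$molar_concentration, 0)
  expect_error(surface_calibration(layer_thickness = 0), "> 0")
})

test_that("stoichiometry rounds to the nearest small-integer ratio", {
  s <- determine_stoichiometry(59, 60)
  expect_equal(s$ratio, 60 / 59)
  expect_identical(s$rounded, "1:1")
  expect_identical(determine_stoichiometry(50, 50)$rounded, "1:1")
  expect_identical(determine_stoichiometry(30, 60)$rounded, "2:1")
  expect_identical(determine_stoichiometry(60, 30)$rounded, "1:2")
  expect_error(determine_stoichiometry(0, 10), "> 0")
})
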