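test_that("fold changes reproduce the printed destabilisation ratios", {
  expect_equal(fold_change(0.0025, 0.0001)$ratio, 25)
  fc8 <- fold_change(4.8e-7, 6.1e-8)
  expect_equal(fc8$rounded, 8)      # "nearly 8-fold"
  fc43 <- fold_change(2.6e-6, 6.1e-8)
  expect_equal(fc43$rounded, 43)    # "nearly 43-fold"
  expect_equal(fold_change(5, 5)$ratio, 1)
  expect_error(fold_change(1, 0), "denominator")
})

test_that("fold change is reciprocal-consistent and propagates error", {
  for (pair in list(c(0.0025, 0.0001), c(4.8e-7, 6.1e-8), c(2, 3))) {
    ab <- fold_change(pair[1], pair[2])$ratio
    ba <- fold_change(pair[2], pair[1])$ratio
    expect_equal(ab * ba, 1, tolerance = 1e-12)
  }
  fc <- fold_change(2.5e-3, 1e-4, 6e-4, 5e-5)
  expect_equal(fc$ratio_sd,
               25 * sqrt((6e-4 / 2.5e-3)^2 + (5e-5 / 1e-4)^2))
})

test_that("published parameter rows all pass the internal K_D ratio check", {
  salt <- build_condition_table(ionic_strength_reference())
  expect_true(all(salt$kd_consistent))
  expect_equal(salt$nacl_mM, c(0, 25, 50, 140))  # ordered by NaCl
  lig <- build_condition_table(ligand_comparison_reference())
  expect_true(all(lig$kd_consistent))
})

test_that("an internally inconsistent K_D row is flagged", {
  rows <- ionic_strength_reference()
  rows$KD[1] <- 1e-7  # inconsistent with k_diss/k_ass = 2.3e-9
  tab <- build_condition_table(rows)
  expect_false(tab$kd_consistent[tab$nacl_mM == 0])
  expect_true(all(tab$kd_consistent[tab$nacl_mM > 0]))
})

test_that("condition table validates its inputs", {
  rows <- ionic_strength_reference()
  expect_error(build_condition_table(rows[0, ]), "empty")
  dup <- rbind(rows[1, ], rows[1, ])
  expect_error(build_condition_table(dup), "unique")
  one <- build_condition_table(rows[2, ])
  expect_equal(nrow(one), 1)
})

test_that("salt trend reports destabilisation with constant association", {
  tab <- build_condition_table(ionic_strength_reference())
  tr <- salt_trend(tab)
  expect_identical(tr$k_diss_trend, "increasing")
  expect_identical(tr$KD_trend, "increasing")
  expect_true(tr$k_ass_constant_within_error)
})

test_that("salt trend detects no-trend and enforces preconditions", {
  rows <- ionic_strength_reference()
  rows$k_diss <- rep(1e-3, 4)
  tr <- salt_trend(build_condition_table(rows))
  expect_identical(tr$k_diss_trend, "constant")
  expect_error(salt_trend(build_condition_table(rows[1:2, ])), ">= 3")
  rows2 <- ionic_strength_reference()
  rows2$nacl_mM[2] <- 0
  rows2$label[2] <- "dup salt"
  expect_error(salt_trend(build_condition_table(rows2)), "duplicate")
})

test_that("injected monotone k_diss trends are recovered from simulation", {
  ## simulate three salt conditions with increasing dissociation rates
  kds <- c(5e-4, 1.5e-3, 4e-3)
  rows <- lapply(seq_along(kds), function(i) {
    sys <- binding_system(4e4, kds[i], 100)
    ser <- simulate_titration(sys, instrument = noisy(0.5, 4),
                              seed = 700 + i,
                              condition = buffer_condition(
                                nacl = c(10, 50, 140)[i]))
    p <- analyze_titration(ser, confidence = NA, with_isotherm = FALSE)
    data.frame(label = paste0("cond", i), nacl_mM = c(10, 50, 140)[i],
               k_ass = p$k_ass, k_ass_sd = p$k_ass_sd,
               k_diss = p$k_diss, k_diss_sd = p$k_diss_sd,
               KD = p$K_D_kin, KD_sd = p$K_D_kin_sd)
  })
  tab <- build_condition_table(do.call(rbind, rows))
  ## recomputed K_D always matches its own ratio by construction
  expect_true(all(tab$kd_consistent))
  tr <- salt_trend(tab)
  expect_identical(tr$k_diss_trend, "increasing")
  expect_identical(tr$KD_trend, "increasing")
})

test_that("competition reduction quantifies blockade with clamping", {
  expect_equal(competition_reduction(100, 50)$fraction, 0.5)
  expect_equal(competition_reduction(100, 100)$fraction, 0)
  expect_equal(competition_reduction(100, 0)$fraction, 1)
  over <- competition_reduction(100, 120)
  expect_equal(over$fraction, -0.05)
  expect_true(over$out_of_band)
  neg <- competition_reduction(100, -10)
  expect_equal(neg$fraction, 1)
  expect_true(neg$out_of_band)
  expect_error(competition_reduction(0, 10), "> 0")
})
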