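test_that("mean absolute error arithmetic and contracts", {
  expect_equal(mae(c(0.1, -0.1, 0.2, 0)), 0.1)
  expect_error(mae(numeric(0)), "empty")
  # nonnegative, zero iff all differences vanish
  expect_equal(mae(rep(0, 5)), 0)
  set.seed(1)
  expect_gt(mae(rnorm(20)), 0)
})

test_that("cohort MAE values match the published analysis", {
  t1 <- load_table1()
  dr <- t1$abi_trad_right - t1$abi_sys_right
  dl <- t1$abi_trad_left - t1$abi_sys_left
  fem <- t1$sex == "F"
  expect_lt(abs(mae(c(dr[fem], dl[fem])) - 0.0939), 0.0005)
  expect_lt(abs(mae(c(dr, dl)) - 0.1051), 0.001)
})

test_that("tolerance-band concordance counts and percentages", {
  cc <- concordance(c(0.05, 0.15, -0.09), 0.1)
  expect_equal(cc$count, 2)
  expect_equal(cc$percent, 200 / 3, tolerance = 1e-9)
  expect_error(concordance(numeric(0)), "empty")
  expect_error(concordance(c(0.1), tol = 0), "positive")
})

test_that("concordance is monotone in the tolerance", {
  set.seed(4)
  d <- rnorm(50, 0, 0.12)
  tols <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  counts <- vapply(tols, function(tl) concordance(d, tl)$count, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("cohort concordance matches the published side and sex breakdown", {
  t1 <- load_table1()
  dr <- t1$abi_trad_right - t1$abi_sys_right
  dl <- t1$abi_trad_left - t1$abi_sys_left
  fem <- t1$sex == "F"
  left <- concordance(dl)
  expect_equal(left$count, 12)
  expect_equal(left$percent, 54.54, tolerance = 0.01)
  expect_equal(concordance(dr[fem])$percent, 77.78, tolerance = 0.01)
  expect_equal(concordance(dl[fem])$percent, 66.67, tolerance = 0.01)
  expect_equal(concordance(dl[!fem])$percent, 46.15, tolerance = 0.01)
  expect_equal(concordance(c(dr[fem], dl[fem]))$percent, 72.22, tolerance = 0.01)
})

test_that("Bland-Altman limits from hand arithmetic and degenerate input", {
  pm <- paired_measurements(c(1, 2, 3), c(2, 2, 2))   # diffs -1, 0, 1
  ba <- bland_altman(pm, "POPULATION")
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(ba$loa_high, 1.96 * sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(ba$n_within, 3)

  zero <- bland_altman(paired_measurements(rep(1, 4), rep(1, 4)))
  expect_equal(c(zero$loa_low, zero$loa_high), c(0, 0))
  expect_equal(zero$n_within, 4)

  expect_error(bland_altman(paired_measurements(1:2, 2:3)), "at least 3")
})

test_that("n_within equals a brute-force count on random differences", {
  set.seed(77)
  for (rep in 1:10) {
    d <- rnorm(30, 0.02, 0.1)
    pm <- paired_measurements(d, rep(0, 30))
    for (mode in c("POPULATION", "SAMPLE")) {
      ba <- bland_altman(pm, mode)
      # independent brute-force count over the same differences
      brute <- 0
      for (x in d) if (x >= ba$loa_low && x <= ba$loa_high) brute <- brute + 1
      expect_equal(ba$n_within, brute)
    }
  }
})

test_that("left-ABI Bland-Altman keeps 21 of 22 inside the limits (both SD modes)", {
  t1 <- load_table1()
  pm <- paired_measurements(t1$abi_trad_left, t1$abi_sys_left)
  expect_equal(bland_altman(pm, "POPULATION")$n_within, 21)
  expect_equal(bland_altman(pm, "SAMPLE")$n_within, 21)
})

test_that("validation report reproduces the published summary statistics", {
  rep <- validation_report()
  expect_lt(abs(rep$female$mae - 0.0939), 0.0005)
  expect_lt(abs(rep$overall$mae - 0.1051), 0.001)
  expect_equal(rep$left$concordance$count, 12)
  expect_equal(rep$female_right$concordance$percent, 77.78, tolerance = 0.01)
  expect_equal(rep$female_left$concordance$percent, 66.67, tolerance = 0.01)
  expect_equal(rep$male_left$concordance$percent, 46.15, tolerance = 0.01)
  expect_equal(rep$female$concordance$percent, 72.22, tolerance = 0.01)
  expect_equal(rep$bland_altman$left$n_within, 21)
  # recomputation from the printed 3-decimal table yields 16 on the right
  # (the published count of 17 relies on unrounded system values)
  expect_equal(rep$right$concordance$count, 16)
})

test_that("validation report serialises to JSON and round-trips key values", {
  rep <- validation_report()
  js <- jsonlite::fromJSON(validation_report_to_json(rep))
  expect_equal(js$female$mae, rep$female$mae, tolerance = 1e-12)
  expect_equal(js$bland_altman$left$n_within, 21)
  expect_equal(js$left$concordance$count, 12)
})
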