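test_that("segment lengths match direct evaluation of the published equations", {
  m <- default_length_model()
  for (H in c(1.465, 1.7, 1.875)) {
    ref <- hand_lengths(H)
    for (seg in names(ref)) {
      expect_equal(segment_length(m, seg, H), ref[[seg]], tolerance = 1e-10,
                   info = paste(seg, "at", H))
    }
  }
  # spot values at H = 1.7
  expect_equal(segment_length(m, "RA", 1.7), 0.909693, tolerance = 1e-4)
  expect_equal(segment_length(m, "PA", 1.7), 0.213331, tolerance = 1e-4)
  expect_equal(segment_length(m, "AR", 1.7), 1.295023, tolerance = 1e-4)
})

test_that("composite foot paths add the plantar segment", {
  m <- default_length_model()
  cl <- composite_lengths(m, 1.7)
  expect_equal(cl$arf_m, 1.508354, tolerance = 1e-4)
  expect_equal(cl$alf_m, 1.505004, tolerance = 1e-4)
  expect_gt(cl$arf_m, cl$ra_m)
  expect_gt(cl$alf_m, cl$la_m)
  # foot paths dominate hand paths over the whole adult range
  for (H in seq(1.4, 2.0, by = 0.1)) {
    cl <- composite_lengths(m, H)
    expect_gt(cl$arf_m, cl$ra_m)
    expect_gt(cl$alf_m, cl$la_m)
  }
})

test_that("heights outside the supported range are rejected", {
  m <- default_length_model()
  expect_error(segment_length(m, "RA", 0.9), "outside the supported range")
  expect_error(segment_length(m, "RA", 2.6), "outside the supported range")
  expect_error(composite_lengths(m, 0.5), "outside the supported range")
  expect_silent(segment_length(m, "RA", 1.0))
  expect_silent(segment_length(m, "RA", 2.5))
})

test_that("default segment lengths increase with height over the adult range", {
  m <- default_length_model()
  # The four limb quadratics peak above 2.0 m and are increasing on all of
  # [1.4, 2.0]; the plantar quadratic peaks at H ~ 1.81 m, so its
  # monotonicity only holds below that point.
  for (seg in c("RA", "LA", "AR", "AL")) {
    lens <- segment_length(m, seg, seq(1.4, 2.0, by = 0.01))
    expect_true(all(diff(lens) > 0), info = seg)
  }
  pa <- segment_length(m, "PA", seq(1.4, 1.8, by = 0.01))
  expect_true(all(diff(pa) > 0))
})

test_that("lengths are physiological for every cohort height", {
  m <- default_length_model()
  for (H in load_table1()$height_m) {
    for (seg in c("RA", "LA", "AR", "AL", "PA")) {
      l <- segment_length(m, seg, H)
      expect_gt(l, 0.1)
      expect_lt(l, 2.0)
    }
  }
})

test_that("least-squares refit recovers exact coefficients from noiseless data", {
  m <- default_length_model()
  hh <- seq(1.45, 1.9, length.out = 10)
  lens <- as.data.frame(lapply(
    stats::setNames(c("RA", "LA", "AR", "AL", "PA"),
                    c("RA", "LA", "AR", "AL", "PA")),
    function(seg) segment_length(m, seg, hh)))
  fit <- fit_length_model(hh, lens)
  expect_equal(fit$model$coefficients, m$coefficients, tolerance = 1e-9)
  expect_true(all(fit$rss < 1e-18))
})

test_that("refit from noisy data recovers lengths to < 1 cm", {
  m <- default_length_model()
  set.seed(35)
  hh <- runif(35, 1.45, 1.9)
  lens <- as.data.frame(lapply(
    stats::setNames(c("RA", "LA", "AR", "AL", "PA"),
                    c("RA", "LA", "AR", "AL", "PA")),
    function(seg) segment_length(m, seg, hh) + rnorm(35, 0, 0.005)))
  fit <- fit_length_model(hh, lens)
  grid <- seq(1.45, 1.9, by = 0.01)
  for (seg in c("RA", "LA", "AR", "AL", "PA")) {
    expect_lt(max(abs(segment_length(fit$model, seg, grid) -
                      segment_length(m, seg, grid))), 0.01)
  }
})

test_that("refit needs at least 3 distinct heights", {
  lens <- data.frame(RA = c(1, 1.1, 1.2), LA = c(1, 1.1, 1.2),
                     AR = c(1, 1.1, 1.2), AL = c(1, 1.1, 1.2),
                     PA = c(0.2, 0.21, 0.22))
  expect_error(fit_length_model(c(1.6, 1.6, 1.7), lens), "3 distinct heights")
})

test_that("length model serialises to JSON and back", {
  m <- default_length_model()
  m2 <- length_model_from_json(length_model_to_json(m))
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-12)
  expect_error(length_model_from_json('{"RA": [1, 2, 3]}'), "missing segment")
})
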