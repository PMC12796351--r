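test_that("profile anchors follow the short/long placement rule", {
  expect_equal(unname(profile_positions(1.2)), c(0.2, 0.6, 1.0))
  expect_equal(unname(profile_positions(3.0)), c(0.35, 1.5, 2.65))
  # boundary L = 2.1 uses the long rule
  expect_equal(unname(profile_positions(2.1)), c(0.35, 1.05, 1.75))
})

test_that("profile extraction reproduces planted cross-sections", {
  cfg <- noise_free_cfg()
  px <- cfg$pixel_size_nm

  # constant image -> flat profile at that value
  obj <- make_obj(1.0, 1.0, 30, 0.8, px)
  flat <- extract_profile(matrix(7, 81, 81), obj, 0.4)
  expect_true(all(abs(flat$intensity - 7) < 1e-9))
  expect_identical(as.integer(count_peaks(flat)), 0L)

  # synthetic 150-nm membrane pair: two maxima ~150 nm apart at the center
  patch <- render_membrane_object(1.2, 150, 20, cfg, patch_size_px = 81)
  ctr_um <- (81 - 1) / 2 * px / 1000
  obj2 <- make_obj(ctr_um, ctr_um, 20, 1.2, px)
  pr <- extract_profile(patch, obj2, 0.6, L = 1.2)
  np <- count_peaks(pr)
  expect_identical(as.integer(np), 2L)
  sep <- diff(range(pr$position_nm[attr(np, "peaks")]))
  expect_lte(abs(sep - 150), px + 1e-9)

  # rotating object and image by 90 degrees leaves the profile unchanged
  patch90 <- render_membrane_object(1.2, 150, 110, cfg, patch_size_px = 81)
  obj90 <- make_obj(ctr_um, ctr_um, 110, 1.2, px)
  pr90 <- extract_profile(patch90, obj90, 0.6, L = 1.2)
  expect_lt(max(abs(pr90$intensity - pr$intensity)) / max(pr$intensity), 1e-3)
})

test_that("peak counting applies prominence and separation gates", {
  x <- seq(-375, 375, by = 25)
  mk <- function(y) structure(list(position_nm = x, intensity = y),
                              class = "line_profile")
  expect_identical(as.integer(count_peaks(mk(rep(1, length(x))))), 0L)
  expect_identical(as.integer(count_peaks(mk(exp(-x^2 / 8000)))), 1L)
  two <- exp(-(x - 80)^2 / 4000) + exp(-(x + 80)^2 / 4000)
  expect_identical(as.integer(count_peaks(mk(two))), 2L)
  # sub-prominence ripple is not a peak
  ripple <- exp(-x^2 / 60000) + 0.02 * sin(x / 30)
  expect_lte(as.integer(count_peaks(mk(ripple))), 1L)
})

test_that("Gaussian width fits reproduce closed forms and the grid oracle", {
  x <- seq(-375, 375, by = 25)
  mk <- function(y) structure(list(position_nm = x, intensity = y,
                                   anchor_offset_um = 0.5),
                              class = "line_profile")

  # single Gaussian, sigma 40 -> FWHM 2 sqrt(2 ln 2) * 40 = 94.17
  y1 <- 5 + 100 * exp(-x^2 / (2 * 40^2))
  p1 <- mk(y1)
  f1 <- fit_width(p1, count_peaks(p1))
  expect_identical(f1$model, "single")
  expect_equal(f1$width_nm, 2 * sqrt(2 * log(2)) * 40, tolerance = 1e-3)
  expect_equal(f1$width_nm, grid_fit_oracle(x, y1, 1L), tolerance = 2 / 94)

  # double Gaussian at -75 / +75 -> width 150
  y2 <- 3 + 90 * exp(-(x - 75)^2 / (2 * 35^2)) + 90 * exp(-(x + 75)^2 / (2 * 35^2))
  p2 <- mk(y2)
  f2 <- fit_width(p2, count_peaks(p2))
  expect_identical(f2$model, "double")
  expect_equal(f2$width_nm, 150, tolerance = 1e-3)
  expect_lt(abs(f2$width_nm - grid_fit_oracle(x, y2, 2L)), 2)

  # double Gaussian with asymmetric centers 100 and 250
  xs <- seq(0, 360, by = 20)
  y3 <- 60 * exp(-(xs - 100)^2 / (2 * 30^2)) + 60 * exp(-(xs - 250)^2 / (2 * 30^2))
  p3 <- structure(list(position_nm = xs, intensity = y3,
                       anchor_offset_um = 0.5), class = "line_profile")
  f3 <- fit_width(p3, count_peaks(p3))
  expect_equal(f3$width_nm, 150, tolerance = 1e-3)

  # 3-4 peaks: side-by-side flag, width from adjacent peak distances
  y4 <- 80 * exp(-(x + 200)^2 / (2 * 25^2)) + 80 * exp(-(x - 0)^2 / (2 * 25^2)) +
    80 * exp(-(x - 200)^2 / (2 * 25^2))
  p4 <- mk(y4)
  n4 <- count_peaks(p4)
  expect_identical(as.integer(n4), 3L)
  f4 <- fit_width(p4, n4)
  expect_identical(f4$model, "multi")
  expect_identical(f4$status, "side_by_side")
  expect_equal(f4$width_nm, 200, tolerance = 1e-6)

  # more than four peaks or a flat profile are rejected
  y5 <- rowSums(vapply(seq(-300, 300, by = 120),
                       function(c0) 50 * exp(-(x - c0)^2 / (2 * 18^2)),
                       numeric(length(x))))
  p5 <- mk(y5)
  expect_identical(fit_width(p5, count_peaks(p5))$model, "rejected")
  expect_identical(fit_width(mk(rep(2, length(x))),
                             count_peaks(mk(rep(2, length(x)))))$status, "no_peak")
})

test_that("per-object widths combine the three anchor fits", {
  okfit <- function(w) structure(list(model = "double", width_nm = w,
                                      width_source = "peak_distance",
                                      r2 = 0.99, pars = NULL, status = "ok",
                                      anchor_offset_um = 0),
                                 class = "peak_fit")
  bad <- structure(list(model = "rejected", width_nm = NA_real_,
                        width_source = NA_character_, r2 = NA_real_,
                        pars = NULL, status = "low_r2",
                        anchor_offset_um = 0), class = "peak_fit")

  ow <- object_width(list(end1 = okfit(150), center = okfit(139), end2 = okfit(150)))
  expect_equal(ow$width_center_nm, 139)
  expect_equal(ow$width_outer_nm, 150)
  expect_equal(ow$width_ratio, 150 / 139, tolerance = 1e-9)

  # rejected ends: center kept, outer undefined
  ow2 <- object_width(list(end1 = bad, center = okfit(139), end2 = bad))
  expect_equal(ow2$width_center_nm, 139)
  expect_true(is.na(ow2$width_outer_nm))
  expect_identical(ow2$qc, "ok")

  # rejected center fails QC
  ow3 <- object_width(list(end1 = okfit(150), center = bad, end2 = okfit(150)))
  expect_identical(ow3$qc, "center_rejected")

  # all equal widths give ratio exactly 1
  ow4 <- object_width(list(end1 = okfit(140), center = okfit(140), end2 = okfit(140)))
  expect_equal(ow4$width_ratio, 1)
})

test_that("width measurement is rotation invariant and unbiased on rendered membranes", {
  cfg <- noise_free_cfg()
  px <- cfg$pixel_size_nm
  widths <- c(150, 200)
  for (w in widths) {
    got <- vapply(c(0, 30, 65, 90), function(ang) {
      patch <- render_membrane_object(1.0, w, ang, cfg, patch_size_px = 81)
      ctr_um <- (81 - 1) / 2 * px / 1000
      obj <- make_obj(ctr_um, ctr_um, ang, 1.0, px)
      pr <- extract_profile(patch, obj, 0.5, L = 1.0)
      fit_width(pr, count_peaks(pr))$width_nm
    }, numeric(1))
    expect_lt(max(got) - min(got), px)        # rotation invariance within 1 px
    expect_lt(max(abs(got - w)) / w, 0.05)    # < 5% bias at resolvable widths
  }
})
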