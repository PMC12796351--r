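test_that("labeling computes closed-form area and honors 8-connectivity", {
  # single 5x5 square at 25 nm/px: A = 25 * 0.025^2
  m <- matrix(0L, 12, 12)
  m[4:8, 5:9] <- 1L
  objs <- label_objects(m, matrix(1, 12, 12), 25)
  expect_length(objs, 1L)
  expect_equal(objs[[1]]$area_um2, 25 * 0.025^2)
  expect_true(is.finite(objs[[1]]$angle_deg))
  expect_gte(objs[[1]]$angle_deg, -90)
  expect_lt(objs[[1]]$angle_deg, 90)

  # two blobs touching only diagonally form one 8-connected object
  d <- matrix(0L, 10, 10)
  d[2:4, 2:4] <- 1L
  d[5:7, 5:7] <- 1L
  expect_length(label_objects(d, matrix(1, 10, 10), 25), 1L)

  # empty mask: empty list, not an error
  expect_length(label_objects(matrix(0L, 5, 5), matrix(1, 5, 5), 25), 0L)
})

test_that("ellipse fit recovers drawn axes and matches the moment oracle", {
  m <- draw_ellipse_mask(101, 40, 12, 25)
  objs <- label_objects(m, matrix(1, 101, 101), 25)
  expect_length(objs, 1L)
  o <- objs[[1]]
  expect_lt(abs(o$major_um - 80 * 0.025) / (80 * 0.025), 0.05)
  expect_lt(abs(o$minor_um - 24 * 0.025) / (24 * 0.025), 0.05)

  # equivalence with an independent eigen-based moment computation, for
  # every component of a random small mask
  set.seed(4)
  rnd <- refine_mask(matrix(as.integer(runif(64 * 64) > 0.93), 64, 64), "dilate")
  objs2 <- label_objects(rnd, matrix(1, 64, 64), 20)
  for (o in objs2) {
    ora <- ellipse_moments_oracle(o$rows, o$cols, 20)
    expect_lt(abs(o$major_um - ora$major_um) / ora$major_um, 1e-6)
    expect_lt(abs(o$minor_um - ora$minor_um) / ora$minor_um, 1e-6)
  }
})

test_that("skeleton length sums Euclidean branch steps", {
  px <- 25
  # horizontal 1x41 line: 40 unit steps = 1 um
  line <- matrix(0L, 9, 50)
  line[5, 5:45] <- 1L
  objs <- label_objects(line, matrix(1, 9, 50), px)
  expect_equal(skeleton_length(objs[[1]]), 1.0)

  # L-shaped path: two 21-px arms sharing the corner pixel, 40 steps total
  ell <- matrix(0L, 30, 30)
  ell[5:25, 5] <- 1L
  ell[25, 5:25] <- 1L
  objsL <- label_objects(ell, matrix(1, 30, 30), px)
  expect_equal(skeleton_length(objsL[[1]]), 1.0)

  # single pixel skeleton has zero length
  pt <- matrix(0L, 5, 5)
  pt[3, 3] <- 1L
  objsP <- label_objects(pt, matrix(1, 5, 5), px)
  expect_equal(skeleton_length(objsP[[1]]), 0)

  # diagonal line: sqrt(2) steps
  dg <- matrix(0L, 25, 25)
  diag(dg) <- 1L
  objsD <- label_objects(dg, matrix(1, 25, 25), px)
  expect_equal(skeleton_length(objsD[[1]]), 24 * sqrt(2) * px / 1000)
})

test_that("length selection follows the area gate", {
  expect_identical(select_length(0.1, 0.4, 0.9), 0.4)
  expect_identical(select_length(0.5, 1.2, 1.5), 1.5)
  # boundary A = 0.2 goes to the larger-of-two branch
  expect_identical(select_length(0.2, 0.7, 1.1), 1.1)
  # never shorter than the ellipse length
  set.seed(7)
  for (i in 1:50) {
    A <- runif(1, 0, 1); le <- runif(1, 0, 3); ls <- runif(1, 0, 3)
    expect_gte(select_length(A, le, ls), le)
  }
  expect_error(select_length(-0.1, 1, 1), "negative")
})

test_that("MDS and shape classification apply the documented thresholds", {
  expect_identical(classify_mds(0.035), "MDS")
  expect_identical(classify_mds(0.423), "mitochondrion")
  expect_identical(classify_mds(0.086), "mitochondrion")  # strict inequality

  expect_identical(classify_shape(0.70), "vesicle")
  expect_identical(classify_shape(0.5), "vesicle")  # inclusive boundary
  expect_identical(classify_shape(0.49), "stick")
  expect_error(classify_shape(1.2), "convention")
  expect_error(classify_shape(0), "positive")

  # monotone step functions: raising A_th can only move objects to MDS
  A <- runif(30, 0, 0.3)
  c1 <- classify_mds(A, 0.086)
  c2 <- classify_mds(A, 0.12)
  expect_true(all(!(c1 == "MDS" & c2 == "mitochondrion")))
})

test_that("population summary reports modes, fractions, and count ratios", {
  rec <- data.frame(
    id = 1:10,
    area_um2 = c(0.03, 0.04, 0.05, 0.3, 0.5, 0.6, 0.7, 0.8, 1.2, 2.0),
    length_um = c(rep(0.3, 3), 1, 2, 3, 4, 5, 12, 15),
    width_nm = c(100, 139, 139, 400, 139, 139, 150, 150, 180, 200),
    ar = c(0.9, 0.6, 0.3, 0.2, 0.2, 0.2, 0.2, 0.2, 0.1, 0.1),
    qc = "ok")
  rec$class <- classify_mds(rec$area_um2)
  rec$shape <- NA_character_
  rec$shape[rec$class == "MDS"] <- classify_shape(rec$ar[rec$class == "MDS"])
  s <- summarize_population(rec)
  expect_equal(s$width_mode_nm, 139)
  expect_equal(s$frac_length_gt_10um, 2 / 7)  # 2 of the 7 mitochondria
  expect_equal(s$n_mds, 3L)
  expect_equal(s$mds_mito_ratio, 3 / 7)
  expect_length(summarize_population(rec[0, ]), 0L)
})

test_that("morphometry recovers planted geometry on noise-free capsules", {
  cfg <- noise_free_cfg(n_mitochondria = 12L, n_mds = 8L, seed = 13,
                        length_range_um = c(0.4, 3.5))
  f <- generate_field(cfg)
  mask <- binarize_bernsen(f$structural, 9L, 15)
  mask <- refine_mask(mask, c("fill_holes", "erode:2", "remove_small:12"))
  mask <- apply_region_exclusion(mask, f$soma_mask)
  objs <- label_objects(mask, f$structural, cfg$pixel_size_nm)
  expect_identical(length(objs), nrow(f$truth))
  rec <- assemble_morph_records(objs)

  # match measured objects to planted ones by centroid
  m <- vapply(seq_len(nrow(rec)), function(i) {
    which.min((f$truth$center_x_um - rec$centroid_x_um[i])^2 +
                (f$truth$center_y_um - rec$centroid_y_um[i])^2)
  }, integer(1))
  expect_identical(sort(m), seq_len(nrow(f$truth)))
  tr <- f$truth[m, ]
  wide <- tr$true_width_nm >= 120 & tr$true_length_um <= 4
  aspect <- tr$true_length_um * 1000 / tr$true_width_nm
  rel_err <- abs(rec$length_um - tr$true_length_um) / tr$true_length_um
  # the moment-ellipse length of an elongated capsule is analytically
  # ~1.11x the tip-to-tip length, so at aspect ratios above ~18 the
  # selected length inherits that bias; within moderate aspect the
  # recovery is within 10%, and the bias never exceeds the analytic bound
  expect_true(all(rel_err[wide & aspect <= 15] <= 0.10))
  expect_true(all(rel_err[wide] <= 0.13))
})
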