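test_that("process map handles blank images and small specks", {
  expect_warning(pm <- build_process_map(matrix(5, 64, 64), NULL, 25),
                 "degenerate|zero-length")
  expect_identical(pm$total_length_um, 0)

  # a 19-px isolated speck contributes nothing
  img <- matrix(rexp(128 * 128, 1), 128, 128)
  img[40:43, 40:44] <- 100  # 20-px block
  img[43, 44] <- 0.1        # now 19 px
  img[90:92, 20:110] <- 60  # a real process band
  pm2 <- build_process_map(img, NULL, 25, n_dilate = 2L, n_erode = 2L)
  expect_gt(pm2$total_length_um, 0)
  expect_true(all(pm2$mask[38:45, 38:46] == 0))
})

test_that("process length of a straight neurite matches the planted length", {
  # 2440 x 200 px at 50 nm/px: a 120-um horizontal neurite with bright
  # objects on it and faint background fluorescence along the process
  set.seed(5)
  nr <- 200; nc <- 2440; px <- 50
  img <- matrix(rexp(nr * nc, 1 / 0.5), nr, nc)
  band <- 95:105
  img[band, 20:2420] <- img[band, 20:2420] + 12
  for (k in seq(60, 2380, by = 120)) {
    img[98:102, k:(k + 8)] <- 150
  }
  img <- matrix(rpois(nr * nc, pmax(img, 0)), nr, nc)
  pm <- build_process_map(img, NULL, px)
  planted_um <- (2420 - 20) * px / 1000
  expect_lt(abs(pm$total_length_um - planted_um) / planted_um, 0.10)
  # intensity scaling above the cap leaves the length unchanged
  pm2 <- build_process_map(img * 4, NULL, px)
  expect_equal(pm2$total_length_um, pm$total_length_um, tolerance = 0.02)
})

test_that("number densities are counts per unit length", {
  expect_equal(unname(number_density(c(MDS = 12), 60)), 0.2)
  expect_equal(unname(number_density(c(MDS = 0), 60)), 0)
  expect_error(number_density(c(MDS = 3), 0), "undefined")

  # equal planted densities in two compartments are statistically
  # indistinguishable across seeded draws
  set.seed(11)
  d_ax <- replicate(12, {
    len <- runif(1, 50, 90)
    unname(number_density(c(n = rpois(1, 0.2 * len)), len))
  })
  d_de <- replicate(12, {
    len <- runif(1, 50, 90)
    unname(number_density(c(n = rpois(1, 0.2 * len)), len))
  })
  expect_gt(t.test(d_ax, d_de)$p.value, 0.05)
})

test_that("turnover ratio follows its definition and bounds", {
  m <- matrix(0L, 6, 6)
  m[2:4, 2:4] <- 1L
  obj <- label_objects(m, matrix(1, 6, 6), 25)[[1]]
  old1 <- matrix(10, 6, 6); new1 <- matrix(0, 6, 6)
  expect_identical(turnover_ratio(obj, old1, new1), 0)
  expect_identical(turnover_ratio(obj, new1, old1), 1)
  expect_true(is.na(turnover_ratio(obj, new1, new1)))
  set.seed(2)
  for (i in 1:20) {
    a <- matrix(rexp(36), 6, 6); b <- matrix(rexp(36), 6, 6)
    r <- turnover_ratio(obj, a, b)
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("radial rings partition objects by distance from the soma edge", {
  n <- 400; px <- 100  # 40 um field at 100 nm/px for cheap geometry
  soma <- matrix(0L, n, n)
  ctr <- 200; rad_px <- 30
  for (i in 1:n) for (j in 1:n) {
    if ((i - ctr)^2 + (j - ctr)^2 <= rad_px^2) soma[i, j] <- 1L
  }
  mk_rec <- function(d_um, ratio, class = "mitochondrion") {
    # place along +x from the soma edge
    x <- (ctr - 1 + rad_px) * px / 1000 + d_um
    data.frame(centroid_x_um = x, centroid_y_um = (ctr - 1) * px / 1000,
               class = class, turnover_ratio = ratio)
  }
  rec <- rbind(mk_rec(5, 0.8), mk_rec(5, 0.8), mk_rec(12, 0.7),
               mk_rec(2, 0.9, "MDS"),
               data.frame(centroid_x_um = (ctr - 1) * px / 1000,
                          centroid_y_um = (ctr - 1) * px / 1000,
                          class = "mitochondrion", turnover_ratio = 0.5))
  rr <- radial_rings(rec, soma, px, ring_width_um = 10)
  expect_identical(rr$records$ring, c(0L, 0L, 1L, 0L, -1L))
  # every included object is in exactly one ring; counts add up
  expect_identical(sum(rr$rings$n), 4L)
  # identical ratios at identical distance: ring SD 0
  r0 <- rr$rings[rr$rings$ring == 0 & rr$rings$class == "mitochondrion", ]
  expect_identical(r0$sd, 0)
  expect_equal(r0$mean, 0.8)

  # half-open convention: distance exactly one ring width starts ring 1
  rec2 <- mk_rec(10, 0.5)
  rr2 <- radial_rings(rec2, soma, px, ring_width_um = 10)
  expect_identical(rr2$records$ring, 1L)
  # with 30-um rings, d = 45 um falls in ring 1 (coarser grid for reach)
  px4 <- 400
  rec3 <- data.frame(centroid_x_um = (ctr - 1 + rad_px) * px4 / 1000 + 45,
                     centroid_y_um = (ctr - 1) * px4 / 1000,
                     class = "mitochondrion", turnover_ratio = 0.5)
  expect_identical(radial_rings(rec3, soma, px4, ring_width_um = 30)$records$ring, 1L)
  expect_error(radial_rings(rec2, matrix(0L, n, n), px), "empty")
})

test_that("protrusion anchors classify by the quarters rule with marker calls", {
  parent <- list(centroid_um = c(x = 5, y = 5), angle_deg = 0, length_um = 2)
  anchor_at <- function(f) c(5 + (f - 0.5) * 2, 5.1)
  expect_identical(classify_protrusion(parent, anchor_at(0.10))$position_class, "tip")
  expect_identical(classify_protrusion(parent, anchor_at(0.40))$position_class, "side")
  expect_identical(classify_protrusion(parent, anchor_at(0.25))$position_class, "tip")
  expect_identical(classify_protrusion(parent, anchor_at(0.90))$position_class, "tip")
  expect_equal(classify_protrusion(parent, anchor_at(0.10))$axial_fraction, 0.1,
               tolerance = 1e-9)

  pr <- classify_protrusion(parent, anchor_at(0.4),
                            marker_means = c(PEX14 = 30, DRP1 = 4),
                            background = list(mean = 5, sd = 2), k = 2)
  expect_identical(unname(pr$marker_calls), c("+", "-"))
  expect_error(classify_protrusion(parent, anchor_at(0.4),
                                   marker_means = c(PEX14 = 30)),
               "background")
})

test_that("recovered tip fractions match the planted generator fraction", {
  cfg <- sim_config(n_mitochondria = 20L, n_mds = 0L, seed = 71,
                    length_range_um = c(1.2, 3.5),
                    protrusion_spec = list(n_protrusions = 14L, tip_fraction = 0.7,
                                           neck_width_nm = 100, length_nm = 250))
  f <- generate_field(cfg)
  expect_identical(nrow(f$protrusions), 14L)
  got <- vapply(seq_len(nrow(f$protrusions)), function(k) {
    p <- f$protrusions[k, ]
    tr <- f$truth[p$parent_id, ]
    parent <- list(centroid_um = c(x = tr$center_x_um, y = tr$center_y_um),
                   angle_deg = tr$angle_deg, length_um = tr$true_length_um)
    classify_protrusion(parent, c(p$anchor_x_um, p$anchor_y_um))$position_class
  }, character(1))
  # classification from geometry agrees with the planted labels
  expect_gte(mean(got == f$protrusions$position_class), 0.9)
  k_tip <- sum(f$protrusions$position_class == "tip")
  expect_gte(k_tip, qbinom(0.005, 14, 0.7))
  expect_lte(k_tip, qbinom(0.995, 14, 0.7))
})

test_that("contact-site linear density counts touching puncta once", {
  mito <- matrix(0L, 60, 60)
  mito[30, 5:55] <- 1L
  mito[29:31, 5:55] <- 1L
  puncta <- matrix(0L, 60, 60)
  puncta[32:33, 10] <- 1L   # adjacent (touching)
  puncta[30, 20] <- 1L      # overlapping
  puncta[45:46, 40:41] <- 1L  # far away
  res <- contact_site_density(mito, puncta, 25, 1000, distance_nm = 0)
  expect_identical(res$n_contacts, 2L)
  expect_identical(res$n_puncta, 3L)
  expect_equal(res$density_per_um, 2 / 25)

  expect_equal(contact_site_density(mito, matrix(0L, 60, 60), 25, 1000)$density_per_um, 0)
  expect_error(contact_site_density(mito, puncta, 0, 1000), "undefined")

  # widening the contact distance reaches the distant punctum
  res2 <- contact_site_density(mito, puncta, 25, 1000, distance_nm = 20000)
  expect_identical(res2$n_contacts, 3L)

  # planted 50% touching recovered exactly on noise-free masks
  set.seed(8)
  mito2 <- matrix(0L, 200, 200)
  mito2[100:102, 10:190] <- 1L
  p2 <- matrix(0L, 200, 200)
  rows_touch <- seq(10, 180, by = 20)
  for (i in seq_along(rows_touch)) {
    cc <- rows_touch[i]
    if (i %% 2 == 0) p2[103:104, cc] <- 1L else p2[130:131, cc] <- 1L
  }
  resp <- contact_site_density(mito2, p2, 18.1, 1000)
  expect_identical(resp$n_contacts, sum(seq_along(rows_touch) %% 2 == 0))
})

test_that("ring means follow a planted monotone turnover gradient", {
  # 120-um field at 50 nm/px: soma-centred gradient across two 30-um rings
  cfg <- sim_config(image_size_px = c(2400L, 2400L), pixel_size_nm = 50,
                    n_mitochondria = 40L, n_mds = 20L, n_paths = 10L,
                    turnover_gradient = c(0.8, -0.005), seed = 23)
  f <- generate_field(cfg)
  mask <- refine_mask(binarize_bernsen(f$structural, 9L, 15),
                      c("fill_holes", "erode:2", "remove_small:8"))
  mask <- apply_region_exclusion(mask, f$soma_mask)
  objs <- label_objects(mask, f$structural, cfg$pixel_size_nm)
  rec <- assemble_morph_records(objs)
  rec$turnover_ratio <- vapply(objs, function(o) {
    turnover_ratio(o, f$turnover_old, f$turnover_new)
  }, numeric(1))
  rr <- radial_rings(rec, f$soma_mask, cfg$pixel_size_nm, ring_width_um = 30)

  # recovered per-ring means sit within 0.05 of the planted means per ring
  planted_ring <- floor(pmax(f$truth$radial_distance_um, 0) / 30)
  for (k in unique(rr$rings$ring)) {
    got <- rr$rings$mean[rr$rings$ring == k]
    want <- mean(f$truth$true_turnover_ratio[planted_ring == k])
    expect_true(all(abs(got - want) < 0.05))
  }
  # ratios bounded and weakly decreasing with distance
  ok <- rr$records$ring >= 0 & is.finite(rr$records$turnover_ratio)
  expect_true(all(rr$records$turnover_ratio[ok] >= 0 &
                    rr$records$turnover_ratio[ok] <= 1))
  sp <- suppressWarnings(cor.test(rr$records$distance_um[ok],
                 rr$records$turnover_ratio[ok], method = "spearman"))
  expect_lte(sp$estimate, 0)
})
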