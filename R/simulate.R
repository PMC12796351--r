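#' Configuration for the synthetic STED-like field generator
#'
#' Bundles every knob of the simulator: geometry of the rendered organelles,
#' optics (pixel pitch and effective PSF), photon budget and noise, the
#' functional-state mixture, the pulse-chase turnover gradient, and
#' protrusion placement. Defaults emulate STED acquisitions of OMM-labeled
#' neuronal mitochondria: widths distributed around a ~140 nm mode, a
#' sub-threshold MDS population, membrane-only (hollow) tubules, Poisson
#' shot noise plus Gaussian read noise.
#'
#' @param image_size_px integer pair, image height and width in pixels.
#' @param pixel_size_nm physical pixel pitch (10--50 nm).
#' @param psf_sigma_nm sigma of the isotropic Gaussian effective PSF.
#' @param n_mitochondria,n_mds number of planted mitochondria / MDSs.
#' @param width_range_nm admissible tube widths (outer diameter), nm.
#' @param length_range_um admissible tip-to-tip lengths, um.
#' @param mds_area_max_um2 area ceiling for planted MDSs (classification
#'   threshold between mitochondria and mitochondrial-derived structures).
#' @param vesicle_fraction fraction of MDSs planted as round vesicles
#'   (aspect ratio 1); the rest are tubular sticks (aspect ratio < 0.5).
#' @param membrane_thickness_nm FWHM of the membrane ridge before PSF.
#' @param peak_intensity structural-channel ridge peak, photon counts.
#' @param background constant background level, counts.
#' @param noise_model list(poisson = logical, gaussian_read_sigma = counts).
#' @param functional_positive_fraction probability an object is planted
#'   functionally positive (e.g. polarized / ROS-positive).
#' @param functional_pos_mean,functional_pos_sd Gaussian brightness of
#'   positive objects in the functional channel.
#' @param functional_neg_mean mean of the exponential background brightness
#'   of negative objects.
#' @param turnover_gradient numeric pair (ratio_at_soma, ratio_slope_per_um):
#'   planted refreshment ratio new/(new+old) as a linear function of radial
#'   distance from the soma edge, clamped to [0, 1].
#' @param protrusion_spec list(n_protrusions, tip_fraction, neck_width_nm,
#'   length_nm): membrane protrusions planted on mitochondrial tubules.
#' @param min_gap_nm minimum edge-to-edge gap between planted objects;
#'   gaps below the PSF scale would make planted objects unresolvable in
#'   principle, so the default keeps neighbours separable.
#' @param soma_radius_um radius of the central soma disk.
#' @param n_paths number of neurite paths radiating from the soma.
#' @param seed integer RNG seed; identical (config, seed) gives
#'   bit-identical output.
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(image_size_px = c(1024L, 1024L),
                       pixel_size_nm = 25,
                       psf_sigma_nm = 25,
                       n_mitochondria = 30L,
                       n_mds = 20L,
                       width_range_nm = c(80, 500),
                       length_range_um = c(0.25, 4),
                       mds_area_max_um2 = 0.086,
                       vesicle_fraction = 0.6,
                       membrane_thickness_nm = 60,
                       peak_intensity = 150,
                       background = 5,
                       noise_model = list(poisson = TRUE, gaussian_read_sigma = 3),
                       functional_positive_fraction = 0.7,
                       functional_pos_mean = 200,
                       functional_pos_sd = 25,
                       functional_neg_mean = 20,
                       turnover_gradient = c(0.8, -0.005),
                       protrusion_spec = list(n_protrusions = 0L, tip_fraction = 0.7,
                                              neck_width_nm = 100, length_nm = 250),
                       min_gap_nm = 300,
                       soma_radius_um = 2.5,
                       n_paths = 8L,
                       seed = 1L) {
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 64))
  if (pixel_size_nm < 10 || pixel_size_nm > 50) {
    stop("pixel_size_nm must lie in [10, 50]")
  }
  if (width_range_nm[1] < 60 || width_range_nm[2] > 600) {
    stop("width_range_nm must lie within [60, 600] nm")
  }
  fracs <- c(vesicle_fraction, functional_positive_fraction,
             protrusion_spec$tip_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  cfg <- list(image_size_px = as.integer(image_size_px),
              pixel_size_nm = pixel_size_nm,
              psf_sigma_nm = psf_sigma_nm,
              n_mitochondria = as.integer(n_mitochondria),
              n_mds = as.integer(n_mds),
              width_range_nm = width_range_nm,
              length_range_um = length_range_um,
              mds_area_max_um2 = mds_area_max_um2,
              vesicle_fraction = vesicle_fraction,
              membrane_thickness_nm = membrane_thickness_nm,
              peak_intensity = peak_intensity,
              background = background,
              noise_model = noise_model,
              functional_positive_fraction = functional_positive_fraction,
              functional_pos_mean = functional_pos_mean,
              functional_pos_sd = functional_pos_sd,
              functional_neg_mean = functional_neg_mean,
              turnover_gradient = turnover_gradient,
              protrusion_spec = protrusion_spec,
              min_gap_nm = min_gap_nm,
              soma_radius_um = soma_radius_um,
              n_paths = as.integer(n_paths),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Footprint area of a capsule (stadium) shape
#'
#' Tip-to-tip length L and width W give a rectangle (L - W) x W plus two
#' half-disks of diameter W. For L = W this degenerates to a disk.
#'
#' @param length_um tip-to-tip length, um.
#' @param width_nm outer width, nm.
#' @return area in um^2.
#' @export
capsule_area_um2 <- function(length_um, width_nm) {
  w <- width_nm / 1000
  (length_um - w) * w + pi * (w / 2)^2
}

# signed geometry helper: distance of pixel grid points to a centreline
# segment of half-length hl (um), centred at (cx, cy), direction angle
# (deg, CCW from +x with y pointing up). Returns a matrix over the window.
# Rows map to y (down = increasing row), columns to x.
dist_to_segment <- function(rows, cols, cx, cy, hl, angle_deg, px_um) {
  th <- angle_deg * pi / 180
  ux <- cos(th); uy <- -sin(th)  # y axis points down in row space
  x <- (cols - 1) * px_um
  y <- (rows - 1) * px_um
  X <- matrix(x, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  Y <- matrix(y, nrow = length(rows), ncol = length(cols))
  dx <- X - cx; dy <- Y - cy
  t <- dx * ux + dy * uy
  t <- pmin(pmax(t, -hl), hl)
  sqrt((dx - t * ux)^2 + (dy - t * uy)^2)
}

# membrane ridge profile: Gaussian of (distance - W/2) with FWHM equal to
# the membrane thickness
ridge_intensity <- function(d_um, width_nm, thickness_nm) {
  sig <- thickness_nm / 2.35482 / 1000
  exp(-(d_um - width_nm / 2000)^2 / (2 * sig^2))
}

#' Render a single hollow-membrane capsule
#'
#' Draws the outline (membrane) of a capsule of the given tip-to-tip length
#' and width as a Gaussian ridge of the configured membrane thickness,
#' convolves it with the isotropic Gaussian PSF, and scales the ridge peak
#' to \code{cfg$peak_intensity}. No noise is applied. A cross-section
#' perpendicular to the axis shows the two membrane peaks when the width is
#' resolvable at the given PSF, or a single merged peak below the
#' resolution limit.
#'
#' @param length_um tip-to-tip length (um); equal to the width for a vesicle.
#' @param width_nm outer width (nm).
#' @param angle_deg axis orientation, degrees CCW from +x (y up).
#' @param cfg \code{\link{sim_config}}.
#' @param patch_size_px patch side length in pixels (square patch, object
#'   centred).
#' @return numeric matrix patch (counts, noise-free, zero background).
#' @export
render_membrane_object <- function(length_um, width_nm, angle_deg, cfg,
                                   patch_size_px = NULL) {
  px_um <- cfg$pixel_size_nm / 1000
  if (width_nm < cfg$width_range_nm[1] || width_nm > cfg$width_range_nm[2]) {
    stop("width outside configured range")
  }
  if (length_um * 1000 < width_nm) stop("length must be >= width (capsule geometry)")
  margin_um <- 4 * cfg$psf_sigma_nm / 1000 + 2 * cfg$membrane_thickness_nm / 1000
  need_um <- length_um + width_nm / 1000 + 2 * margin_um
  if (is.null(patch_size_px)) patch_size_px <- ceiling(need_um / px_um) + 1L
  if (patch_size_px * px_um < need_um) {
    stop("object geometry exceeds patch bounds; increase patch_size_px")
  }
  n <- as.integer(patch_size_px)
  if (n %% 2L == 0L) n <- n + 1L  # odd patch: object center on a pixel center
  cx <- (n - 1) / 2 * px_um
  cy <- cx
  hl <- max(length_um - width_nm / 1000, 0) / 2
  d <- dist_to_segment(seq_len(n), seq_len(n), cx, cy, hl, angle_deg, px_um)
  ridge <- ridge_intensity(d, width_nm, cfg$membrane_thickness_nm)
  blurred <- as.matrix(EBImage::gblur(ridge, sigma = cfg$psf_sigma_nm / cfg$pixel_size_nm))
  blurred / max(blurred) * cfg$peak_intensity
}

# sample geometry for one object; returns list(width_nm, length_um, shape)
sample_geometry <- function(class, cfg) {
  if (class == "mitochondrion") {
    for (i in 1:200) {
      w <- exp(stats::rnorm(1, log(140), 0.22))
      w <- min(max(w, cfg$width_range_nm[1]), cfg$width_range_nm[2])
      l <- exp(stats::rnorm(1, log(1.1), 0.45))
      l <- min(max(l, cfg$length_range_um[1]), cfg$length_range_um[2])
      l <- max(l, w / 1000)
      if (capsule_area_um2(l, w) >= 1.25 * cfg$mds_area_max_um2) {
        return(list(width_nm = w, length_um = l, shape = "stick"))
      }
    }
    stop("could not sample a mitochondrion geometry above the MDS area ceiling")
  }
  # MDS: target area below the ceiling, mode near 0.035 um^2
  for (i in 1:200) {
    a <- exp(stats::rnorm(1, log(0.035), 0.35))
    if (a >= 0.008 && a <= 0.92 * cfg$mds_area_max_um2) break
  }
  a <- min(max(a, 0.008), 0.92 * cfg$mds_area_max_um2)
  if (stats::runif(1) < cfg$vesicle_fraction) {
    w <- 2 * sqrt(a / pi) * 1000
    w <- min(max(w, cfg$width_range_nm[1]), cfg$width_range_nm[2])
    list(width_nm = w, length_um = w / 1000, shape = "vesicle")
  } else {
    ar <- stats::runif(1, 0.2, 0.45)
    w <- sqrt(a / (1 / ar - 1 + pi / 4)) * 1000
    w <- min(max(w, cfg$width_range_nm[1]), cfg$width_range_nm[2])
    list(width_nm = w, length_um = w / ar / 1000, shape = "stick")
  }
}

# build neurite polylines radiating from the soma rim
build_paths <- function(cfg) {
  px_um <- cfg$pixel_size_nm / 1000
  fov <- cfg$image_size_px * px_um
  ctr <- fov / 2
  lapply(seq_len(cfg$n_paths), function(k) {
    ang <- 2 * pi * (k - 1) / cfg$n_paths + stats::rnorm(1, 0, 0.15)
    pos <- c(ctr[2] + cfg$soma_radius_um * cos(ang),
             ctr[1] + cfg$soma_radius_um * sin(ang))  # (x, y)
    pts <- matrix(pos, ncol = 2)
    heading <- ang
    repeat {
      heading <- heading + stats::rnorm(1, 0, 0.25)
      pos <- pos + 1.5 * c(cos(heading), sin(heading))
      if (pos[1] < 0.5 || pos[2] < 0.5 ||
          pos[1] > fov[2] - 0.5 || pos[2] > fov[1] - 0.5) break
      pts <- rbind(pts, pos)
    }
    pts
  })
}

# pick a random point + direction along a polyline
sample_on_path <- function(path) {
  if (nrow(path) < 2L) return(NULL)
  seg <- sample.int(nrow(path) - 1L, 1L)
  p0 <- path[seg, ]; p1 <- path[seg + 1L, ]
  t <- stats::runif(1)
  pos <- p0 + t * (p1 - p0)
  ang_img <- atan2(p1[2] - p0[2], p1[1] - p0[1])  # y down
  list(x = pos[1], y = pos[2], angle_deg = -ang_img * 180 / pi)
}

#' Generate a synthetic field with ground truth
#'
#' Places hollow-membrane mitochondria and MDSs along neurite paths
#' radiating from a central soma disk, renders the structural channel
#' (ridge + PSF + Poisson/read noise), a functional channel whose
#' per-object brightness follows a two-component mixture (positive:
#' Gaussian; negative: exponential background), and a pulse-chase channel
#' pair whose per-object intensity split follows the planted radial
#' turnover gradient. Objects never overlap (planted protrusions attached
#' to a parent tubule are the one exception).
#'
#' @param cfg \code{\link{sim_config}}.
#' @return list of class \code{sim_field}: \code{structural},
#'   \code{functional}, \code{turnover_old}, \code{turnover_new} (count
#'   matrices), \code{soma_mask} (0/1 matrix), \code{truth} (ground-truth
#'   data.frame, one row per planted object), \code{protrusions}
#'   (data.frame, possibly empty), \code{cfg}.
#' @export
generate_field <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  px_um <- cfg$pixel_size_nm / 1000
  nr <- cfg$image_size_px[1]; nc <- cfg$image_size_px[2]
  fov <- c(nr, nc) * px_um
  ctr <- fov / 2  # (y, x)

  # soma disk mask
  rows_y <- (seq_len(nr) - 1) * px_um
  cols_x <- (seq_len(nc) - 1) * px_um
  DY <- matrix(rows_y - ctr[1], nr, nc)
  DX <- matrix(cols_x - ctr[2], nr, nc, byrow = TRUE)
  soma <- matrix(as.integer(sqrt(DX^2 + DY^2) <= cfg$soma_radius_um), nr, nc)

  paths <- build_paths(cfg)
  ridge_canvas <- matrix(0, nr, nc)
  fill_func <- matrix(0, nr, nc)
  fill_new <- matrix(0, nr, nc)
  fill_old <- matrix(0, nr, nc)
  # occupancy carries object ids (-1 soma, 0 free) so protrusions can be
  # collision-checked against everything except their own parent
  occupancy <- matrix(0L, nr, nc)
  occupancy[soma != 0] <- -1L
  margin_px <- max(2L, ceiling(cfg$min_gap_nm / cfg$pixel_size_nm))

  n_total <- cfg$n_mitochondria + cfg$n_mds
  classes <- c(rep("mitochondrion", cfg$n_mitochondria), rep("MDS", cfg$n_mds))
  truth <- vector("list", n_total)

  place_one <- function(geom) {
    for (attempt in 1:1000) {
      s <- sample_on_path(paths[[sample.int(length(paths), 1L)]])
      if (is.null(s)) next
      jit <- stats::rnorm(2, 0, 0.1)
      cx <- s$x + jit[1]; cy <- s$y + jit[2]
      ang <- s$angle_deg + stats::rnorm(1, 0, 8)
      half_extent <- geom$length_um / 2 + geom$width_nm / 2000
      pad_um <- half_extent + margin_px * px_um
      r0 <- floor((cy - pad_um) / px_um) + 1L; r1 <- ceiling((cy + pad_um) / px_um) + 1L
      c0 <- floor((cx - pad_um) / px_um) + 1L; c1 <- ceiling((cx + pad_um) / px_um) + 1L
      if (r0 < 1L || c0 < 1L || r1 > nr || c1 > nc) next
      rows <- r0:r1; cols <- c0:c1
      hl <- max(geom$length_um - geom$width_nm / 1000, 0) / 2
      d <- dist_to_segment(rows, cols, cx, cy, hl, ang, px_um)
      foot <- d <= geom$width_nm / 2000
      foot_marg <- d <= geom$width_nm / 2000 + margin_px * px_um
      if (any(occupancy[rows, cols] != 0L & foot_marg)) next
      return(list(cx = cx, cy = cy, angle = ang, rows = rows, cols = cols,
                  d = d, foot = foot))
    }
    NULL
  }

  grad <- cfg$turnover_gradient
  for (i in seq_len(n_total)) {
    geom <- sample_geometry(classes[i], cfg)
    pl <- place_one(geom)
    if (is.null(pl)) {
      stop(sprintf("could not place object %d of %d after 1000 attempts; reduce object count or enlarge the field", i, n_total))
    }
    occ_win <- occupancy[pl$rows, pl$cols]
    occ_win[pl$foot] <- i
    occupancy[pl$rows, pl$cols] <- occ_win
    ridge_canvas[pl$rows, pl$cols] <- ridge_canvas[pl$rows, pl$cols] +
      ridge_intensity(pl$d, geom$width_nm, cfg$membrane_thickness_nm)
    func_pos <- stats::runif(1) < cfg$functional_positive_fraction
    bright <- if (func_pos) {
      max(stats::rnorm(1, cfg$functional_pos_mean, cfg$functional_pos_sd), 1)
    } else {
      stats::rexp(1, 1 / cfg$functional_neg_mean)
    }
    fill_func[pl$rows, pl$cols] <- fill_func[pl$rows, pl$cols] + bright * pl$foot
    rad <- max(0, sqrt((pl$cx - ctr[2])^2 + (pl$cy - ctr[1])^2) - cfg$soma_radius_um)
    rho <- min(max(grad[1] + grad[2] * rad, 0), 1)
    turn_total <- 200
    fill_new[pl$rows, pl$cols] <- fill_new[pl$rows, pl$cols] + turn_total * rho * pl$foot
    fill_old[pl$rows, pl$cols] <- fill_old[pl$rows, pl$cols] + turn_total * (1 - rho) * pl$foot
    truth[[i]] <- data.frame(
      id = i,
      class = classes[i],
      shape = geom$shape,
      center_x_um = pl$cx, center_y_um = pl$cy,
      angle_deg = ((pl$angle + 90) %% 180) - 90,
      true_length_um = geom$length_um,
      true_width_nm = geom$width_nm,
      true_area_um2 = capsule_area_um2(geom$length_um, geom$width_nm),
      functional_state = if (func_pos) "+" else "-",
      true_turnover_ratio = rho,
      protrusion = "none",
      radial_distance_um = rad,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)

  # protrusions planted on mitochondrial tubules
  pspec <- cfg$protrusion_spec
  prot_rows <- list()
  if (pspec$n_protrusions > 0L) {
    eligible <- which(truth$class == "mitochondrion" &
                        truth$true_length_um * 1000 >= 3 * pspec$length_nm)
    if (length(eligible) == 0L) stop("no tubule long enough to host protrusions")
    for (k in seq_len(pspec$n_protrusions)) {
      placed <- FALSE
      for (attempt in 1:100) {
        pid <- eligible[sample.int(length(eligible), 1L)]
        tr <- truth[pid, ]
        frac <- if (stats::runif(1) < pspec$tip_fraction) {
          if (stats::runif(1) < 0.5) stats::runif(1, 0.03, 0.25) else stats::runif(1, 0.75, 0.97)
        } else stats::runif(1, 0.28, 0.72)
        th <- tr$angle_deg * pi / 180
        ux <- cos(th); uy <- -sin(th)
        px_ <- -uy; py_ <- ux  # perpendicular, row space
        side <- if (stats::runif(1) < 0.5) 1 else -1
        ax_off <- (frac - 0.5) * tr$true_length_um
        ax_off <- min(max(ax_off, -(tr$true_length_um - tr$true_width_nm / 1000) / 2),
                      (tr$true_length_um - tr$true_width_nm / 1000) / 2)
        anchor_x <- tr$center_x_um + ax_off * ux + side * tr$true_width_nm / 2000 * px_
        anchor_y <- tr$center_y_um + ax_off * uy + side * tr$true_width_nm / 2000 * py_
        plen <- pspec$length_nm / 1000
        pcx <- anchor_x + side * plen / 2 * px_
        pcy <- anchor_y + side * plen / 2 * py_
        pang_img <- atan2(side * py_, side * px_)
        pad_um <- plen / 2 + pspec$neck_width_nm / 2000 + margin_px * px_um
        r0 <- floor((pcy - pad_um) / px_um) + 1L
        r1 <- ceiling((pcy + pad_um) / px_um) + 1L
        c0 <- floor((pcx - pad_um) / px_um) + 1L
        c1 <- ceiling((pcx + pad_um) / px_um) + 1L
        if (r0 < 1L || c0 < 1L || r1 > nr || c1 > nc) next
        rows <- r0:r1; cols <- c0:c1
        hlp <- max(plen - pspec$neck_width_nm / 1000, 0) / 2
        d <- dist_to_segment(rows, cols, pcx, pcy, hlp, -pang_img * 180 / pi, px_um)
        foot <- d <= pspec$neck_width_nm / 2000
        foot_marg <- d <= pspec$neck_width_nm / 2000 + margin_px * px_um
        occ_win <- occupancy[rows, cols]
        if (any(occ_win != 0L & occ_win != pid & foot_marg)) next
        ridge_canvas[rows, cols] <- ridge_canvas[rows, cols] +
          ridge_intensity(d, pspec$neck_width_nm, cfg$membrane_thickness_nm)
        occ_win[foot] <- pid
        occupancy[rows, cols] <- occ_win
        pos_class <- if (frac <= 0.25 || frac >= 0.75) "tip" else "side"
        truth$protrusion[pid] <- pos_class
        prot_rows[[k]] <- data.frame(parent_id = tr$id, axial_fraction = frac,
                                     position_class = pos_class,
                                     anchor_x_um = anchor_x, anchor_y_um = anchor_y,
                                     neck_width_nm = pspec$neck_width_nm,
                                     stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place a protrusion without collisions")
    }
  }
  protrusions <- if (length(prot_rows)) do.call(rbind, prot_rows) else
    data.frame(parent_id = integer(), axial_fraction = numeric(),
               position_class = character(), anchor_x_um = numeric(),
               anchor_y_um = numeric(), neck_width_nm = numeric())

  # membranes that meet (protrusion necks on their parent tubule) form one
  # continuous surface, not a doubled label density
  ridge_canvas <- pmin(ridge_canvas, 1)

  psf_px <- cfg$psf_sigma_nm / cfg$pixel_size_nm
  apply_noise <- function(img) {
    out <- img
    if (isTRUE(cfg$noise_model$poisson)) out <- matrix(stats::rpois(length(out), pmax(out, 0)),
                                                       nrow(out), ncol(out))
    sig <- cfg$noise_model$gaussian_read_sigma
    if (!is.null(sig) && sig > 0) out <- out + stats::rnorm(length(out), 0, sig)
    pmax(out, 0)
  }
  blur_scale <- function(canvas, peak) {
    b <- as.matrix(EBImage::gblur(canvas, sigma = psf_px))
    if (max(b) > 0) b <- b / max(b) * peak
    b
  }
  structural <- apply_noise(blur_scale(ridge_canvas, cfg$peak_intensity) + cfg$background)
  functional <- apply_noise(as.matrix(EBImage::gblur(fill_func, sigma = psf_px)) + 1)
  turnover_new <- apply_noise(as.matrix(EBImage::gblur(fill_new, sigma = psf_px)) + 1)
  turnover_old <- apply_noise(as.matrix(EBImage::gblur(fill_old, sigma = psf_px)) + 1)

  structure(list(structural = structural,
                 functional = functional,
                 turnover_old = turnover_old,
                 turnover_new = turnover_new,
                 soma_mask = soma,
                 truth = truth,
                 protrusions = protrusions,
                 cfg = cfg),
            class = "sim_field")
}

#' Write a simulated field to disk
#'
#' Multi-page 16-bit TIFF (structural, functional, turnover old, turnover
#' new), an 8-bit soma-mask TIFF, the ground-truth table as CSV, and the
#' configuration (including the seed) as YAML.
#'
#' @param field a \code{sim_field}.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
write_field_bundle <- function(field, dir) {
  stopifnot(inherits(field, "sim_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  to16 <- function(m) pmin(pmax(m / 65535, 0), 1)
  pages <- lapply(list(field$structural, field$functional,
                       field$turnover_old, field$turnover_new), to16)
  f_img <- file.path(dir, "channels.tif")
  tiff::writeTIFF(pages, f_img, bits.per.sample = 16)
  f_soma <- file.path(dir, "soma_mask.tif")
  tiff::writeTIFF(pmin(field$soma_mask, 1), f_soma, bits.per.sample = 8)
  f_truth <- file.path(dir, "ground_truth.csv")
  utils::write.csv(field$truth, f_truth, row.names = FALSE)
  f_prot <- file.path(dir, "protrusions.csv")
  utils::write.csv(field$protrusions, f_prot, row.names = FALSE)
  f_cfg <- file.path(dir, "config.yaml")
  cfg <- field$cfg
  class(cfg) <- NULL
  yaml::write_yaml(cfg, f_cfg)
  invisible(c(channels = f_img, soma = f_soma, truth = f_truth,
              protrusions = f_prot, config = f_cfg))
}
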