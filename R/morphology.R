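#' Label connected components and fit ellipse parameters
#'
#' 8-connected component labeling of the binary mask, followed by per-object
#' particle analysis: pixel count and area, centroid, and an ellipse fit
#' from the normalized second central moments, rescaled so the ellipse area
#' equals the component area. The intensity image is multiplied with a
#' dilated copy of the mask to zero the background outside the organelles;
#' this masked intensity copy (used for line-profile extraction downstream)
#' is attached as an attribute.
#'
#' @param mask 0/1 matrix (structural binary mask).
#' @param img numeric matrix, the structural intensity channel (same shape).
#' @param pixel_size_nm physical pixel pitch in nanometres.
#' @param background_dilate_px radius (in 3x3-cross dilation passes) used to
#'   grow the mask before zeroing the background on the intensity copy.
#' @return list of labeled objects, each a list with \code{id}, \code{idx}
#'   (linear pixel indices), \code{rows}, \code{cols}, \code{n_px},
#'   \code{area_um2}, \code{centroid_um} (x, y), \code{major_um},
#'   \code{minor_um}, \code{angle_deg} in [-90, 90), and
#'   \code{pixel_size_nm}. Attributes: \code{masked_intensity} (matrix),
#'   \code{labels} (label matrix). An empty mask gives an empty list.
#' @export
label_objects <- function(mask, img, pixel_size_nm, background_dilate_px = 5L) {
  if (!all(dim(mask) == dim(img))) stop("mask and image shapes differ")
  lab <- label8(mask)
  n_obj <- max(lab)
  dil <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  for (i in seq_len(background_dilate_px)) dil <- as.matrix(EBImage::dilate(dil, cross3()))
  masked_intensity <- img * dil
  px_um <- pixel_size_nm / 1000
  objs <- vector("list", n_obj)
  if (n_obj > 0L) {
    ord <- order(lab[lab > 0L])
    idx_all <- which(lab > 0L)
    split_idx <- split(idx_all, lab[idx_all])
    for (k in seq_len(n_obj)) {
      idx <- split_idx[[as.character(k)]]
      rows <- ((idx - 1L) %% nrow(mask)) + 1L
      cols <- ((idx - 1L) %/% nrow(mask)) + 1L
      n_px <- length(idx)
      mx <- mean(cols); my <- mean(rows)
      # second central moments with the 1/12 single-pixel extent term
      mu20 <- mean((cols - mx)^2) + 1 / 12
      mu02 <- mean((rows - my)^2) + 1 / 12
      mu11 <- mean((cols - mx) * (rows - my))
      tr <- mu20 + mu02
      det_ <- mu20 * mu02 - mu11^2
      disc <- sqrt(max(tr^2 / 4 - det_, 0))
      l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
      a0 <- 2 * sqrt(l1); b0 <- 2 * sqrt(l2)
      s <- sqrt(n_px / (pi * a0 * b0))
      # image rows grow downward; report angle CCW with y up
      ang <- -0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
      ang <- ((ang + 90) %% 180) - 90
      objs[[k]] <- list(id = k, idx = idx, rows = rows, cols = cols,
                        n_px = n_px,
                        area_um2 = n_px * px_um^2,
                        centroid_um = c(x = (mx - 1) * px_um, y = (my - 1) * px_um),
                        major_um = 2 * a0 * s * px_um,
                        minor_um = 2 * b0 * s * px_um,
                        angle_deg = ang,
                        pixel_size_nm = pixel_size_nm)
    }
  }
  attr(objs, "masked_intensity") <- masked_intensity
  attr(objs, "labels") <- lab
  objs
}

#' Skeleton-based length of one labeled object
#'
#' Thins the component to a 1-pixel skeleton and sums the Euclidean branch
#' step lengths (1 or sqrt(2) pixels). A single-pixel skeleton has length 0.
#'
#' @param obj one element of \code{\link{label_objects}} output.
#' @return length in micrometres.
#' @export
skeleton_length <- function(obj) {
  if (obj$n_px == 0L) stop("empty object")
  r0 <- min(obj$rows); c0 <- min(obj$cols)
  patch <- matrix(0L, max(obj$rows) - r0 + 3L, max(obj$cols) - c0 + 3L)
  patch[cbind(obj$rows - r0 + 2L, obj$cols - c0 + 2L)] <- 1L
  skel <- skeletonize_mask(patch)
  skeleton_path_length_um(skel, obj$pixel_size_nm)
}

#' Axial extent of a labeled object
#'
#' Length of the projection of the object's pixel set onto its major axis
#' (Feret length along the fitted orientation) plus one pixel. For straight
#' tubules this tracks the tip-to-tip length without the elongation bias of
#' the moment ellipse; used e.g. to place protrusion anchors on the
#' quarters scale.
#'
#' @param obj one element of \code{\link{label_objects}} output.
#' @return extent in micrometres.
#' @export
object_axial_extent <- function(obj) {
  th <- obj$angle_deg * pi / 180
  ux <- cos(th); uy <- -sin(th)
  px_um <- obj$pixel_size_nm / 1000
  t <- ((obj$cols - 1) * px_um - obj$centroid_um[["x"]]) * ux +
    ((obj$rows - 1) * px_um - obj$centroid_um[["y"]]) * uy
  diff(range(t)) + px_um
}

#' Area-gated length selection
#'
#' Small objects (A < 0.2 um^2) take the ellipse major-axis length, which is
#' more accurate for small, non-branched shapes whose skeleton under-covers
#' the rounded caps; larger objects take the longer of the ellipse and
#' skeleton lengths. The boundary A = 0.2 um^2 is assigned to the "larger"
#' branch.
#'
#' @param A area in um^2.
#' @param L_ell ellipse major-axis length, um.
#' @param L_skel skeleton branch-length sum, um.
#' @return selected length, um.
#' @export
select_length <- function(A, L_ell, L_skel) {
  if (any(c(A, L_ell, L_skel) < 0)) stop("negative input")
  ifelse(A < 0.2, L_ell, pmax(L_ell, L_skel))
}

#' Classify an object as mitochondrion or MDS by area
#'
#' Mitochondrial-derived structures (MDSs) are defined as objects with area
#' strictly below the threshold A_th; the boundary value itself counts as a
#' mitochondrion.
#'
#' @param A area in um^2 (vectorized).
#' @param A_th area threshold, um^2 (default 0.086).
#' @return character vector, \code{"MDS"} or \code{"mitochondrion"}.
#' @export
classify_mds <- function(A, A_th = 0.086) {
  if (any(A < 0)) stop("negative area")
  ifelse(A < A_th, "MDS", "mitochondrion")
}

#' Classify MDS shape from the aspect ratio
#'
#' Aspect ratio AR = W / L. Round vesicles have AR in [0.5, 1] (inclusive at
#' 0.5); tubular sticks have AR < 0.5.
#'
#' @param AR aspect ratio in (0, 1] (vectorized).
#' @return character vector, \code{"vesicle"} or \code{"stick"}.
#' @export
classify_shape <- function(AR) {
  if (any(AR <= 0)) stop("aspect ratio must be positive")
  if (any(AR > 1)) stop("aspect ratio above 1: width/length convention violated upstream")
  ifelse(AR >= 0.5, "vesicle", "stick")
}

#' Assemble per-object morphometry records
#'
#' Builds the morphometry table from labeled objects: ellipse and skeleton
#' lengths, the selected length, MDS classification, aspect ratio (fitted
#' center width when available, otherwise the ellipse minor axis), and the
#' vesicle/stick shape class for MDSs. The aspect ratio is clamped to 1
#' (flagged in \code{qc}) when the measured width marginally exceeds the
#' selected length, as happens for near-circular vesicles.
#'
#' @param objects output of \code{\link{label_objects}}.
#' @param widths optional data.frame with columns \code{id},
#'   \code{width_center_nm} (W_m), \code{width_outer_nm} (W_o),
#'   \code{width_qc} (\code{"ok"} for accepted center fits), as produced by
#'   \code{\link{measure_object_widths}}.
#' @param A_th MDS area threshold, um^2.
#' @return data.frame, one row per object: id, centroid, angle, area,
#'   ellipse axes, skeleton length, selected length, widths, AR, width
#'   ratio W_o/W_m, class, shape, qc.
#' @export
assemble_morph_records <- function(objects, widths = NULL, A_th = 0.086) {
  if (length(objects) == 0L) {
    return(data.frame(id = integer(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), angle_deg = numeric(),
                      area_um2 = numeric(), ellipse_major_um = numeric(),
                      ellipse_minor_um = numeric(), skeleton_length_um = numeric(),
                      length_um = numeric(), width_center_nm = numeric(),
                      width_outer_nm = numeric(), width_nm = numeric(),
                      ar = numeric(), width_ratio = numeric(),
                      class = character(), shape = character(), qc = character()))
  }
  rec <- do.call(rbind, lapply(objects, function(o) {
    lsk <- skeleton_length(o)
    data.frame(id = o$id,
               centroid_x_um = o$centroid_um[["x"]],
               centroid_y_um = o$centroid_um[["y"]],
               angle_deg = o$angle_deg,
               area_um2 = o$area_um2,
               ellipse_major_um = o$major_um,
               ellipse_minor_um = o$minor_um,
               skeleton_length_um = lsk,
               stringsAsFactors = FALSE)
  }))
  rec$length_um <- select_length(rec$area_um2, rec$ellipse_major_um,
                                 rec$skeleton_length_um)
  rec$width_center_nm <- NA_real_
  rec$width_outer_nm <- NA_real_
  rec$qc <- "ok"
  if (!is.null(widths) && nrow(widths)) {
    m <- match(rec$id, widths$id)
    has <- !is.na(m)
    rec$width_center_nm[has] <- widths$width_center_nm[m[has]]
    rec$width_outer_nm[has] <- widths$width_outer_nm[m[has]]
    bad <- has & widths$width_qc[m[has]] != "ok"
    rec$qc[bad] <- "width_rejected"
    rec$width_center_nm[bad] <- NA_real_
  }
  rec$width_nm <- ifelse(is.finite(rec$width_center_nm), rec$width_center_nm,
                         rec$ellipse_minor_um * 1000)
  ar_raw <- (rec$width_nm / 1000) / rec$length_um
  clamped <- is.finite(ar_raw) & ar_raw > 1
  rec$qc[clamped & rec$qc == "ok"] <- "ar_clamped"
  rec$ar <- pmin(ar_raw, 1)
  rec$width_ratio <- rec$width_outer_nm / rec$width_center_nm
  rec$class <- classify_mds(rec$area_um2, A_th)
  rec$shape <- NA_character_
  is_mds <- rec$class == "MDS" & is.finite(rec$ar) & rec$ar > 0
  rec$shape[is_mds] <- classify_shape(rec$ar[is_mds])
  rownames(rec) <- NULL
  rec
}

#' Cohort-level morphometry summary
#'
#' Per-class histograms (MDS area with 0.01 um^2 bins, aspect ratio with 0.1
#' bins, width with 20 nm bins), modes and medians, the fraction of
#' mitochondrial widths in the 100--200 nm band, the fraction of
#' mitochondria longer than 10 um, and the MDS / mitochondria count ratio.
#'
#' @param records data.frame from \code{\link{assemble_morph_records}}.
#' @param area_bin,ar_bin,width_bin_nm histogram bin widths.
#' @return list of summary components; empty input gives an empty list.
#' @export
summarize_population <- function(records, area_bin = 0.01, ar_bin = 0.1,
                                 width_bin_nm = 20) {
  ok <- records[records$qc %in% c("ok", "ar_clamped"), , drop = FALSE]
  if (nrow(ok) == 0L) return(list())
  hist_of <- function(x, bin) {
    if (!length(x)) return(NULL)
    br <- seq(0, max(x, na.rm = TRUE) + bin, by = bin)
    h <- graphics::hist(x, breaks = br, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  }
  # mode estimate: median of the observations falling in the modal bin
  mode_of <- function(x, bin) {
    if (!length(x)) return(NA_real_)
    b <- floor(x / bin)
    tb <- table(b)
    modal <- as.numeric(names(tb)[which.max(tb)])
    stats::median(x[b == modal])
  }
  mds <- ok[ok$class == "MDS", , drop = FALSE]
  mito <- ok[ok$class == "mitochondrion", , drop = FALSE]
  widths <- ok$width_nm[is.finite(ok$width_nm)]
  wh <- hist_of(widths, width_bin_nm)
  ah <- hist_of(mds$area_um2, area_bin)
  arh <- hist_of(mds$ar[is.finite(mds$ar)], ar_bin)
  list(
    n_total = nrow(ok),
    n_mds = nrow(mds),
    n_mitochondria = nrow(mito),
    mds_mito_ratio = if (nrow(mito)) nrow(mds) / nrow(mito) else NA_real_,
    area_hist_mds = ah,
    area_mode_mds = mode_of(mds$area_um2, area_bin),
    area_median_mds = stats::median(mds$area_um2),
    ar_hist_mds = arh,
    width_hist = wh,
    width_mode_nm = mode_of(widths, width_bin_nm),
    width_median_nm = stats::median(widths),
    frac_width_100_200 = if (length(widths)) mean(widths >= 100 & widths <= 200) else NA_real_,
    frac_length_gt_10um = if (nrow(mito)) mean(mito$length_um > 10) else NA_real_,
    vesicle_fraction_mds = if (nrow(mds)) mean(mds$shape == "vesicle", na.rm = TRUE) else NA_real_
  )
}
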