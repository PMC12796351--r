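#' Anchor offsets for the three width profiles
#'
#' Profiles are taken at the object center and near the two endpoints along
#' the major axis. For short objects (L < 2.1 um) the end anchors sit at
#' L/6 and 5L/6; for long objects (L >= 2.1 um, boundary included) at
#' 350 nm and L - 350 nm, so the end profiles stay clear of the rounded
#' caps.
#'
#' @param L selected object length, um (> 0).
#' @return named numeric vector (end1, center, end2) of offsets along the
#'   axis from one tip, in um.
#' @export
profile_positions <- function(L) {
  stopifnot(L > 0)
  if (L < 2.1) {
    c(end1 = L / 6, center = L / 2, end2 = 5 * L / 6)
  } else {
    c(end1 = 0.35, center = L / 2, end2 = L - 0.35)
  }
}

#' Extract a perpendicular intensity line profile
#'
#' Samples the intensity along a 0.75-um line centred on the object axis at
#' the given axial offset, perpendicular to the object orientation, with
#' bilinear interpolation at 1-pixel steps, averaged over 5 parallel lines
#' spaced 1 pixel along the axis. Samples falling outside the image flag
#' the profile as truncated and are dropped from the average.
#'
#' @param img numeric matrix (background-masked intensity image).
#' @param obj labeled object (see \code{\link{label_objects}}).
#' @param anchor_offset_um axial offset of the profile anchor from the
#'   object tip, um (as returned by \code{\link{profile_positions}}).
#' @param L object length used to convert the offset to a position, um
#'   (defaults to the ellipse major axis).
#' @param profile_length_um total profile length, um.
#' @param n_lines number of parallel lines averaged.
#' @return list of class \code{line_profile}: \code{position_nm} (signed,
#'   centred on the axis), \code{intensity}, \code{anchor_offset_um},
#'   \code{truncated}, \code{object_id}.
#' @export
extract_profile <- function(img, obj, anchor_offset_um,
                            L = obj$major_um,
                            profile_length_um = 0.75, n_lines = 5L) {
  px_um <- obj$pixel_size_nm / 1000
  th <- obj$angle_deg * pi / 180
  ux <- cos(th); uy <- -sin(th)        # axis direction in (x, y-down) space
  vx <- -uy; vy <- ux                  # perpendicular
  ax_off <- anchor_offset_um - L / 2
  cx <- obj$centroid_um[["x"]] + ax_off * ux
  cy <- obj$centroid_um[["y"]] + ax_off * uy
  half <- profile_length_um / 2
  t <- seq(-half, half, by = px_um)
  lat <- (seq_len(n_lines) - (n_lines + 1) / 2) * px_um
  acc <- matrix(NA_real_, length(t), n_lines)
  for (j in seq_along(lat)) {
    sx <- cx + lat[j] * ux + t * vx
    sy <- cy + lat[j] * uy + t * vy
    acc[, j] <- bilinear_sample(img, sy / px_um + 1, sx / px_um + 1)
  }
  truncated <- anyNA(acc)
  intensity <- rowMeans(acc, na.rm = TRUE)
  keep <- is.finite(intensity)
  structure(list(position_nm = t[keep] * 1000,
                 intensity = intensity[keep],
                 anchor_offset_um = anchor_offset_um,
                 truncated = truncated,
                 object_id = obj$id),
            class = "line_profile")
}

#' Count peaks in a line profile
#'
#' Local maxima with prominence of at least a fraction of the profile
#' dynamic range and a minimum separation of two samples. A flat profile
#' has zero peaks.
#'
#' @param p \code{line_profile} (or list with \code{intensity}).
#' @param prominence_frac minimum prominence as a fraction of the dynamic
#'   range.
#' @param min_separation minimum index separation between accepted peaks.
#' @return integer peak count, with attribute \code{peaks} (indices).
#' @export
count_peaks <- function(p, prominence_frac = 0.1, min_separation = 2L) {
  y <- p$intensity
  n <- length(y)
  rng <- diff(range(y))
  if (n < 3L || rng <= 0) {
    return(structure(0L, peaks = integer()))
  }
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  # plateau maxima: flat tops yield no strict sign change
  if (!length(cand)) {
    imax <- which.max(y)
    if (imax > 1L && imax < n) cand <- imax
  }
  if (!length(cand)) return(structure(0L, peaks = integer()))
  # accept candidates by descending height; a candidate is a peak when the
  # saddle separating it from every already-accepted peak drops at least
  # the prominence threshold below it
  cand <- cand[order(-y[cand])]
  accepted <- integer()
  for (i in cand) {
    if (!length(accepted)) {
      accepted <- i
      next
    }
    if (any(abs(accepted - i) < min_separation)) next
    saddles <- c()
    left <- accepted[accepted < i]
    if (length(left)) saddles <- c(saddles, min(y[max(left):i]))
    right <- accepted[accepted > i]
    if (length(right)) saddles <- c(saddles, min(y[i:min(right)]))
    if ((y[i] - max(saddles)) >= prominence_frac * rng) accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  structure(length(accepted), peaks = accepted)
}

gauss1 <- function(x, b0, A, c1, s1) b0 + A * exp(-(x - c1)^2 / (2 * s1^2))
gauss2 <- function(x, b0, A1, c1, s1, A2, c2, s2) {
  b0 + A1 * exp(-(x - c1)^2 / (2 * s1^2)) + A2 * exp(-(x - c2)^2 / (2 * s2^2))
}

r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(0)
  1 - sum((y - yhat)^2) / sst
}

# Levenberg-Marquardt least squares through nls.lm (robust to the
# zero-residual case that breaks nls-model construction on noise-free data)
lm_fit <- function(x, y, model_fn, start, lower) {
  resid_fn <- function(p) y - do.call(model_fn, c(list(x), as.list(p)))
  fit <- tryCatch(minpack.lm::nls.lm(
    par = start, lower = lower, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) return(NULL)
  cf <- fit$par
  list(coef = cf, fitted = do.call(model_fn, c(list(x), as.list(cf))))
}

#' Gaussian-fit decision tree for one line profile
#'
#' One detected peak: single Gaussian plus constant baseline, width =
#' FWHM = 2*sqrt(2*ln 2)*sigma (this overestimates the true width when two
#' unresolved membranes merge into one peak, but is the best available
#' estimate there). Two peaks: double Gaussian plus baseline, width =
#' distance between the two fitted centers. Three or four peaks: likely two
#' objects side by side; the width is the mean adjacent peak distance from
#' the detected positions and the fit is flagged \code{side_by_side}
#' (excluded from non-width parameters downstream). More than four peaks,
#' a fit R-squared below the threshold, or a non-convergent fit rejects
#' the profile.
#'
#' @param p \code{line_profile}.
#' @param n_peaks peak count from \code{\link{count_peaks}} (its
#'   \code{peaks} attribute is used for initialization when present).
#' @param r2_threshold minimum R-squared for an accepted fit.
#' @param shared_sigma constrain both Gaussians of a double fit to one
#'   sigma.
#' @return list of class \code{peak_fit}: \code{model} (single, double,
#'   multi, rejected), \code{width_nm}, \code{width_source}, \code{r2},
#'   \code{pars}, \code{status}, \code{anchor_offset_um}.
#' @export
fit_width <- function(p, n_peaks, r2_threshold = 0.80, shared_sigma = FALSE) {
  x <- p$position_nm
  y <- p$intensity
  peaks <- attr(n_peaks, "peaks")
  n <- as.integer(n_peaks)
  rejected <- function(status) {
    structure(list(model = "rejected", width_nm = NA_real_,
                   width_source = NA_character_, r2 = NA_real_,
                   pars = NULL, status = status,
                   anchor_offset_um = p$anchor_offset_um),
              class = "peak_fit")
  }
  if (n == 0L) return(rejected("no_peak"))
  if (n > 4L) return(rejected("too_many_peaks"))
  if (n %in% c(3L, 4L)) {
    pos <- sort(x[peaks])
    return(structure(list(model = "multi",
                          width_nm = mean(diff(pos)),
                          width_source = "peak_distance", r2 = NA_real_,
                          pars = list(peak_positions_nm = pos),
                          status = "side_by_side",
                          anchor_offset_um = p$anchor_offset_um),
                     class = "peak_fit"))
  }
  b0_init <- min(y)
  if (n == 1L) {
    i1 <- if (length(peaks)) peaks[1] else which.max(y)
    fit <- lm_fit(x, y, gauss1,
                  start = c(b0 = b0_init, A = y[i1] - b0_init, c1 = x[i1], s1 = 60),
                  lower = c(b0 = -Inf, A = 0, c1 = min(x), s1 = 2))
    if (is.null(fit)) return(rejected("fit_failed"))
    cf <- fit$coef
    r2 <- r_squared(y, fit$fitted)
    if (r2 < r2_threshold) return(rejected("low_r2"))
    return(structure(list(model = "single",
                          width_nm = 2 * sqrt(2 * log(2)) * cf[["s1"]],
                          width_source = "fwhm", r2 = r2,
                          pars = as.list(cf), status = "ok",
                          anchor_offset_um = p$anchor_offset_um),
                     class = "peak_fit"))
  }
  # n == 2
  if (length(peaks) < 2L) peaks <- order(-y)[1:2]
  i1 <- min(peaks[1:2]); i2 <- max(peaks[1:2])
  if (shared_sigma) {
    gauss2s <- function(x, b0, A1, c1, s1, A2, c2) gauss2(x, b0, A1, c1, s1, A2, c2, s1)
    fit <- lm_fit(x, y, gauss2s,
                  start = c(b0 = b0_init, A1 = y[i1] - b0_init, c1 = x[i1],
                            s1 = 40, A2 = y[i2] - b0_init, c2 = x[i2]),
                  lower = c(b0 = -Inf, A1 = 0, c1 = min(x), s1 = 2,
                            A2 = 0, c2 = min(x)))
  } else {
    fit <- lm_fit(x, y, gauss2,
                  start = c(b0 = b0_init, A1 = y[i1] - b0_init, c1 = x[i1],
                            s1 = 40, A2 = y[i2] - b0_init, c2 = x[i2], s2 = 40),
                  lower = c(b0 = -Inf, A1 = 0, c1 = min(x), s1 = 2,
                            A2 = 0, c2 = min(x), s2 = 2))
  }
  if (is.null(fit)) return(rejected("fit_failed"))
  cf <- fit$coef
  r2 <- r_squared(y, fit$fitted)
  if (r2 < r2_threshold) return(rejected("low_r2"))
  structure(list(model = "double",
                 width_nm = abs(cf[["c2"]] - cf[["c1"]]),
                 width_source = "peak_distance", r2 = r2,
                 pars = as.list(cf), status = "ok",
                 anchor_offset_um = p$anchor_offset_um),
            class = "peak_fit")
}

#' Combine the three per-object profile fits into center and outer widths
#'
#' W_m is the center-anchor width; W_o is the mean of the accepted
#' end-anchor widths. The object fails width QC when the center fit is
#' rejected.
#'
#' @param fits list of three \code{peak_fit}s named \code{end1},
#'   \code{center}, \code{end2}.
#' @return list: \code{width_center_nm}, \code{width_outer_nm},
#'   \code{width_ratio} (W_o / W_m), \code{qc} (\code{"ok"} or a reason),
#'   \code{side_by_side}.
#' @export
object_width <- function(fits) {
  stopifnot(all(c("end1", "center", "end2") %in% names(fits)))
  ok <- vapply(fits, function(f) f$status %in% c("ok", "side_by_side"), logical(1))
  if (!any(ok)) {
    return(list(width_center_nm = NA_real_, width_outer_nm = NA_real_,
                width_ratio = NA_real_, qc = "all_rejected",
                side_by_side = FALSE))
  }
  side <- any(vapply(fits, function(f) identical(f$status, "side_by_side"), logical(1)))
  wc <- if (ok[["center"]]) fits$center$width_nm else NA_real_
  ends <- c(fits$end1$width_nm[ok[["end1"]]], fits$end2$width_nm[ok[["end2"]]])
  wo <- if (length(ends)) mean(ends) else NA_real_
  qc <- if (!ok[["center"]]) "center_rejected" else "ok"
  list(width_center_nm = wc, width_outer_nm = wo,
       width_ratio = if (is.finite(wc) && is.finite(wo)) wo / wc else NA_real_,
       qc = qc, side_by_side = side)
}

#' Measure widths for every labeled object
#'
#' Runs the full profile pipeline per object: anchor placement, profile
#' extraction from the background-masked intensity image, peak counting,
#' the Gaussian-fit decision tree, and the center/outer width combination.
#'
#' @param img background-masked intensity image (attribute
#'   \code{masked_intensity} of \code{\link{label_objects}} output).
#' @param objects list from \code{\link{label_objects}}.
#' @param lengths optional numeric vector of selected lengths (um) per
#'   object; defaults to each object's ellipse major axis.
#' @param r2_threshold,prominence_frac,shared_sigma fit and peak-detection
#'   settings (see \code{\link{fit_width}}, \code{\link{count_peaks}}).
#' @return data.frame with one row per object: \code{id},
#'   \code{width_center_nm}, \code{width_outer_nm}, \code{width_ratio},
#'   \code{n_peaks_center}, \code{width_qc}, \code{side_by_side}.
#' @export
measure_object_widths <- function(img, objects, lengths = NULL,
                                  r2_threshold = 0.80, prominence_frac = 0.1,
                                  shared_sigma = FALSE) {
  if (length(objects) == 0L) {
    return(data.frame(id = integer(), width_center_nm = numeric(),
                      width_outer_nm = numeric(), width_ratio = numeric(),
                      n_peaks_center = integer(), width_qc = character(),
                      side_by_side = logical()))
  }
  rows <- lapply(seq_along(objects), function(k) {
    obj <- objects[[k]]
    L <- if (is.null(lengths)) obj$major_um else lengths[k]
    offs <- profile_positions(max(L, 1e-6))
    fits <- lapply(offs, function(o) {
      pr <- extract_profile(img, obj, o, L = L)
      np <- count_peaks(pr, prominence_frac = prominence_frac)
      fit_width(pr, np, r2_threshold = r2_threshold, shared_sigma = shared_sigma)
    })
    names(fits) <- names(offs)
    ow <- object_width(fits)
    pr_c <- extract_profile(img, obj, offs[["center"]], L = L)
    data.frame(id = obj$id,
               width_center_nm = ow$width_center_nm,
               width_outer_nm = ow$width_outer_nm,
               width_ratio = ow$width_ratio,
               n_peaks_center = as.integer(count_peaks(pr_c, prominence_frac = prominence_frac)),
               width_qc = ow$qc,
               side_by_side = ow$side_by_side,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
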