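#' Global binarization
#'
#' Thresholds the structural channel at a fixed count level, or derives the
#' level automatically with the triangle rule on the intensity histogram
#' (maximal perpendicular distance from the peak-to-tail chord).
#'
#' @param img numeric matrix (counts).
#' @param threshold numeric count level, or \code{"auto"} for the triangle
#'   rule.
#' @return integer 0/1 mask with attributes \code{method}, \code{params},
#'   recording provenance.
#' @export
binarize_global <- function(img, threshold = "auto") {
  stopifnot(is.matrix(img), length(img) > 0)
  if (identical(threshold, "auto")) {
    thr <- triangle_threshold_values(as.vector(img))
  } else {
    thr <- as.numeric(threshold)
  }
  mask <- matrix(as.integer(img > thr), nrow(img), ncol(img))
  attr(mask, "method") <- "global"
  attr(mask, "params") <- list(threshold = thr, auto = identical(threshold, "auto"))
  mask
}

#' Local Bernsen binarization
#'
#' For each pixel, the local minimum and maximum over a disk of the given
#' radius define a midgray (min + max) / 2 and a local contrast
#' (max - min). High-contrast pixels (contrast >= \code{contrast}) are
#' thresholded at the local midgray; low-contrast pixels are assigned as a
#' block by comparing the local midgray against the global half-range, so
#' uniform background regions fall to background.
#'
#' @param img numeric matrix.
#' @param radius_px disk radius in pixels (>= 1).
#' @param contrast contrast gate in counts.
#' @return integer 0/1 mask with provenance attributes.
#' @export
binarize_bernsen <- function(img, radius_px = 9L, contrast = 15) {
  stopifnot(is.matrix(img))
  radius_px <- as.integer(radius_px)
  if (radius_px < 1L) stop("radius_px must be >= 1")
  if (2L * radius_px + 1L > min(dim(img))) stop("Bernsen radius larger than image")
  kern <- EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
  # EBImage grayscale morphology clamps to [0, 1]: normalize and restore
  mn <- min(img); mx <- max(img)
  rngv <- if (mx > mn) mx - mn else 1
  z <- (img - mn) / rngv
  lmin <- as.matrix(EBImage::erode(z, kern)) * rngv + mn
  lmax <- as.matrix(EBImage::dilate(z, kern)) * rngv + mn
  mid <- (lmin + lmax) / 2
  lcontrast <- lmax - lmin
  global_half <- (max(img) + min(img)) / 2
  fg <- ifelse(lcontrast >= contrast, img > mid, mid > global_half)
  mask <- matrix(as.integer(fg), nrow(img), ncol(img))
  attr(mask, "method") <- "bernsen"
  attr(mask, "params") <- list(radius_px = radius_px, contrast = contrast,
                               global_half = global_half)
  mask
}

#' Morphological refinement of a binary mask
#'
#' Applies an ordered list of morphological steps with a 3x3 cross
#' structuring element. Step names: \code{erode}, \code{dilate},
#' \code{open}, \code{close}, \code{fill_holes}, and
#' \code{remove_small(n)} (drop 8-connected components with fewer than
#' \code{n} pixels). Steps may carry a repeat count or argument after a
#' colon, e.g. \code{"dilate:3"}, \code{"remove_small:20"}.
#'
#' Disc-kernel variants \code{erode_disc:r} / \code{dilate_disc:r} apply a
#' single pass with a disc of radius r pixels (isotropic boundary shift,
#' used to strip the PSF halo around thresholded membranes).
#'
#' @param mask 0/1 matrix.
#' @param steps character vector of step names, applied in order; an empty
#'   vector returns the mask unchanged.
#' @return refined 0/1 mask (provenance attributes extended).
#' @export
refine_mask <- function(mask, steps = character()) {
  out <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  kern <- cross3()
  for (st in steps) {
    parts <- strsplit(st, ":", fixed = TRUE)[[1]]
    name <- parts[1]
    arg <- if (length(parts) > 1L) as.integer(parts[2]) else NA_integer_
    out <- switch(
      name,
      erode = {
        n <- if (is.na(arg)) 1L else arg
        m <- out
        for (i in seq_len(n)) m <- as.matrix(EBImage::erode(m, kern))
        m
      },
      dilate = {
        n <- if (is.na(arg)) 1L else arg
        m <- out
        for (i in seq_len(n)) m <- as.matrix(EBImage::dilate(m, kern))
        m
      },
      erode_disc = {
        r <- if (is.na(arg)) 1L else arg
        as.matrix(EBImage::erode(out, EBImage::makeBrush(2L * r + 1L, "disc")))
      },
      dilate_disc = {
        r <- if (is.na(arg)) 1L else arg
        as.matrix(EBImage::dilate(out, EBImage::makeBrush(2L * r + 1L, "disc")))
      },
      open = as.matrix(EBImage::dilate(as.matrix(EBImage::erode(out, kern)), kern)),
      close = as.matrix(EBImage::erode(as.matrix(EBImage::dilate(out, kern)), kern)),
      fill_holes = as.matrix(EBImage::fillHull(out)),
      remove_small = {
        n <- if (is.na(arg)) 20L else arg
        lab <- label8(out)
        if (max(lab) > 0L) {
          sizes <- tabulate(lab[lab > 0L])
          drop <- which(sizes < n)
          out[lab %in% drop] <- 0L
        }
        out
      },
      stop(sprintf("unknown refinement step '%s'", name))
    )
    out <- matrix(as.integer(out != 0), nrow(mask), ncol(mask))
  }
  attr(out, "method") <- attr(mask, "method")
  attr(out, "params") <- c(attr(mask, "params"), list(refine_steps = steps))
  out
}

#' Exclude a region (e.g. the soma) from a mask
#'
#' @param mask 0/1 matrix.
#' @param exclusion 0/1 matrix of the same shape; pixels set here are
#'   removed from \code{mask}.
#' @return 0/1 matrix \code{mask AND NOT exclusion}.
#' @export
apply_region_exclusion <- function(mask, exclusion) {
  if (!all(dim(mask) == dim(exclusion))) stop("mask and exclusion shapes differ")
  out <- matrix(as.integer(mask != 0 & exclusion == 0), nrow(mask), ncol(mask))
  attr(out, "method") <- attr(mask, "method")
  attr(out, "params") <- c(attr(mask, "params"), list(region_excluded = TRUE))
  out
}
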