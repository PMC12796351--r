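#' Build the neurite process map and measure its total length
#'
#' Recovers the neurite processes from the residual background fluorescence
#' of the structural channel: zero the soma, cap intensities at a high
#' quantile ceiling, triangle-rule global binarization, remove small
#' objects (< 20 px), dilate 20x and erode 15x (3x3 cross), keep the
#' largest connected component, then skeletonize and sum branch lengths.
#'
#' @param img structural channel, numeric matrix.
#' @param soma_mask 0/1 matrix (may be all zero).
#' @param pixel_size_nm pixel pitch, nm.
#' @param cap_quantile intensity ceiling quantile (applied before
#'   thresholding so bright organelles do not dominate the histogram).
#' @param small_px minimum component size kept before dilation.
#' @param n_dilate,n_erode dilation / erosion pass counts.
#' @return list of class \code{process_map}: \code{mask}, \code{skeleton},
#'   \code{total_length_um}, \code{params}. An image with no surviving
#'   foreground yields a zero-length map with a warning.
#' @export
build_process_map <- function(img, soma_mask = NULL, pixel_size_nm,
                              cap_quantile = 0.995, small_px = 20L,
                              n_dilate = 20L, n_erode = 15L) {
  work <- img
  if (!is.null(soma_mask)) {
    if (!all(dim(soma_mask) == dim(img))) stop("soma mask shape mismatch")
    work <- work * (soma_mask == 0)
  }
  ceiling_val <- stats::quantile(work, cap_quantile)
  work <- pmin(work, ceiling_val)
  thr <- tryCatch(triangle_threshold_values(as.vector(work)),
                  error = function(e) NA_real_)
  if (!is.finite(thr)) {
    warning("degenerate intensity histogram; zero-length process map")
    z <- matrix(0L, nrow(img), ncol(img))
    return(structure(list(mask = z, skeleton = z, total_length_um = 0,
                          params = list(threshold = NA_real_, cap = ceiling_val)),
                     class = "process_map"))
  }
  mask <- matrix(as.integer(work > thr), nrow(img), ncol(img))
  mask <- refine_mask(mask, c(sprintf("remove_small:%d", small_px),
                              sprintf("dilate:%d", n_dilate),
                              sprintf("erode:%d", n_erode)))
  mask <- largest_component(mask)
  if (!any(mask == 1L)) {
    warning("no process foreground survived filtering; zero-length map")
    return(structure(list(mask = mask, skeleton = mask, total_length_um = 0,
                          params = list(threshold = thr, cap = ceiling_val)),
                     class = "process_map"))
  }
  skel <- skeletonize_mask(mask)
  structure(list(mask = mask, skeleton = skel,
                 total_length_um = skeleton_path_length_um(skel, pixel_size_nm),
                 params = list(threshold = thr, cap = ceiling_val,
                               small_px = small_px, n_dilate = n_dilate,
                               n_erode = n_erode)),
            class = "process_map")
}

#' Number density of objects per unit process length
#'
#' @param counts named integer vector (e.g. c(mitochondrion = 30, MDS = 12)).
#' @param pm \code{process_map} (or a number, the total length in um).
#' @return named numeric vector of densities, per um.
#' @export
number_density <- function(counts, pm) {
  len <- if (inherits(pm, "process_map")) pm$total_length_um else as.numeric(pm)
  if (!is.finite(len) || len <= 0) stop("process length is zero; density undefined")
  counts / len
}

#' Pulse-chase refreshment ratio of one object
#'
#' R = sum(new) / (sum(old) + sum(new)) over the object's pixels: 1 means
#' fully refreshed protein within the chase interval, 0 none. A zero total
#' signal gives NA (excluded upstream with a log entry).
#'
#' @param obj labeled object.
#' @param ch_old,ch_new aligned channel matrices (old and new label).
#' @return ratio in [0, 1], or NA.
#' @export
turnover_ratio <- function(obj, ch_old, ch_new) {
  if (!all(dim(ch_old) == dim(ch_new))) stop("channel shapes differ")
  s_old <- sum(ch_old[obj$idx])
  s_new <- sum(ch_new[obj$idx])
  tot <- s_old + s_new
  if (tot <= 0) return(NA_real_)
  s_new / tot
}

#' Radial ring statistics from the soma outward
#'
#' Assigns each object to a concentric ring of the given thickness by the
#' Euclidean distance from its centroid to the soma-mask boundary
#' (half-open intervals [k w, (k+1) w)), and aggregates a per-object value
#' (e.g. the refreshment ratio) as mean and SD per ring, separately for
#' mitochondria and MDSs. Centroids inside the soma get ring -1 and are
#' excluded. Optionally normalizes the value by the ring-0 mean (proximal
#' normalization for expression-level differences).
#'
#' @param records data.frame with \code{centroid_x_um},
#'   \code{centroid_y_um}, \code{class}, and the value column.
#' @param soma_mask 0/1 matrix.
#' @param pixel_size_nm pixel pitch, nm.
#' @param value_col name of the per-object value column.
#' @param ring_width_um ring thickness, um (default 30).
#' @param normalize_proximal divide values by the ring-0 mean.
#' @return list: \code{records} (input plus \code{ring},
#'   \code{distance_um}), \code{rings} (data.frame: ring, class, inner/outer
#'   radius, n, mean, sd).
#' @export
radial_rings <- function(records, soma_mask, pixel_size_nm,
                         value_col = "turnover_ratio", ring_width_um = 30,
                         normalize_proximal = FALSE) {
  if (!any(soma_mask != 0)) stop("soma mask is empty")
  px_um <- pixel_size_nm / 1000
  dmap <- as.matrix(EBImage::distmap(matrix(as.numeric(soma_mask == 0),
                                            nrow(soma_mask), ncol(soma_mask)))) * px_um
  rr <- pmin(pmax(round(records$centroid_y_um / px_um) + 1, 1), nrow(soma_mask))
  cc <- pmin(pmax(round(records$centroid_x_um / px_um) + 1, 1), ncol(soma_mask))
  d <- dmap[cbind(rr, cc)]
  inside <- soma_mask[cbind(rr, cc)] != 0
  ring <- ifelse(inside, -1L, as.integer(floor(d / ring_width_um)))
  records$distance_um <- ifelse(inside, NA_real_, d)
  records$ring <- ring
  vals <- records[[value_col]]
  if (normalize_proximal) {
    base <- mean(vals[ring == 0L], na.rm = TRUE)
    if (is.finite(base) && base > 0) {
      vals <- vals / base
      records[[paste0(value_col, "_norm")]] <- vals
    }
  }
  keep <- ring >= 0L & is.finite(vals)
  if (!any(keep)) {
    rings <- data.frame(ring = integer(), class = character(),
                        inner_um = numeric(), outer_um = numeric(),
                        n = integer(), mean = numeric(), sd = numeric())
  } else {
    grp <- interaction(ring[keep], records$class[keep], drop = TRUE)
    agg <- lapply(split(seq_len(sum(keep)), grp), function(ii) {
      v <- vals[keep][ii]
      k <- ring[keep][ii][1]
      data.frame(ring = k, class = records$class[keep][ii][1],
                 inner_um = k * ring_width_um,
                 outer_um = (k + 1) * ring_width_um,
                 n = length(v), mean = mean(v), sd = stats::sd(v),
                 stringsAsFactors = FALSE)
    })
    rings <- do.call(rbind, agg)
    rings <- rings[order(rings$class, rings$ring), ]
    rownames(rings) <- NULL
  }
  list(records = records, rings = rings)
}

#' Classify a protrusion as tip or side, and call its markers
#'
#' Projects the protrusion anchor onto the parent tubule's major axis,
#' divides the tubule length into quarters, and classifies anchors in the
#' two extremity quarters (axial fraction <= 0.25 or >= 0.75, boundaries
#' inclusive to the extremities) as tip, the middle two quarters as side.
#' For each marker channel, the protrusion is called positive when its
#' mean footprint intensity exceeds the background mean by at least
#' k background SDs.
#'
#' @param parent list with \code{centroid_um} (x, y), \code{angle_deg},
#'   \code{length_um} of the parent tubule.
#' @param anchor_um numeric pair (x, y): protrusion anchor on the parent
#'   boundary, um.
#' @param marker_means optional named numeric vector of mean marker
#'   intensities at the protrusion footprint.
#' @param background optional list(mean, sd) of the neurite background
#'   reference (within filaments, outside labeled structures).
#' @param k positivity gate in background SDs.
#' @return list: \code{axial_fraction}, \code{position_class}
#'   (\code{"tip"}/\code{"side"}), \code{marker_calls} (named +/- vector,
#'   possibly empty).
#' @export
classify_protrusion <- function(parent, anchor_um, marker_means = NULL,
                                background = NULL, k = 2) {
  th <- parent$angle_deg * pi / 180
  ux <- cos(th); uy <- -sin(th)
  dx <- anchor_um[1] - parent$centroid_um[["x"]]
  dy <- anchor_um[2] - parent$centroid_um[["y"]]
  t <- dx * ux + dy * uy
  frac <- min(max(t / parent$length_um + 0.5, 0), 1)
  pos_class <- if (frac <= 0.25 || frac >= 0.75) "tip" else "side"
  calls <- character()
  if (!is.null(marker_means)) {
    if (is.null(background)) stop("marker calls need a background reference")
    calls <- ifelse(marker_means > background$mean + k * background$sd, "+", "-")
    names(calls) <- names(marker_means)
  }
  list(axial_fraction = frac, position_class = pos_class, marker_calls = calls)
}

#' Linear density of marker puncta contacting mitochondria
#'
#' A punctum (8-connected component of the puncta mask) contacts a
#' mitochondrion when its boundary-to-boundary distance to the
#' mitochondrial mask is at most \code{distance_nm}; the default 0 counts
#' overlapping or pixel-adjacent puncta. Density = contacting puncta per
#' um of summed selected mitochondrial length.
#'
#' @param mito_mask 0/1 matrix of mitochondria.
#' @param puncta_mask 0/1 matrix of marker puncta.
#' @param total_length_um summed selected lengths of the mitochondria, um.
#' @param pixel_size_nm pixel pitch, nm.
#' @param distance_nm maximum boundary-to-boundary contact distance.
#' @return list: \code{n_contacts}, \code{n_puncta},
#'   \code{density_per_um}.
#' @export
contact_site_density <- function(mito_mask, puncta_mask, total_length_um,
                                 pixel_size_nm, distance_nm = 0) {
  if (!all(dim(mito_mask) == dim(puncta_mask))) stop("mask shapes differ")
  if (!is.finite(total_length_um) || total_length_um <= 0) {
    stop("total mitochondrial length is zero; density undefined")
  }
  lab <- label8(puncta_mask)
  n_puncta <- max(lab)
  if (n_puncta == 0L) {
    return(list(n_contacts = 0L, n_puncta = 0L, density_per_um = 0))
  }
  reach <- matrix(as.integer(mito_mask != 0), nrow(mito_mask), ncol(mito_mask))
  # one 3x3-box pass captures 8-adjacency (boundary distance 0); extra
  # passes extend the reach by one pixel pitch each
  n_pass <- 1L + floor(distance_nm / pixel_size_nm)
  for (i in seq_len(n_pass)) {
    reach <- as.matrix(EBImage::dilate(reach, EBImage::makeBrush(3, "box")))
  }
  touched <- unique(lab[lab > 0L & reach > 0])
  list(n_contacts = length(touched), n_puncta = n_puncta,
       density_per_um = length(touched) / total_length_um)
}
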