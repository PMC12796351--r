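#' Read a multi-channel TIFF bundle
#'
#' Loads TIFF pages, assigns them to named roles, and coerces mask roles to
#' 0/1. Pixel size comes from the caller's configuration (microscopy TIFF
#' metadata dialects are unreliable); 8- and 16-bit inputs are both
#' accepted and returned on their native count scale.
#'
#' @param path path to a multi-page TIFF, or a character vector of
#'   single-page TIFFs.
#' @param roles character vector naming each page in order, e.g.
#'   \code{c("structural", "functional", "soma")}. Roles containing
#'   \code{"mask"} or equal to \code{"soma"} are binarized.
#' @return named list of matrices.
#' @export
read_image_bundle <- function(path, roles) {
  pages <- list()
  for (p in path) {
    got <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(got)) got <- list(got)
    pages <- c(pages, got)
  }
  if (length(pages) < length(roles)) {
    stop(sprintf("bundle has %d pages but %d roles were requested (role missing)",
                 length(pages), length(roles)))
  }
  pages <- pages[seq_along(roles)]
  dims <- vapply(pages, function(m) paste(dim(m)[1:2], collapse = "x"), character(1))
  if (length(unique(dims)) != 1L) stop("channel shapes differ across pages")
  out <- lapply(seq_along(roles), function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m <- matrix(as.numeric(m), nrow(m), ncol(m))
    if (grepl("mask", roles[i]) || roles[i] == "soma") {
      m <- matrix(as.integer(m > 0), nrow(m), ncol(m))
    }
    m
  })
  names(out) <- roles
  out
}

#' Run the full analysis pipeline on one field
#'
#' Segmentation (global or Bernsen, refinement, soma exclusion), object
#' labeling and morphometry, profile-based widths, functional +/- calls,
#' and the spatial statistics, driven by one configuration list. Stages
#' whose input channels are missing are skipped with a warning and listed
#' in the manifest.
#'
#' @param images named list of matrices: \code{structural} required;
#'   optional \code{functional}, \code{turnover_old}, \code{turnover_new},
#'   \code{soma}.
#' @param pixel_size_nm pixel pitch, nm.
#' @param method \code{"global"} or \code{"bernsen"}.
#' @param threshold global threshold (counts or \code{"auto"}).
#' @param bernsen_radius_px,bernsen_contrast Bernsen parameters.
#' @param refine_steps morphology step list for \code{\link{refine_mask}};
#'   \code{NULL} selects a method-matched default that strips the PSF halo
#'   so the mask tracks the object footprint (Bernsen: fill holes, two
#'   cross erosions, drop < 12 px; global: fill holes, disc-3 erosion,
#'   drop < 5 px).
#' @param A_th MDS area threshold, um^2.
#' @param min_px components smaller than this are discarded before
#'   morphometry.
#' @param r2_threshold width-fit acceptance threshold.
#' @param measure_widths run the line-profile width stage.
#' @param ring_width_um ring thickness for the radial turnover analysis.
#' @param min_call_n minimum object count for a functional threshold fit.
#' @param image_id identifier recorded in the call table.
#' @param out_dir optional directory; when given, tables are written as CSV
#'   and the manifest as JSON.
#' @return list of class \code{pipeline_result}: \code{mask},
#'   \code{objects}, \code{records}, \code{widths}, \code{calls},
#'   \code{call_model}, \code{turnover} (records + rings), \code{summary},
#'   \code{skipped}, \code{manifest}.
#' @export
run_pipeline <- function(images, pixel_size_nm,
                         method = c("bernsen", "global"),
                         threshold = "auto",
                         bernsen_radius_px = 9L, bernsen_contrast = 15,
                         refine_steps = NULL,
                         A_th = 0.086, min_px = 5L,
                         r2_threshold = 0.80,
                         measure_widths = TRUE,
                         ring_width_um = 30,
                         min_call_n = 30L,
                         image_id = "image1",
                         out_dir = NULL) {
  method <- match.arg(method)
  if (is.null(images$structural)) stop("structural channel is required")
  if (is.null(refine_steps)) {
    refine_steps <- if (method == "bernsen") {
      c("fill_holes", "erode:2", "remove_small:12")
    } else {
      c("fill_holes", "erode_disc:3", "remove_small:5")
    }
  }
  img <- images$structural
  skipped <- character()

  mask <- if (method == "global") {
    binarize_global(img, threshold)
  } else {
    binarize_bernsen(img, bernsen_radius_px, bernsen_contrast)
  }
  mask <- refine_mask(mask, refine_steps)
  if (!is.null(images$soma)) mask <- apply_region_exclusion(mask, images$soma)

  objects <- label_objects(mask, img, pixel_size_nm)
  masked_int <- attr(objects, "masked_intensity")

  widths <- NULL
  if (measure_widths && length(objects)) {
    lengths <- vapply(objects, function(o) o$major_um, numeric(1))
    widths <- measure_object_widths(masked_int, objects, lengths = lengths,
                                    r2_threshold = r2_threshold)
  } else if (measure_widths) {
    skipped <- c(skipped, "widths(no objects)")
  }
  records <- assemble_morph_records(objects, widths = widths, A_th = A_th)

  calls <- NULL; call_model <- NULL
  if (!is.null(images$functional)) {
    means <- object_mean_signal(objects, images$functional)
    if (length(means) >= min_call_n) {
      call_model <- fit_threshold(means, min_n = min_call_n)
      calls <- call_objects(means, call_model, image_id = image_id)
      calls$class <- records$class[match(calls$id, records$id)]
    } else {
      skipped <- c(skipped, "functional(too few objects)")
      warning("functional stage skipped: too few objects for a threshold fit")
    }
  } else {
    skipped <- c(skipped, "functional(channel missing)")
  }

  turnover <- NULL
  if (!is.null(images$turnover_old) && !is.null(images$turnover_new)) {
    records$turnover_ratio <- vapply(objects, function(o) {
      turnover_ratio(o, images$turnover_old, images$turnover_new)
    }, numeric(1))
    if (!is.null(images$soma) && any(images$soma != 0)) {
      turnover <- radial_rings(records, images$soma, pixel_size_nm,
                               value_col = "turnover_ratio",
                               ring_width_um = ring_width_um)
      records <- turnover$records
    }
  } else if (!is.null(images$turnover_old) || !is.null(images$turnover_new)) {
    skipped <- c(skipped, "turnover(channel pair incomplete)")
    warning("turnover stage skipped: both label channels are required")
  } else {
    skipped <- c(skipped, "turnover(channels missing)")
  }

  manifest <- list(pixel_size_nm = pixel_size_nm, method = method,
                   threshold = if (identical(threshold, "auto")) "auto" else threshold,
                   applied_threshold = attr(mask, "params")$threshold,
                   bernsen_radius_px = bernsen_radius_px,
                   bernsen_contrast = bernsen_contrast,
                   refine_steps = refine_steps, A_th = A_th,
                   min_px = min_px, r2_threshold = r2_threshold,
                   ring_width_um = ring_width_um, min_call_n = min_call_n,
                   image_id = image_id, skipped = skipped,
                   n_objects = length(objects))

  res <- structure(list(mask = mask, objects = objects, records = records,
                        widths = widths, calls = calls, call_model = call_model,
                        turnover = turnover,
                        summary = summarize_population(records),
                        skipped = skipped, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' Write pipeline tables and manifest to a directory
#'
#' Stable column order, comma-separated UTF-8 CSVs; manifest (every
#' parameter that affects the outputs) as JSON.
#'
#' @param res \code{pipeline_result}.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    paths[[name]] <<- f
  }
  wr(res$records, "morph_records.csv")
  if (!is.null(res$widths)) wr(res$widths, "width_fits.csv")
  if (!is.null(res$calls)) wr(res$calls, "call_table.csv")
  if (!is.null(res$turnover)) wr(res$turnover$rings, "ring_stats.csv")
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(res$manifest, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths[["manifest.json"]] <- f
  invisible(paths)
}
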