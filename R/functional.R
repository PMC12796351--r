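#' Per-object mean channel intensity
#'
#' Arithmetic mean of a functional channel (TMRE, MitoSOX, lysosome,
#' marker) over each object's pixel set.
#'
#' @param objects list from \code{\link{label_objects}}.
#' @param ch numeric matrix, aligned with the structural image.
#' @return numeric vector of means, named by object id.
#' @export
object_mean_signal <- function(objects, ch) {
  if (length(objects)) {
    d <- dim(attr(objects, "labels"))
    if (!is.null(d) && !all(d == dim(ch))) stop("channel not aligned with structural image")
  }
  out <- vapply(objects, function(o) mean(ch[o$idx]), numeric(1))
  names(out) <- vapply(objects, function(o) as.character(o$id), character(1))
  out
}

#' Fit the per-image positive/negative intensity threshold
#'
#' Histograms the per-object mean intensities (Freedman--Diaconis bin
#' width, floored at 12 bins) and fits counts with an exponential decay
#' (background population) plus a Gaussian (true signal population):
#' f(x) = a exp(-b x) + A exp(-(x - mu)^2 / (2 sigma^2)). The threshold t*
#' is the local minimum of the fitted f between the background mode at 0
#' and the Gaussian mean, located on a dense grid. The intersection point
#' of the two fitted components is computed alongside for comparison. If
#' the fit fails or the fitted f has no interior valley, the threshold
#' falls back to Otsu's rule on the means, flagged.
#'
#' @param means numeric vector of per-object mean intensities.
#' @param min_n minimum number of objects required.
#' @return list of class \code{threshold_model}: \code{threshold},
#'   \code{status} (\code{"ok"} or \code{"fallback"}), \code{pars},
#'   \code{r2}, \code{intersection}, \code{hist} (data.frame mid/count),
#'   \code{bin_width}.
#' @export
fit_threshold <- function(means, min_n = 30L) {
  means <- means[is.finite(means)]
  if (length(means) < min_n) {
    stop(sprintf("need at least %d objects to fit a threshold, got %d",
                 min_n, length(means)))
  }
  fallback <- function(h, bw, reason) {
    structure(list(threshold = otsu_threshold_values(means),
                   status = "fallback", fallback_reason = reason,
                   pars = NULL, r2 = NA_real_, intersection = NA_real_,
                   hist = h, bin_width = bw),
              class = "threshold_model")
  }
  rng <- diff(range(means))
  if (rng <= 0) {
    h <- data.frame(mid = means[1], count = length(means))
    return(fallback(h, 0, "degenerate"))
  }
  bw_fd <- 2 * stats::IQR(means) / length(means)^(1 / 3)
  n_bins <- max(12L, if (bw_fd > 0) ceiling(rng / bw_fd) else 12L)
  br <- seq(min(means), max(means), length.out = n_bins + 1L)
  hh <- graphics::hist(means, breaks = br, plot = FALSE)
  h <- data.frame(mid = hh$mids, count = hh$counts)
  bw <- diff(br[1:2])

  # initialization: decay rate from the lower quartile, Gaussian from the
  # upper-half mode
  q25 <- stats::quantile(means, 0.25)
  b_init <- 1 / max(mean(means[means <= q25]), bw)
  upper <- h[h$mid > stats::median(means), , drop = FALSE]
  mu_init <- if (nrow(upper)) upper$mid[which.max(upper$count)] else max(means)
  sig_init <- max(stats::sd(means[means > stats::median(means)]), bw)
  a_init <- max(h$count)
  A_init <- max(upper$count, 1)

  fit <- tryCatch(minpack.lm::nlsLM(
    count ~ a * exp(-b * mid) + A * exp(-(mid - mu)^2 / (2 * sigma^2)),
    data = h,
    start = list(a = a_init, b = b_init, A = A_init, mu = mu_init, sigma = sig_init),
    lower = c(a = 0, b = 1e-8, A = 0, mu = min(means), sigma = bw / 4),
    control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback(h, bw, "fit_failed"))
  cf <- as.list(stats::coef(fit))
  r2 <- r_squared(h$count, stats::predict(fit))
  if (cf$mu <= 0) return(fallback(h, bw, "non_bimodal"))

  grid <- seq(max(min(means), 0), cf$mu, length.out = 2000L)
  f <- cf$a * exp(-cf$b * grid) + cf$A * exp(-(grid - cf$mu)^2 / (2 * cf$sigma^2))
  im <- which.min(f)
  interior <- im > 1L && im < length(grid)
  if (!interior) return(fallback(h, bw, "non_bimodal"))
  tstar <- grid[im]

  diffc <- cf$a * exp(-cf$b * grid) - cf$A * exp(-(grid - cf$mu)^2 / (2 * cf$sigma^2))
  sgn <- sign(diffc)
  cross <- which(diff(sgn) != 0)
  intersection <- if (length(cross)) grid[cross[length(cross)]] else NA_real_

  structure(list(threshold = tstar, status = "ok", fallback_reason = NA_character_,
                 pars = cf, r2 = r2, intersection = intersection,
                 hist = h, bin_width = bw),
            class = "threshold_model")
}

#' Call objects positive or negative against a threshold model
#'
#' An object is positive when its mean channel intensity exceeds the
#' per-image threshold t*.
#'
#' @param means named numeric vector from \code{\link{object_mean_signal}}.
#' @param model \code{threshold_model} from \code{\link{fit_threshold}}.
#' @param image_id identifier recorded per row (thresholds are per image).
#' @return data.frame: \code{id}, \code{mean_intensity}, \code{call}
#'   (\code{"+"} / \code{"-"}), \code{image_id}, \code{threshold}.
#' @export
call_objects <- function(means, model, image_id = "image1") {
  stopifnot(inherits(model, "threshold_model"))
  data.frame(id = if (is.null(names(means))) seq_along(means) else
               as.integer(names(means)),
             mean_intensity = as.numeric(means),
             call = ifelse(means > model$threshold, "+", "-"),
             image_id = image_id,
             threshold = model$threshold,
             stringsAsFactors = FALSE)
}

#' Colocalization calling against a second organelle channel
#'
#' Applies the same per-image threshold machinery to a marker channel
#' (e.g. a lysosome label) and reports, per object class, the fraction of
#' positive objects — e.g. the MDS-Lyso+ / total-MDS ratio.
#'
#' @param objects list from \code{\link{label_objects}}.
#' @param marker_channel numeric matrix.
#' @param classes optional character vector of per-object classes (from
#'   \code{\link{assemble_morph_records}}); enables per-class ratios.
#' @param min_n minimum object count for the threshold fit.
#' @param image_id image identifier.
#' @return list: \code{calls} (data.frame as in \code{\link{call_objects}},
#'   plus \code{class} when given), \code{model}, \code{positive_fraction},
#'   and \code{fraction_by_class} (named vector) when classes are given.
#' @export
colocalization_call <- function(objects, marker_channel, classes = NULL,
                                min_n = 30L, image_id = "image1") {
  means <- object_mean_signal(objects, marker_channel)
  model <- fit_threshold(means, min_n = min_n)
  calls <- call_objects(means, model, image_id = image_id)
  out <- list(calls = calls, model = model,
              positive_fraction = mean(calls$call == "+"))
  if (!is.null(classes)) {
    calls$class <- classes
    out$calls <- calls
    out$fraction_by_class <- tapply(calls$call == "+", calls$class, mean)
  }
  out
}
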