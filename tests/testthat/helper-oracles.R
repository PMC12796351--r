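# Independent oracles used across the suite. These re-derive expected
# values by brute force or dense numerics and never call the code paths
# they check.

# Dense 1-D forward model of a membrane cross-section: capsule ridge
# profile (Gaussian of |x| - W/2 with the membrane-thickness FWHM)
# convolved with the Gaussian PSF. Returns positions/intensity plus the
# prominent-peak positions under the same 10% prominence rule the peak
# detector documents.
oracle_cross_section <- function(width_nm, psf_sigma_nm = 25,
                                 thickness_nm = 60, half_span_nm = 400,
                                 step_nm = 0.25, prominence_frac = 0.1) {
  x <- seq(-half_span_nm, half_span_nm, by = step_nm)
  sm <- thickness_nm / (2 * sqrt(2 * log(2)))
  pre <- exp(-(abs(x) - width_nm / 2)^2 / (2 * sm^2))
  kx <- seq(-6 * psf_sigma_nm, 6 * psf_sigma_nm, by = step_nm)
  k <- exp(-kx^2 / (2 * psf_sigma_nm^2))
  k <- k / sum(k)
  f <- stats::filter(pre, k, sides = 2)
  keep <- !is.na(f)
  x <- x[keep]; f <- as.numeric(f[keep])
  cand <- which(diff(sign(diff(f))) < 0) + 1L
  if (!length(cand)) cand <- which.max(f)  # plateau top
  rng <- diff(range(f))
  # twin ridges merge when the valley between them rises to within the
  # prominence threshold of the peaks; otherwise both survive
  if (length(cand) >= 2L) {
    valley <- min(f[min(cand):max(cand)])
    if (max(f[cand]) - valley < prominence_frac * rng) {
      peaks <- cand[which.max(f[cand])]
    } else {
      peaks <- cand[(f[cand] - valley) >= prominence_frac * rng]
    }
  } else {
    peaks <- cand
  }
  list(position_nm = x, intensity = f, peak_positions_nm = x[peaks],
       n_peaks = length(peaks))
}

# Brute-force Bernsen rule, evaluated pixel by pixel from the kernel
# offsets; local min/max over the kernel-image intersection.
bernsen_brute <- function(img, radius_px, contrast) {
  kern <- EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
  offs <- which(kern == 1, arr.ind = TRUE)
  offs <- offs - (radius_px + 1L)
  gh <- (max(img) + min(img)) / 2
  out <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      ii <- i + offs[, 1]; jj <- j + offs[, 2]
      ok <- ii >= 1 & ii <= nrow(img) & jj >= 1 & jj <= ncol(img)
      v <- img[cbind(ii[ok], jj[ok])]
      lmin <- min(v); lmax <- max(v)
      mid <- (lmin + lmax) / 2
      out[i, j] <- if ((lmax - lmin) >= contrast) {
        as.integer(img[i, j] > mid)
      } else {
        as.integer(mid > gh)
      }
    }
  }
  out
}

# Independent moment-based ellipse fit: covariance eigendecomposition via
# eigen(), area-preserving rescale. Mirrors the definition, not the code.
ellipse_moments_oracle <- function(rows, cols, pixel_size_nm) {
  px_um <- pixel_size_nm / 1000
  n <- length(rows)
  cx <- mean(cols); cy <- mean(rows)
  C <- matrix(c(mean((cols - cx)^2) + 1 / 12,
                mean((cols - cx) * (rows - cy)),
                mean((cols - cx) * (rows - cy)),
                mean((rows - cy)^2) + 1 / 12), 2, 2)
  ev <- eigen(C, symmetric = TRUE)
  a0 <- 2 * sqrt(ev$values[1]); b0 <- 2 * sqrt(max(ev$values[2], 1e-12))
  s <- sqrt(n / (pi * a0 * b0))
  v <- ev$vectors[, 1]
  ang <- -atan2(v[2], v[1]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  list(major_um = 2 * a0 * s * px_um, minor_um = 2 * b0 * s * px_um,
       angle_deg = ang)
}

# Rasterize a filled ellipse mask (axes in px, angle deg CCW, y up).
draw_ellipse_mask <- function(n, a_px, b_px, angle_deg = 0) {
  ctr <- (n + 1) / 2
  th <- angle_deg * pi / 180
  m <- matrix(0L, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      x <- j - ctr; y <- -(i - ctr)
      u <- x * cos(th) + y * sin(th)
      v <- -x * sin(th) + y * cos(th)
      if ((u / a_px)^2 + (v / b_px)^2 <= 1) m[i, j] <- 1L
    }
  }
  m
}

# Coarse-grid + polish least-squares Gaussian fit oracle for line profiles.
# Single: baseline + one Gaussian (FWHM width). Double: baseline + two
# Gaussians (center-distance width). Grid over centers/sigma, then optim().
grid_fit_oracle <- function(x, y, n_peaks) {
  sse1 <- function(p) {
    yhat <- p[1] + p[2] * exp(-(x - p[3])^2 / (2 * p[4]^2))
    sum((y - yhat)^2)
  }
  sse2 <- function(p) {
    yhat <- p[1] + p[2] * exp(-(x - p[3])^2 / (2 * p[4]^2)) +
      p[5] * exp(-(x - p[6])^2 / (2 * p[7]^2))
    sum((y - yhat)^2)
  }
  b0 <- min(y); amp <- max(y) - b0
  if (n_peaks == 1L) {
    grid <- expand.grid(c = seq(min(x), max(x), length.out = 41),
                        s = seq(10, 200, length.out = 30))
    errs <- mapply(function(cc, ss) sse1(c(b0, amp, cc, ss)), grid$c, grid$s)
    best <- grid[which.min(errs), ]
    fit <- stats::optim(c(b0, amp, best$c, best$s), sse1,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    2 * sqrt(2 * log(2)) * abs(fit$par[4])
  } else {
    grid <- expand.grid(c1 = seq(min(x), 0, length.out = 25),
                        c2 = seq(0, max(x), length.out = 25),
                        s = seq(15, 80, length.out = 12))
    errs <- mapply(function(c1, c2, ss) sse2(c(b0, amp, c1, ss, amp, c2, ss)),
                   grid$c1, grid$c2, grid$s)
    best <- grid[which.min(errs), ]
    fit <- stats::optim(c(b0, amp, best$c1, best$s, amp, best$c2, best$s),
                        sse2, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    abs(fit$par[6] - fit$par[3])
  }
}

# Analytic valley of the functional-intensity mixture density
# w_bg * Exp(rate) + w_sig * Normal(mu, sd), located on a dense grid.
mixture_valley_oracle <- function(w_sig = 0.3, rate = 1 / 20, mu = 200, sd = 25) {
  x <- seq(0.1, mu, by = 0.05)
  g <- (1 - w_sig) * stats::dexp(x, rate) + w_sig * stats::dnorm(x, mu, sd)
  x[which.min(g)]
}

# Minimal labeled-object stub for profile tests (geometry only).
make_obj <- function(cx_um, cy_um, angle_deg, major_um, pixel_size_nm = 25,
                     id = 1L) {
  list(id = id, centroid_um = c(x = cx_um, y = cy_um), angle_deg = angle_deg,
       major_um = major_um, pixel_size_nm = pixel_size_nm, n_px = 1L)
}

# Noise-free simulator configuration shared by several tests.
noise_free_cfg <- function(...) {
  sim_config(noise_model = list(poisson = FALSE, gaussian_read_sigma = 0), ...)
}
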