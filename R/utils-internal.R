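# Internal helpers: skeletonization, 8-connected labeling, interpolation,
# histogram threshold rules. Not exported unless noted.

#' Topological skeleton of a binary mask
#'
#' Already-thin curves (fixed points of Zhang--Suen) pass through
#' unchanged, so a 1-pixel path keeps its exact geometry. Thick shapes are
#' thinned with Guo--Hall two-subiteration thinning, which avoids the
#' 2-pixel diagonal staircase residue Zhang--Suen leaves on oblique bars.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer 0/1 matrix of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  img <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(img == 1L)) return(img)
  z <- thin_zhang_suen(img, max_iter = 1L)
  if (identical(z, img)) return(img)
  thin_guo_hall(img)
}

thin_zhang_suen <- function(img, max_iter = Inf) {
  nr <- nrow(img); nc <- ncol(img)
  ir <- 2:(nr + 1L); ic <- 2:(nc + 1L)
  iter <- 0L
  repeat {
    changed <- FALSE
    iter <- iter + 1L
    if (iter > max_iter) break
    for (step in 1:2) {
      p <- matrix(0L, nr + 2L, nc + 2L)
      p[ir, ic] <- img
      # neighbours in clockwise order starting north
      P2 <- p[ir - 1L, ic];     P3 <- p[ir - 1L, ic + 1L]
      P4 <- p[ir, ic + 1L];     P5 <- p[ir + 1L, ic + 1L]
      P6 <- p[ir + 1L, ic];     P7 <- p[ir + 1L, ic - 1L]
      P8 <- p[ir, ic - 1L];     P9 <- p[ir - 1L, ic - 1L]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
           (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
           (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
           (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      if (step == 1L) {
        cond <- (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        cond <- (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      del <- img == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

thin_guo_hall <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  ir <- 2:(nr + 1L); ic <- 2:(nc + 1L)
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      p <- matrix(0L, nr + 2L, nc + 2L)
      p[ir, ic] <- img
      P2 <- p[ir - 1L, ic];     P3 <- p[ir - 1L, ic + 1L]
      P4 <- p[ir, ic + 1L];     P5 <- p[ir + 1L, ic + 1L]
      P6 <- p[ir + 1L, ic];     P7 <- p[ir + 1L, ic - 1L]
      P8 <- p[ir, ic - 1L];     P9 <- p[ir - 1L, ic - 1L]
      C <- ((1L - P2) & (P3 | P4)) + ((1L - P4) & (P5 | P6)) +
           ((1L - P6) & (P7 | P8)) + ((1L - P8) & (P9 | P2))
      N1 <- (P9 | P2) + (P3 | P4) + (P5 | P6) + (P7 | P8)
      N2 <- (P2 | P3) + (P4 | P5) + (P6 | P7) + (P8 | P9)
      N <- pmin(N1, N2)
      m <- if (step == 0L) ((P6 | P7 | (1L - P9)) & P8) else
        ((P2 | P3 | (1L - P5)) & P4)
      del <- img == 1L & C == 1L & N >= 2L & N <= 3L & m == 0L
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

#' Euclidean path length of a skeleton
#'
#' Sums unit steps between 4-adjacent skeleton pixels and sqrt(2) steps
#' between diagonal neighbours. A diagonal step is skipped when the two
#' pixels already share a 4-adjacent skeleton pixel (the path runs through
#' the corner, so the diagonal would double-count it). A single isolated
#' skeleton pixel has length 0.
#'
#' @param skel 0/1 matrix (skeleton).
#' @param pixel_size_nm physical pixel pitch in nanometres.
#' @return length in micrometres.
#' @export
skeleton_path_length_um <- function(skel, pixel_size_nm) {
  s <- matrix(as.integer(skel != 0), nrow(skel), ncol(skel))
  if (sum(s) < 2L) return(0)
  nr <- nrow(s); nc <- ncol(s)
  p <- matrix(0L, nr + 2L, nc + 2L)
  ir <- 2:(nr + 1L); ic <- 2:(nc + 1L)
  p[ir, ic] <- s
  E  <- p[ir, ic + 1L]; S  <- p[ir + 1L, ic]
  SE <- p[ir + 1L, ic + 1L]; SW <- p[ir + 1L, ic - 1L]
  W  <- p[ir, ic - 1L]
  n_straight <- sum(s * E) + sum(s * S)
  # diagonal SE valid unless E or S neighbour bridges the corner
  diag_se <- s * SE * (1L - pmax(E, S))
  diag_sw <- s * SW * (1L - pmax(W, S))
  n_diag <- sum(diag_se) + sum(diag_sw)
  (n_straight + sqrt(2) * n_diag) * pixel_size_nm / 1000
}

# 8-connected labeling: EBImage::bwlabel is 4-connected; merge labels that
# touch diagonally with a union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nmax <- max(lab)
  if (nmax <= 1L) return(lab)
  parent <- seq_len(nmax)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),  # SE
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))   # SW
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  remap <- match(root, sort(unique(root)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# Bilinear interpolation at fractional (row, col) positions (1-based).
# Positions outside the image return NA.
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  v <- (1 - fr) * (1 - fc) * img[cbind(r0, c0)] +
       (1 - fr) * fc       * img[cbind(r0, c0 + 1L)] +
       fr       * (1 - fc) * img[cbind(r0 + 1L, c0)] +
       fr       * fc       * img[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- v
  out
}

# Triangle threshold rule on a numeric vector (histogram geometry:
# maximal perpendicular distance from the peak-to-tail chord).
triangle_threshold_values <- function(x, n_bins = 256L) {
  if (length(unique(x)) < 2L) {
    stop("triangle threshold undefined for a constant input (degenerate histogram)")
  }
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  ipk <- which.max(counts)
  # use the longer tail from the peak
  left_span <- ipk - 1L
  right_span <- length(counts) - ipk
  if (right_span >= left_span) {
    idx <- ipk:length(counts)
  } else {
    idx <- rev(1:ipk)
  }
  cts <- counts[idx]
  n <- length(cts)
  if (n < 3L) return(mids[ipk])
  # chord from (1, peak) to (n, tail end); distance of each point to it
  x1 <- 1; y1 <- cts[1]; x2 <- n; y2 <- cts[n]
  xs <- seq_len(n); ys <- cts
  d <- abs((y2 - y1) * xs - (x2 - x1) * ys + x2 * y1 - y2 * x1)
  ib <- which.max(d)
  mids[idx[ib]]
}

# Otsu threshold on a numeric vector (between-class variance maximization).
otsu_threshold_values <- function(x, n_bins = 256L) {
  if (length(unique(x)) < 2L) return(x[1])
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  w <- h$counts / sum(h$counts)
  m <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * m)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  m[which.max(sigma_b)]
}

# largest connected component (8-connected) of a binary mask
largest_component <- function(mask) {
  lab <- label8(mask)
  if (max(lab) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  tab <- tabulate(lab[lab > 0L])
  keep <- which.max(tab)
  matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
}

cross3 <- function() EBImage::makeBrush(3, shape = "diamond")
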