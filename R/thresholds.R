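#' Histogram of an intensity image
#'
#' Fixed-width 256-bin histogram over the observed intensity range, the
#' basis of both histogram thresholding methods used by the pipeline.
#'
#' @param img Numeric matrix.
#' @param n_bins Number of bins.
#' @return A list with `counts`, `mids`, `breaks` (length `n_bins + 1`).
#' @export
image_histogram <- function(img, n_bins = 256) {
  v <- as.vector(img)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("image has no finite pixels", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    # degenerate: all mass in one bin
    breaks <- seq(lo - 0.5, lo + 0.5, length.out = n_bins + 1)
  } else {
    breaks <- seq(lo, hi, length.out = n_bins + 1)
  }
  idx <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  list(counts = counts, mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
       breaks = breaks)
}

#' Triangle threshold of a histogram
#'
#' Geometric thresholding for skewed histograms: draw the line from the
#' histogram peak to the far end of its longer tail, and take the bin whose
#' point `(bin, count)` lies farthest (perpendicular distance) from that
#' line. Used to estimate the dark background peak of fluorescence images.
#'
#' @param counts Integer vector of histogram counts.
#' @return The threshold bin index (1-based); pixels in bins at or below it
#'   are background when the tail is on the right.
#' @export
triangle_threshold_bin <- function(counts) {
  n <- length(counts)
  nz <- which(counts > 0)
  if (length(nz) == 0) stop("empty histogram", call. = FALSE)
  peak <- which.max(counts)
  low <- nz[1]; high <- nz[length(nz)]
  if (low == high) return(low)
  flipped <- (peak - low) > (high - peak)  # long tail on the left: mirror
  h <- if (flipped) rev(counts) else counts
  p <- if (flipped) n - peak + 1 else peak
  tail_bin <- if (flipped) n - low + 1 else high
  if (tail_bin <= p) {
    t <- p
  } else {
    b <- p:tail_bin
    # |cross product| of (tail - peak) x (bin - peak); denominator constant
    d <- abs((tail_bin - p) * (h[p] - h[b]) - (p - b) * (h[tail_bin] - h[p]))
    t <- b[which.max(d)]
  }
  if (flipped) n - t + 1 else t
}

#' Huang minimum-fuzziness threshold of a histogram
#'
#' For each candidate threshold the pixels are split into background and
#' foreground with means `mu0`, `mu1`; each grey level gets a fuzzy
#' membership `u = 1 / (1 + |g - mu| / C)` (C = grey-level range) to its own
#' side, and the threshold minimizing the total Shannon entropy of the
#' memberships, `sum(counts * S(u))` with `S(u) = -u log u - (1-u) log(1-u)`,
#' is returned.
#'
#' @param counts Histogram counts.
#' @param mids Bin centres (grey levels); defaults to bin indices.
#' @return Threshold bin index: bins above it are foreground.
#' @export
huang_threshold_bin <- function(counts, mids = seq_along(counts)) {
  n <- length(counts)
  nz <- which(counts > 0)
  if (length(nz) == 0) stop("empty histogram", call. = FALSE)
  first <- nz[1]; last <- nz[length(nz)]
  if (first == last) return(first)
  cw <- cumsum(counts * mids)
  cn <- cumsum(counts)
  tw <- cw[n]; tn <- cn[n]
  C <- mids[last] - mids[first]
  shannon <- function(u) {
    s <- numeric(length(u))
    inner <- u > 1e-12 & u < 1 - 1e-12
    ui <- u[inner]
    s[inner] <- -ui * log(ui) - (1 - ui) * log(1 - ui)
    s
  }
  best_t <- first; best_e <- Inf
  for (t in first:(last - 1)) {
    mu0 <- cw[t] / cn[t]
    mu1 <- (tw - cw[t]) / (tn - cn[t])
    u <- c(1 / (1 + abs(mids[1:t] - mu0) / C),
           1 / (1 + abs(mids[(t + 1):n] - mu1) / C))
    e <- sum(counts * shannon(u))
    if (e < best_e - 1e-12) {
      best_e <- e; best_t <- t
    }
  }
  best_t
}

#' Triangle background estimation and subtraction
#'
#' Computes the Triangle threshold on the image histogram, takes the mean of
#' all pixels at or below the threshold as the background level, and
#' subtracts it from every pixel (values may go negative; masking happens
#' later).
#'
#' @param img Numeric matrix.
#' @param n_bins Histogram bins.
#' @return A list with `background_mean`, `threshold` (intensity value) and
#'   `corrected` (matrix).
#' @export
triangle_background <- function(img, n_bins = 256) {
  v <- as.vector(img)
  if (length(v) == 0) stop("empty image", call. = FALSE)
  if (max(v) == min(v)) {
    return(list(background_mean = v[1], threshold = v[1],
                corrected = img - v[1]))
  }
  h <- image_histogram(img, n_bins)
  t_bin <- triangle_threshold_bin(h$counts)
  thr <- h$breaks[t_bin + 1]
  bg <- mean(img[img <= thr])
  list(background_mean = bg, threshold = thr, corrected = img - bg)
}

# Circular offsets with radius r (squared distance <= r^2), incl. centre.
disc_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, ]
}

#' Median smoothing with a circular neighbourhood
#'
#' Sliding median over the disc of the given radius (13 pixels at radius 2),
#' with replicated borders; output is floating point. Removes shot noise
#' before masking and segmentation.
#'
#' @param img Numeric matrix (background-corrected).
#' @param radius Neighbourhood radius in pixels.
#' @return Filtered numeric matrix of the same size.
#' @export
preprocess_frame <- function(img, radius = 2) {
  nr <- nrow(img); nc <- ncol(img)
  off <- disc_offsets(radius)
  k <- nrow(off)
  stack <- matrix(0, nr * nc, k)
  ri <- seq_len(nr); ci <- seq_len(nc)
  for (j in seq_len(k)) {
    rs <- pmin(pmax(ri + off$dy[j], 1), nr)
    cs <- pmin(pmax(ci + off$dx[j], 1), nc)
    stack[, j] <- as.vector(img[rs, cs])
  }
  matrix(matrixStats::rowMedians(stack), nr, nc)
}

#' Huang fuzzy cell mask
#'
#' Computes the Huang minimal-fuzziness threshold on the image histogram and
#' sets every pixel at or below it (intensity close to background) to `NaN`;
#' the binary mask is true where the image exceeds the threshold.
#'
#' @param img Preprocessed numeric matrix.
#' @param n_bins Histogram bins.
#' @return A list with `mask` (logical matrix), `masked` (matrix with `NaN`
#'   background) and `threshold`.
#' @export
huang_mask <- function(img, n_bins = 256) {
  v <- as.vector(img)
  if (max(v) == min(v)) {
    if (v[1] <= 0) {
      # uniform at/below zero after background subtraction: no signal
      warning("Huang mask is empty: image appears to be all background",
              call. = FALSE)
      masked <- img
      masked[] <- NaN
      return(list(mask = matrix(FALSE, nrow(img), ncol(img)),
                  masked = masked, threshold = v[1]))
    }
    # uniform bright image: everything is foreground
    return(list(mask = matrix(TRUE, nrow(img), ncol(img)), masked = img,
                threshold = v[1] - 1))
  }
  h <- image_histogram(img, n_bins)
  t_bin <- huang_threshold_bin(h$counts, h$mids)
  thr <- h$breaks[t_bin + 1]
  mask <- img > thr
  if (!any(mask)) {
    warning("Huang mask is empty: image appears to be all background",
            call. = FALSE)
  }
  masked <- img
  masked[!mask] <- NaN
  list(mask = mask, masked = masked, threshold = thr)
}
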