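# Pixel-level primitives shared by the bead and network pipelines:
# flat-field correction, variance filtering, FFT band-pass, histogram
# auto-thresholds and binary morphology.

# ---- Fourier-domain Gaussian smoothing ------------------------------------
# A Gaussian low-pass applied in the frequency domain, with mirror padding
# to suppress wrap-around. Used both for flat-field estimation (where sigma
# is of the order of a bead diameter and a spatial kernel would exceed the
# image) and as the building block of the band-pass filter.
fft_gaussian_lowpass <- function(img, sigma) {
  stopifnot(sigma > 0)
  nr <- nrow(img); nc <- ncol(img)
  pr <- min(nr, ceiling(3 * sigma))
  pc <- min(nc, ceiling(3 * sigma))
  pad <- img
  if (pr > 0)
    pad <- rbind(pad[pr:1, , drop = FALSE], pad, pad[nr:(nr - pr + 1), , drop = FALSE])
  if (pc > 0)
    pad <- cbind(pad[, pc:1, drop = FALSE], pad, pad[, nc:(nc - pc + 1), drop = FALSE])
  Nr <- nrow(pad); Nc <- ncol(pad)
  fr <- c(0:floor(Nr / 2), -((Nr - floor(Nr / 2) - 1):1))[seq_len(Nr)] / Nr
  fc <- c(0:floor(Nc / 2), -((Nc - floor(Nc / 2) - 1):1))[seq_len(Nc)] / Nc
  H <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, `+`))
  sm <- Re(stats::fft(stats::fft(pad) * H, inverse = TRUE)) / (Nr * Nc)
  sm[(pr + 1):(pr + nr), (pc + 1):(pc + nc)]
}

#' Flat-field (uneven illumination) correction
#'
#' Divides the image by a pseudo flat field obtained by Gaussian smoothing
#' of the image itself at a scale \code{sigma} chosen as the average bead
#' diameter. Multiplicative shading (e.g. the meniscus of the culture
#' medium) at scales larger than \code{sigma} is removed; the output has
#' mean close to 1 for smoothly varying inputs.
#'
#' @param img numeric matrix of non-negative intensities.
#' @param sigma smoothing scale in pixels (> 0).
#' @return corrected image, same shape as \code{img}.
#' @export
flatfield_correct <- function(img, sigma) {
  check_image(img)
  stopifnot(sigma > 0)
  if (max(img) <= 0) stop("degenerate image: all intensities are zero")
  flat <- fft_gaussian_lowpass(img, sigma)
  img / pmax(flat, .angio_eps(img))
}

#' Local variance filter
#'
#' Each output pixel is the variance of the intensities in the discrete
#' circular neighbourhood of the given radius (pixels whose centre lies
#' within \code{radius}); borders are handled by edge replication. Enhances
#' strong edges and merges the paired positive/negative halo bands of
#' phase-contrast optics into a single ridge.
#'
#' @param img numeric matrix.
#' @param radius neighbourhood radius in pixels (>= 1).
#' @return image of local variances (>= 0).
#' @export
variance_filter <- function(img, radius) {
  check_image(img)
  stopifnot(radius >= 1)
  k <- disc_kernel(radius)
  k <- k / sum(k)
  mu <- EBImage::filter2(img, k, boundary = "replicate")
  mu2 <- EBImage::filter2(img^2, k, boundary = "replicate")
  pmax(mu2 - mu^2, 0)
}

#' Logarithmic enhancement
#'
#' Returns \code{log(img + eps)} with an epsilon floor of 1e-6 of the image
#' maximum, compressing the dynamic range before variance filtering so that
#' bright bead rims do not dominate the edge response.
#'
#' @param img numeric matrix of non-negative intensities.
#' @return log-transformed image.
#' @export
log_enhance <- function(img) {
  check_image(img)
  log(img + .angio_eps(img))
}

#' FFT band-pass filter
#'
#' Difference of two Fourier-domain Gaussian low-passes: structures smaller
#' than \code{v1} and larger than \code{v2} pixels are suppressed. The
#' Gaussian sigma used for a structure size s is 0.4 s, calibrated so that a
#' sinusoid of wavelength 4 v2 is attenuated below 20 percent while
#' mid-band wavelengths pass essentially unchanged. The output is a
#' zero-mean residual (plus the retained band); no offset is added.
#'
#' @param img numeric matrix.
#' @param v1 minimum structure size to keep, pixels.
#' @param v2 maximum structure size to keep, pixels (v1 < v2).
#' @return filtered image, approximately zero-mean.
#' @export
fft_bandpass <- function(img, v1, v2) {
  check_image(img)
  if (!(v1 > 0 && v2 > 0 && v1 < v2))
    stop("band-pass parameters must satisfy 0 < v1 < v2")
  fft_gaussian_lowpass(img, 0.4 * v1) - fft_gaussian_lowpass(img, 0.4 * v2)
}

# 256-bin histogram over [min, max], mirroring the 8-bit convention.
.hist256 <- function(img) {
  lo <- min(img); hi <- max(img)
  if (hi <= lo) return(list(counts = c(length(img), rep(0L, 255)),
                            mids = rep(lo, 256), lo = lo, hi = lo, bw = 0))
  bw <- (hi - lo) / 256
  bin <- pmin(floor((img - lo) / bw), 255)
  counts <- tabulate(as.integer(bin) + 1L, nbins = 256)
  mids <- lo + (seq_len(256) - 0.5) * bw
  list(counts = counts, mids = mids, lo = lo, hi = hi, bw = bw)
}

#' Subtract the histogram modal value
#'
#' Subtracts the midpoint value of the most populated of 256 histogram bins
#' spanning the intensity range, clipping at zero. Removes the diffuse
#' background of the variance-enhanced image.
#'
#' @param img numeric matrix.
#' @return background-subtracted image (>= 0).
#' @export
subtract_modal <- function(img) {
  check_image(img)
  h <- .hist256(img)
  mode_val <- h$mids[which.max(h$counts)]
  pmax(img - mode_val, 0)
}

.thresh_mean <- function(img) mean(img)

.thresh_isodata <- function(img) {
  x <- as.vector(img)
  if (length(unique(x)) < 2)
    stop("IsoData threshold needs at least two distinct values")
  t_cur <- mean(x)
  for (i in seq_len(1000)) {
    lo <- x[x <= t_cur]; hi <- x[x > t_cur]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < 1e-9 * (max(x) - min(x))) {
      t_cur <- t_new; break
    }
    t_cur <- t_new
  }
  t_cur
}

.thresh_minimum <- function(img, max_iter = 10000) {
  if (length(unique(as.vector(img))) < 2)
    stop("Minimum threshold needs at least two distinct values")
  h <- .hist256(img)
  counts <- as.numeric(h$counts)
  n_peaks <- function(y) {
    n <- length(y)
    sum(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n])
  }
  it <- 0
  while (n_peaks(counts) > 2 && it < max_iter) {
    counts <- (c(counts[1], counts[-length(counts)]) + counts +
                 c(counts[-1], counts[length(counts)])) / 3
    it <- it + 1
  }
  if (n_peaks(counts) != 2) stop("histogram not bimodal")
  n <- length(counts)
  pk <- which(counts[2:(n - 1)] > counts[1:(n - 2)] &
                counts[2:(n - 1)] > counts[3:n]) + 1L
  valley_rel <- which.min(counts[pk[1]:pk[2]])
  h$mids[pk[1] + valley_rel - 1L]
}

#' Histogram auto-thresholding
#'
#' Computes a global threshold by one of three classical histogram methods
#' and returns the binary mask of pixels strictly above it (ties go to
#' background). \code{"mean"}: the image mean. \code{"isodata"}: iterate
#' t = (mean below + mean above)/2 to its fixed point. \code{"minimum"}:
#' smooth the 256-bin histogram by an iterated 3-bin moving average until
#' exactly two local maxima remain and take the minimum between them.
#'
#' @param img numeric matrix.
#' @param method one of \code{"isodata"}, \code{"minimum"}, \code{"mean"}.
#' @return 0/1 mask with attribute \code{"threshold"}.
#' @export
auto_threshold <- function(img, method = c("isodata", "minimum", "mean")) {
  check_image(img)
  method <- match.arg(tolower(method), c("isodata", "minimum", "mean"))
  thr <- switch(method,
                mean = .thresh_mean(img),
                isodata = .thresh_isodata(img),
                minimum = .thresh_minimum(img))
  mask <- as_mask(img > thr)
  attr(mask, "threshold") <- thr
  mask
}

# ---- binary morphology ----------------------------------------------------

.box3 <- matrix(1, 3, 3)

.morph_kern <- function(r) if (is.null(r)) .box3 else disc_kernel(r)

#' Binary morphology
#'
#' Standard binary morphology with a 3x3 box structuring element unless a
#' radius is given (then a discrete disc). \code{fill_holes} fills
#' background components not connected to the image border;
#' \code{maximum_filter} is a grey-level dilation usable on intensity
#' images.
#'
#' @param mask 0/1 matrix (or intensity matrix for \code{maximum_filter}).
#' @param op one of \code{"close"}, \code{"open"}, \code{"dilate"},
#'   \code{"erode"}, \code{"fill_holes"}, \code{"maximum_filter"}.
#' @param r optional structuring-element radius in pixels.
#' @return transformed mask.
#' @export
binary_morphology <- function(mask, op, r = NULL) {
  check_mask(mask)
  op <- match.arg(op, c("close", "open", "dilate", "erode",
                        "fill_holes", "maximum_filter"))
  k <- .morph_kern(r)
  out <- switch(op,
                close = EBImage::closing(mask, k),
                open = EBImage::opening(mask, k),
                dilate = EBImage::dilate(mask, k),
                erode = EBImage::erode(mask, k),
                fill_holes = EBImage::fillHull(mask),
                maximum_filter = EBImage::dilate(mask, k))
  out <- unclass(out)
  dim(out) <- dim(mask)
  out
}

#' @rdname binary_morphology
#' @export
morph_close <- function(mask, r = NULL) binary_morphology(mask, "close", r)
#' @rdname binary_morphology
#' @export
morph_open <- function(mask, r = NULL) binary_morphology(mask, "open", r)
#' @rdname binary_morphology
#' @export
morph_dilate <- function(mask, r = NULL) binary_morphology(mask, "dilate", r)
#' @rdname binary_morphology
#' @export
morph_erode <- function(mask, r = NULL) binary_morphology(mask, "erode", r)
#' @rdname binary_morphology
#' @export
fill_holes <- function(mask) binary_morphology(mask, "fill_holes")
#' @rdname binary_morphology
#' @param img intensity matrix (for \code{maximum_filter}).
#' @export
maximum_filter <- function(img, r = 2) binary_morphology(img, "maximum_filter", r)

#' Filter parameter set for the network pipeline
#'
#' @param sigma flat-field scale, pixels: the average bead diameter.
#' @param edge_radius variance radius for bead-rim enhancement, pixels.
#' @param max_radius grey-level maximum-filter radius for bead interiors.
#' @param tree_variance_radius variance radius for filament enhancement.
#' @param fft_v1 band-pass: minimum structure size to keep, pixels.
#' @param fft_v2 band-pass: maximum structure size to keep, pixels;
#'   defaults to \code{sigma} (same scale as the shadows to remove).
#' @return list of validated parameters, class \code{"filter_params"}.
#' @export
filter_params <- function(sigma, edge_radius = 3, max_radius = 2,
                          tree_variance_radius = 2, fft_v1 = 1.5,
                          fft_v2 = sigma) {
  p <- list(sigma = sigma, edge_radius = edge_radius, max_radius = max_radius,
            tree_variance_radius = tree_variance_radius,
            fft_v1 = fft_v1, fft_v2 = fft_v2)
  if (any(unlist(p) <= 0)) stop("all filter parameters must be positive")
  if (!(fft_v1 < fft_v2)) stop("fft_v1 must be smaller than fft_v2")
  structure(p, class = "filter_params")
}
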