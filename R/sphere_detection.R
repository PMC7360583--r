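# Detection of Cytodex microcarrier beads ("spheres") in phase-contrast
# images of the fibrin bead assay. Beads appear as dark disks surrounded by
# a bright envelope; they are located by edge enhancement, coarse
# segmentation, interior extraction and circle fitting.

#' Parameters for bead detection
#'
#' @param sigma expected bead diameter, pixels; also the flat-field scale.
#' @param edge_radius apparent thickness of the bead envelope, pixels.
#' @param min_diameter,max_diameter plausible bead size window, pixels;
#'   default 0.5 and 2 times \code{sigma}.
#' @param max_radius grey-level maximum-filter radius used when extracting
#'   bead interiors (default 2).
#' @param edge_thickness radius enlargement added to the fitted circle to
#'   account for the thickness of the bead envelope; defaults to
#'   \code{edge_radius}.
#' @return list of validated parameters, class \code{"sphere_params"}.
#' @export
sphere_params <- function(sigma, edge_radius = 3,
                          min_diameter = 0.5 * sigma,
                          max_diameter = 2 * sigma,
                          max_radius = 2, edge_thickness = edge_radius) {
  stopifnot(sigma > 0, edge_radius > 0, max_radius > 0, edge_thickness >= 0)
  if (!(min_diameter > 0 && min_diameter < max_diameter))
    stop("need 0 < min_diameter < max_diameter")
  structure(list(sigma = sigma, edge_radius = edge_radius,
                 min_diameter = min_diameter, max_diameter = max_diameter,
                 max_radius = max_radius, edge_thickness = edge_thickness),
            class = "sphere_params")
}

empty_circles <- function() {
  data.frame(cx = numeric(0), cy = numeric(0), radius = numeric(0),
             fit_residual = numeric(0))
}

#' Coarse bead mask
#'
#' First segmentation pass: flat-field correction, log enhancement,
#' variance filtering at the envelope scale, IsoData thresholding, then a
#' close / fill-holes / open / fill-holes cycle that closes the bead
#' outline and removes thin clutter. A field with no edge response above
#' the minimum envelope contrast (IsoData threshold below 0.02 in
#' squared-relative-contrast units) yields an empty mask.
#'
#' @param img grayscale image matrix.
#' @param p \code{\link{sphere_params}}.
#' @return 0/1 mask covering the bead disks.
#' @export
coarse_sphere_mask <- function(img, p) {
  check_image(img)
  if (nrow(img) <= p$sigma || ncol(img) <= p$sigma)
    stop("image too small for the configured bead diameter")
  lfc <- flatfield_correct(img, p$sigma)
  enh <- variance_filter(log_enhance(lfc), p$edge_radius)
  m <- auto_threshold(enh, "isodata")
  # after flat-field correction and log transform the variance image is in
  # squared-relative-contrast units; a bead envelope in phase contrast is a
  # high-contrast edge, so a threshold below 0.02 (~14% rms local contrast)
  # means the field holds noise only and the mask is empty
  if (attr(m, "threshold") < 0.02) return(m * 0)
  fill_holes(morph_open(fill_holes(morph_close(m))))
}

#' Bead interior mask
#'
#' Second segmentation pass, separating touching beads: the difference of
#' the coarse mask and the (normalised) edge-enhanced image is high inside
#' the beads and low on the bright envelope, so after a grey-level maximum
#' filter, Minimum-method thresholding, hole filling and opening, each bead
#' interior becomes one connected component even when the envelopes touch.
#' If the Minimum method fails to find a bimodal histogram, IsoData is used
#' instead and a warning is emitted.
#'
#' @param img grayscale image matrix.
#' @param coarse the mask from \code{\link{coarse_sphere_mask}}.
#' @param p \code{\link{sphere_params}}.
#' @return 0/1 mask of bead interiors.
#' @export
interior_mask <- function(img, coarse, p) {
  check_image(img)
  check_mask(coarse)
  if (sum(coarse) == 0) return(coarse * 0)
  lfc <- flatfield_correct(img, p$sigma)
  enh <- variance_filter(log_enhance(lfc), p$edge_radius)
  # normalise the edge response by its own scale on the bead envelopes
  # (robust within-mask quantile), so the interior/envelope contrast does
  # not depend on the strongest edge elsewhere in the field
  enh_n <- pmin(enh / stats::quantile(enh[coarse > 0], 0.75), 1)
  diff <- coarse - enh_n
  diff <- maximum_filter(diff, p$max_radius)
  m <- tryCatch(auto_threshold(diff, "minimum"),
                error = function(e) {
                  warning("Minimum threshold not bimodal; falling back to IsoData")
                  auto_threshold(diff, "isodata")
                })
  m <- m * coarse  # interiors live inside the coarse bead mask
  morph_open(fill_holes(m))
}

# Algebraic (Kasa) least-squares circle fit to a set of points.
fit_circle_kasa <- function(rows, cols) {
  x <- cols; y <- rows
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(max(sol[3] + cx^2 + cy^2, 0))
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  list(cx = cx, cy = cy, radius = r,
       residual = sqrt(mean((d - r)^2)))
}

# Boundary pixels of a labelled component: foreground with a 4-neighbour
# outside the component.
.component_boundary <- function(mask) {
  inner <- shift_mat(mask, 1, 0, 0) * shift_mat(mask, -1, 0, 0) *
    shift_mat(mask, 0, 1, 0) * shift_mat(mask, 0, -1, 0) * mask
  mask_which(mask - inner)
}

#' Fit circles to bead interiors
#'
#' Each connected component of the interior mask is fitted with an
#' algebraic least-squares circle on its boundary pixels; the radius is
#' then enlarged by \code{edge_thickness} to reach the middle of the bead
#' envelope. Components whose enlarged diameter falls outside the
#' configured size window, or whose RMS fit residual exceeds a quarter of
#' the radius (dirt, crescents), are discarded.
#'
#' @param interior mask from \code{\link{interior_mask}}.
#' @param p \code{\link{sphere_params}}.
#' @return data frame of circles (\code{cx}, \code{cy}, \code{radius},
#'   \code{fit_residual}), sorted by (cy, cx). Coordinates are 1-based
#'   (row = cy, col = cx).
#' @export
fit_spheres <- function(interior, p) {
  check_mask(interior)
  lab <- label8(interior)
  ncomp <- max(lab)
  out <- empty_circles()
  if (ncomp == 0) return(out)
  for (id in seq_len(ncomp)) {
    comp <- as_mask(lab == id)
    bd <- .component_boundary(comp)
    if (nrow(bd) < 5) next
    fit <- fit_circle_kasa(bd[, "row"], bd[, "col"])
    if (is.null(fit) || fit$radius <= 0) next
    r_enl <- fit$radius + p$edge_thickness
    if (2 * r_enl < p$min_diameter || 2 * r_enl > p$max_diameter) next
    if (fit$residual > 0.25 * r_enl) next
    out <- rbind(out, data.frame(cx = fit$cx, cy = fit$cy, radius = r_enl,
                                 fit_residual = fit$residual))
  }
  out[order(out$cy, out$cx), , drop = FALSE]
}

#' Detect beads in a fibrin-bead-assay image
#'
#' Public entry point composing \code{\link{coarse_sphere_mask}},
#' \code{\link{interior_mask}} and \code{\link{fit_spheres}}.
#'
#' @param img grayscale image matrix.
#' @param p \code{\link{sphere_params}}.
#' @return data frame of fitted circles (possibly empty).
#' @export
detect_spheres <- function(img, p) {
  coarse <- coarse_sphere_mask(img, p)
  if (sum(coarse) == 0) return(empty_circles())
  inter <- interior_mask(img, coarse, p)
  fit_spheres(inter, p)
}
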