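# Segmentation of pseudo-capillary structures and reduction to a clean
# one-pixel-wide, 8-connected skeleton. In bead (FBA) mode the skeleton is
# anchored to the detected circles: bead disks are filled before thinning,
# floating structures are discarded and the bead interiors are cleared
# afterwards. In tube-formation (ETFA) mode the whole field is thinned.

#' Segment the capillary network
#'
#' Flat-field correction, FFT band-pass (removing pixel noise below
#' \code{fft_v1} and phase-contrast shadows above \code{fft_v2}), variance
#' filtering at the filament scale (merging the paired bright/dark halo
#' bands into one ridge), modal background subtraction, Mean thresholding,
#' then one closing and one dilation to smooth the mask and make it
#' continuous. A field whose strongest enhanced response is within a
#' factor 25 of the mean threshold has no structure above the noise floor
#' and yields an empty mask.
#'
#' @param img grayscale image matrix.
#' @param p \code{\link{filter_params}}.
#' @return 0/1 mask of the network.
#' @export
segment_network <- function(img, p) {
  check_image(img)
  lfc <- fft_bandpass(flatfield_correct(img, p$sigma), p$fft_v1, p$fft_v2)
  enh <- subtract_modal(variance_filter(lfc, p$tree_variance_radius))
  m <- auto_threshold(enh, "mean")
  # a mean threshold on a structure-free field sits inside the noise bulk
  # and keeps about half the pixels (peak-to-threshold ratio ~15); real
  # filaments push the strongest response far above the mean (>= ~23 even
  # for dense fields, where many foreground pixels raise the mean).
  if (max(enh) < 20 * attr(m, "threshold")) return(m * 0)
  thr <- attr(m, "threshold")
  # hysteresis: flat-field division amplifies noise wherever illumination
  # was low, and the global mean threshold then admits barely-above-
  # threshold noise patches there. Before any morphology, raw threshold
  # components are kept only if they contain at least one strong pixel
  # (5x the threshold -- real filaments run an order of magnitude above
  # it, noise patches stay below ~2.5x).
  lab <- label8(m)
  if (max(lab) > 0) {
    strong <- unique(lab[enh >= 5 * thr & lab > 0])
    m[!(lab %in% c(0L, strong))] <- 0
  }
  m <- morph_dilate(morph_close(m))
  # the Fourier filters see a mirrored image beyond the frame; under
  # strong shading the crease responds like an edge, so the outermost
  # 8 px band is not trusted
  b <- 8
  m[c(seq_len(b), nrow(m) - seq_len(b) + 1), ] <- 0
  m[, c(seq_len(b), ncol(m) - seq_len(b) + 1)] <- 0
  m
}

# ---- thinning -------------------------------------------------------------

# One Zhang-Suen subiteration, vectorised over the whole image.
.zs_pass <- function(m, step) {
  p2 <- shift_mat(m, 1, 0); p3 <- shift_mat(m, 1, -1)
  p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
  p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
  p8 <- shift_mat(m, 0, 1); p9 <- shift_mat(m, 1, 1)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  if (step == 1L) {
    cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
  } else {
    cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
  }
  del <- m == 1 & b >= 2 & b <= 6 & a == 1 & cond
  m[del] <- 0
  list(m = m, changed = any(del))
}

# Yokoi 8-connectivity number of the centre pixel of a 3x3 patch given its
# 8 neighbours in order E, NE, N, NW, W, SW, S, SE. The pixel is "simple"
# (deletable without topology change) when the number is 1.
.connectivity8 <- function(nb) {
  x <- 1 - nb  # complement for 8-connectivity of foreground
  idx <- c(1, 3, 5, 7)
  s <- 0
  for (k in idx) {
    k1 <- if (k == 7) 8 else k + 1
    k2 <- if (k >= 7) k - 6 else k + 2
    s <- s + (x[k] - x[k] * x[k1] * x[k2])
  }
  s
}

.NB_ORDER <- cbind(dr = c(0, -1, -1, -1, 0, 1, 1, 1),
                   dc = c(1, 1, 0, -1, -1, -1, 0, 1))

# Remove redundant pixels left by the parallel thinning (2x2 blocks and
# staircase corners). A pixel with 3 or more neighbours whose Yokoi
# connectivity number is 1 is a simple point: deleting it preserves both
# topology and line ends, and turns redundant corner pairs into clean
# diagonal steps. True bifurcation pixels have connectivity >= 2 and are
# never touched.
.staircase_cleanup <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    cand <- which(m == 1 & neighbor_count(m) >= 2)
    changed <- FALSE
    for (idx in cand) {
      r <- ((idx - 1L) %% nr) + 1L
      c <- ((idx - 1L) %/% nr) + 1L
      if (r < 2 || c < 2 || r > nr - 1 || c > nc - 1) next
      nb <- m[cbind(r + .NB_ORDER[, 1], c + .NB_ORDER[, 2])]
      s <- sum(nb)
      if (s >= 3) {
        del <- .connectivity8(nb) == 1
      } else if (s == 2) {
        # corner pixel whose two neighbours are themselves adjacent: the
        # path survives through the direct diagonal step
        w <- which(nb == 1)
        del <- max(abs(.NB_ORDER[w[1], ] - .NB_ORDER[w[2], ])) == 1
      } else del <- FALSE
      if (del) {
        m[idx] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Thin a binary mask to a one-pixel skeleton
#'
#' Topology-preserving parallel thinning (Zhang-Suen) followed by a
#' sequential cleanup of residual staircase pixels, yielding an 8-connected
#' unit-width skeleton with no 2x2 foreground block.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 skeleton matrix.
#' @export
thin_mask <- function(mask) {
  check_mask(mask)
  m <- as_mask(mask)
  repeat {
    s1 <- .zs_pass(m, 1L)
    s2 <- .zs_pass(s1$m, 2L)
    m <- s2$m
    if (!s1$changed && !s2$changed) break
  }
  .staircase_cleanup(m)
}

#' Prune short terminal twigs from a skeleton
#'
#' Thinning a segmented ribbon leaves short terminal spurs wherever the
#' mask boundary is ragged. Twigs are walked inward from every endpoint;
#' a twig that reaches a bifurcation pixel in fewer than \code{min_len}
#' steps is an artifact and is deleted (the bifurcation pixel is kept).
#' Applied iteratively until stable. Genuine branches, which are longer
#' than \code{min_len}, and isolated fragments with no bifurcation are
#' untouched.
#'
#' @param m 0/1 skeleton matrix.
#' @param min_len twig length threshold in pixels (steps).
#' @return pruned skeleton matrix.
#' @export
prune_twigs <- function(m, min_len = 10) {
  nr <- nrow(m)
  repeat {
    nb <- neighbor_count(m)
    ends <- which(m == 1 & nb == 1)
    if (!length(ends)) break
    changed <- FALSE
    for (idx in ends) {
      if (m[idx] == 0) next
      path <- integer(0)
      cur <- idx
      hit_node <- FALSE
      for (step in seq_len(min_len)) {
        path <- c(path, cur)
        r <- ((cur - 1L) %% nr) + 1L; c <- ((cur - 1L) %/% nr) + 1L
        nxt <- integer(0)
        n_here <- 0L
        for (k in seq_len(8)) {
          rr <- r + .N8[k, 1]; cc <- c + .N8[k, 2]
          if (rr < 1 || rr > nr || cc < 1 || cc > ncol(m)) next
          j <- (cc - 1L) * nr + rr
          if (m[j] == 1) {
            n_here <- n_here + 1L
            if (!(j %in% path)) nxt <- c(nxt, j)
          }
        }
        if (length(nxt) == 0) break  # isolated fragment: keep
        # does the next pixel sit on a bifurcation?
        jn <- nxt[1]
        rj <- ((jn - 1L) %% nr) + 1L; cj <- ((jn - 1L) %/% nr) + 1L
        deg_next <- 0L
        for (k in seq_len(8)) {
          rr <- rj + .N8[k, 1]; cc <- cj + .N8[k, 2]
          if (rr < 1 || rr > nr || cc < 1 || cc > ncol(m)) next
          if (m[(cc - 1L) * nr + rr] == 1) deg_next <- deg_next + 1L
        }
        if (deg_next >= 3) { hit_node <- TRUE; break }
        cur <- jn
      }
      if (hit_node) {
        m[path] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # a deleted twig can leave its attachment pixel as a redundant corner
  .staircase_cleanup(m)
}

# Fill enclosed background components smaller than max_area pixels.
# Halo interference can punch pinholes into the segmented ribbons; left in
# place they become spurious skeleton loops. Real meshes are orders of
# magnitude larger than the 8 x 8 px ceiling used here.
fill_small_holes <- function(mask, max_area = 64) {
  comp <- as_mask(mask == 0)
  lab <- EBImage::bwlabel(comp)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  border <- unique(c(lab[1, ], lab[nrow(mask), ], lab[, 1], lab[, ncol(mask)]))
  sizes <- tabulate(lab, nbins = max(lab, 1))
  small <- setdiff(which(sizes > 0 & sizes < max_area), border)
  if (length(small)) mask[lab %in% small] <- 1
  mask
}

# Distance of every pixel to a circle's ring: | dist(center) - radius |.
.ring_dist <- function(nr, nc, circle) {
  abs(sqrt(pixel_dist2(nr, nc, circle$cy, circle$cx)) - circle$radius)
}

.min_ring_dist <- function(nr, nc, circles) {
  d <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(circles)))
    d <- pmin(d, .ring_dist(nr, nc, circles[i, ]))
  d
}

#' Skeletonize the network mask
#'
#' In FBA mode (non-empty \code{circles}) the detected bead disks are
#' filled into the mask so sprouts join their bead, the mask is thinned,
#' skeleton components not in contact with any circle (no pixel within 1 px
#' of a circle ring, nor inside it) are removed as floating objects, and
#' finally all skeleton pixels strictly inside a circle (centre distance
#' < radius - clear_inset) are cleared, cutting each sprout at the bead boundary.
#' In ETFA mode (empty \code{circles}) the mask is thinned only.
#'
#' @param mask 0/1 network mask.
#' @param circles data frame of circles as from \code{\link{detect_spheres}}
#'   (may be empty / missing for ETFA).
#' @param max_hole_area enclosed background components smaller than this
#'   (pixels) are filled before thinning; they are halo pinholes, not
#'   meshes.
#' @param twig_length terminal spurs shorter than this are pruned from the
#'   skeleton (see \code{\link{prune_twigs}}).
#' @param clear_inset circle interiors are cleared up to radius minus this
#'   inset (pixels). Thinning can route a sprout's attachment a few pixels
#'   inside the envelope; keeping a thin interior margin preserves that
#'   attachment so the sprout still reaches the ring.
#' @return object of class \code{"angio_skeleton"}: a list with
#'   \code{pixels} (0/1 matrix) and \code{circles}.
#' @export
skeletonize_network <- function(mask, circles = empty_circles(),
                                max_hole_area = 64, twig_length = 10,
                                clear_inset = 4) {
  check_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  mask <- fill_small_holes(mask, max_hole_area)
  if (nrow(circles) == 0) {
    sk <- prune_twigs(thin_mask(mask), twig_length)
    return(structure(list(pixels = sk, circles = empty_circles(),
                          mode = "ETFA"), class = "angio_skeleton"))
  }
  m <- as_mask(mask)
  for (i in seq_len(nrow(circles))) {
    ci <- circles[i, ]
    m[pixel_dist2(nr, nc, ci$cy, ci$cx) <= ci$radius^2] <- 1
  }
  sk <- prune_twigs(thin_mask(m), twig_length)
  ringd <- .min_ring_dist(nr, nc, circles)
  centerd <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(circles))) {
    ci <- circles[i, ]
    centerd <- pmin(centerd,
                    sqrt(pixel_dist2(nr, nc, ci$cy, ci$cx)) - ci$radius)
  }
  lab <- label8(sk)
  if (max(lab) > 0) {
    touching <- sort(unique(lab[lab > 0 & (ringd <= 1 | centerd < 0)]))
    sk[!(lab %in% c(0L, touching))] <- 0
  }
  inside <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(circles))) {
    ci <- circles[i, ]
    inside <- inside | sqrt(pixel_dist2(nr, nc, ci$cy, ci$cx)) < ci$radius - clear_inset
  }
  sk[inside] <- 0
  # thinning can route a sprout's last stretch through the bead interior,
  # so after clearing its stub may stop well short of the ring. Every
  # surviving component was bead-connected (floating ones were removed
  # above), so an endpoint near a ring whose straight radial corridor to
  # the ring is mask-foreground is reattached with a 1-px line.
  nbv <- neighbor_count(sk)
  ends <- which(sk == 1 & nbv == 1)
  for (idx in ends) {
    er <- ((idx - 1L) %% nr) + 1L; ec <- ((idx - 1L) %/% nr) + 1L
    for (i in seq_len(nrow(circles))) {
      ci <- circles[i, ]
      dc <- sqrt((er - ci$cy)^2 + (ec - ci$cx)^2) - ci$radius
      if (dc <= 1 || dc > 16) next
      u <- c(er - ci$cy, ec - ci$cx) / (dc + ci$radius)
      tgt <- c(ci$cy, ci$cx) + (ci$radius - 1) * u
      t <- seq(0, 1, length.out = max(3, ceiling(2 * (dc + 1))))
      px <- unique(cbind(round(er + t * (tgt[1] - er)),
                         round(ec + t * (tgt[2] - ec))))
      px <- px[px[, 1] >= 1 & px[, 1] <= nr & px[, 2] >= 1 & px[, 2] <= nc, , drop = FALSE]
      if (all(m[px] == 1)) {
        sk[px] <- 1
        break
      }
    }
  }
  sk <- .staircase_cleanup(sk)
  structure(list(pixels = sk, circles = circles, mode = "FBA"),
            class = "angio_skeleton")
}
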