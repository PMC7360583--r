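# Synthetic phase-contrast scene renderer with exact ground truth.
# Emulates the image properties of the two assays: dark microcarrier beads
# with a bright envelope, thin filaments rendered as a bright ridge with
# dark phase-contrast halo bands, multiplicative meniscus-like shading and
# additive Gaussian noise. Scene geometry is generated under an explicit
# seed and carries its own vectorial ground truth (circles, junction /
# branch / segment / anchorage counts, mesh areas), so every pipeline
# stage can be validated without microscopy data.

# ---- ground-truth graph reduction ----------------------------------------

#' Reduce a centreline graph to ground-truth object counts
#'
#' Reduces a planar centreline graph (vertices with coordinates, straight
#' edges) to the vectorial model: anchor vertices and degree >= 3 vertices
#' are junctions, degree-1 vertices extremities, degree-2 vertices
#' dissolve into their neighbours. A component that reduces to a pure
#' cycle counts as one synthetic junction carrying a self-loop segment,
#' mirroring the tracer's convention. This is the independent oracle the
#' scene renderer uses to label its ground truth.
#'
#' @param vertices data frame (id, row, col, anchor, bead).
#' @param edges data frame (v1, v2) of vertex ids.
#' @return list of counts: junctions, anchorage, branches, segments,
#'   isolated, meshes.
#' @export
gt_reduce <- function(vertices, edges) {
  if (nrow(edges) == 0)
    return(list(junctions = 0L, anchorage = sum(vertices$anchor),
                branches = 0L, segments = 0L, isolated = 0L, meshes = 0L))
  deg <- tabulate(c(edges$v1, edges$v2), nbins = max(vertices$id))
  is_junc <- vertices$anchor | deg[vertices$id] >= 3
  e <- edges
  repeat {
    deg <- tabulate(c(e$v1, e$v2), nbins = max(vertices$id))
    cand <- vertices$id[!vertices$anchor & deg[vertices$id] == 2 &
                          !is_junc[match(vertices$id, vertices$id)]]
    done <- TRUE
    for (v in cand) {
      inc <- which(e$v1 == v | e$v2 == v)
      if (length(inc) != 2) next  # self-loop or parallel; leave
      a <- setdiff(c(e$v1[inc[1]], e$v2[inc[1]]), v)
      b <- setdiff(c(e$v1[inc[2]], e$v2[inc[2]]), v)
      if (length(a) == 0 || length(b) == 0) next
      e <- e[-inc, , drop = FALSE]
      e <- rbind(e, data.frame(v1 = a, v2 = b))
      done <- FALSE
      break
    }
    if (done) break
  }
  # cycles that lost every classified vertex: self-loop on synthetic junction
  syn <- sum(e$v1 == e$v2 & !is_junc[match(e$v1, vertices$id)] &
               tabulate(c(e$v1, e$v2), nbins = max(vertices$id))[e$v1] == 2)
  kind_of <- function(v) {
    if (is_junc[match(v, vertices$id)]) "junction" else "extremity"
  }
  k1 <- vapply(e$v1, kind_of, character(1))
  k2 <- vapply(e$v2, kind_of, character(1))
  self_cycle <- e$v1 == e$v2 & k1 == "extremity"
  k1[self_cycle] <- "junction"; k2[self_cycle] <- "junction"
  branches <- sum((k1 == "junction") != (k2 == "junction"))
  segments <- sum(k1 == "junction" & k2 == "junction")
  isolated <- sum(k1 == "extremity" & k2 == "extremity")
  # cyclomatic number on the original graph
  vs <- vertices$id
  parent <- seq_along(vs); names(parent) <- vs
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  idx <- setNames(seq_along(vs), vs)
  for (k in seq_len(nrow(edges))) {
    ra <- find(idx[[as.character(edges$v1[k])]])
    rb <- find(idx[[as.character(edges$v2[k])]])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  ccount <- length(unique(vapply(seq_along(vs), find, integer(1))))
  meshes <- nrow(edges) - length(vs) + ccount
  janch <- sum(vertices$anchor)
  list(junctions = sum(is_junc & !vertices$anchor) + sum(self_cycle),
       anchorage = janch, branches = branches, segments = segments,
       isolated = isolated, meshes = meshes)
}

# ---- rasterization helpers ------------------------------------------------

# Dense rasterization of the straight edge set: (row, col) pixels.
.rasterize_edges <- function(vertices, edges, dim) {
  pts <- list()
  for (k in seq_len(nrow(edges))) {
    a <- vertices[match(edges$v1[k], vertices$id), c("row", "col")]
    b <- vertices[match(edges$v2[k], vertices$id), c("row", "col")]
    len <- sqrt(sum((unlist(a) - unlist(b))^2))
    t <- seq(0, 1, length.out = max(2, ceiling(len * 4)))
    pts[[k]] <- cbind(round(a$row + t * (b$row - a$row)),
                      round(a$col + t * (b$col - a$col)))
  }
  px <- unique(do.call(rbind, pts))
  px <- px[px[, 1] >= 1 & px[, 1] <= dim[1] & px[, 2] >= 1 & px[, 2] <= dim[2], , drop = FALSE]
  m <- matrix(0, dim[1], dim[2])
  m[px] <- 1
  m
}

# Mesh areas of the ground-truth centreline drawing: flood fill of the
# complement (independent oracle, computed on the true geometry).
.gt_mesh_areas <- function(centerline) {
  lab <- EBImage::bwlabel(as_mask(centerline == 0))
  lab <- matrix(as.integer(lab), nrow(centerline), ncol(centerline))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  ids <- setdiff(sort(unique(lab[lab > 0])), border)
  if (!length(ids)) return(numeric(0))
  as.numeric(tabulate(lab, nbins = max(lab))[ids])
}

# ---- scene generation -----------------------------------------------------

#' Random fibrin-bead-assay scene
#'
#' Draws 1 to 4 beads with sprouting trees under geometric separation
#' constraints, reproducibly from the seed: beads at least one radius
#' apart, sprouts angularly separated, and filament centrelines of
#' different sprouts at least 20 px apart -- tubes closer than the width
#' of their segmented ribbons merge optically and are not recoverable as
#' separate objects. Trunks are 40-55 px, bifurcation arms 25-45 px, so
#' every true edge is comfortably longer than the pruning and fusion
#' scales.
#'
#' @param seed integer seed.
#' @param n_beads number of beads (default: drawn from 1:4).
#' @param size image side, pixels.
#' @param noise_sd additive Gaussian noise level (image in [0, 1] units).
#' @param shading_amp amplitude of the multiplicative shading ramp.
#' @return a \code{scene_spec} list.
#' @export
fba_scene <- function(seed, n_beads = NULL, size = 512, noise_sd = 0.02,
                      shading_amp = 0.25) {
  with_seed(seed, {
    nb <- if (is.null(n_beads)) sample(1:4, 1) else n_beads
    # bead centres: at least one bead radius of clear gel between rims
    repeat {
      radii <- runif(nb, 34, 44)
      lo <- radii + 50; hi <- size - lo
      ok <- FALSE
      for (attempt in seq_len(500)) {
        ctr <- cbind(row = runif(nb, lo, hi), col = runif(nb, lo, hi))
        ok <- TRUE
        if (nb > 1) {
          dd <- as.matrix(dist(ctr))
          for (i in seq_len(nb - 1)) for (j in (i + 1):nb)
            if (dd[i, j] < radii[i] + radii[j] + max(radii[i], radii[j]) + 15)
              ok <- FALSE
        }
        if (ok) break
      }
      if (ok) break
      nb <- nb - 1  # crowded draw: fall back to fewer beads
    }
    vertices <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                           anchor = logical(0), bead = integer(0))
    edges <- data.frame(v1 = integer(0), v2 = integer(0))
    vid <- 0L
    add_v <- function(row, col, anchor = FALSE, bead = NA_integer_) {
      vid <<- vid + 1L
      vertices[nrow(vertices) + 1L, ] <<- list(vid, row, col, anchor, bead)
      vid
    }
    # accepted sample points of already placed sprouts, for clearance tests
    placed <- matrix(numeric(0), 0, 2)
    seg_points <- function(a, b) {
      t <- seq(0, 1, length.out = max(2, ceiling(sqrt(sum((a - b)^2)) / 3)))
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    }
    clear_of_scene <- function(pts, bead) {
      if (any(pts < 12 | pts > size - 12)) return(FALSE)
      for (b2 in seq_len(nb)) {
        if (b2 == bead) next
        d <- sqrt((pts[, 1] - ctr[b2, 1])^2 + (pts[, 2] - ctr[b2, 2])^2)
        if (any(d < radii[b2] + 16)) return(FALSE)
      }
      if (nrow(placed)) {
        for (i in seq_len(nrow(pts))) {
          d2 <- (placed[, 1] - pts[i, 1])^2 + (placed[, 2] - pts[i, 2])^2
          if (any(d2 < 20^2)) return(FALSE)
        }
      }
      TRUE
    }
    for (b in seq_len(nb)) {
      ns <- sample(2:4, 1)
      used_ang <- numeric(0)
      for (s in seq_len(ns)) {
        done <- FALSE
        for (attempt in seq_len(60)) {
          a <- runif(1, 0, 2 * pi)
          if (length(used_ang) &&
              min(abs(((a - used_ang + pi) %% (2 * pi)) - pi)) < 55 * pi / 180)
            next
          trunk <- runif(1, 40, 55)
          root <- c(ctr[b, 1] + radii[b] * sin(a), ctr[b, 2] + radii[b] * cos(a))
          mid <- c(ctr[b, 1] + (radii[b] + trunk) * sin(a),
                   ctr[b, 2] + (radii[b] + trunk) * cos(a))
          bifurcate <- runif(1) < 0.5
          pts <- seg_points(root, mid)
          tips <- list()
          if (bifurcate) {
            spread <- runif(1, 30, 40) * pi / 180
            arms_ok <- TRUE
            for (sgn in c(-1, 1)) {
              arm <- runif(1, 25, 45)
              tip <- c(mid[1] + arm * sin(a + sgn * spread),
                       mid[2] + arm * cos(a + sgn * spread))
              tips[[length(tips) + 1]] <- tip
              pts <- rbind(pts, seg_points(mid, tip))
            }
          }
          if (!clear_of_scene(pts, b)) next
          va <- add_v(root[1], root[2], anchor = TRUE, bead = b)
          v1 <- add_v(mid[1], mid[2], bead = b)
          edges[nrow(edges) + 1L, ] <- list(va, v1)
          for (tip in tips) {
            vt <- add_v(tip[1], tip[2], bead = b)
            edges[nrow(edges) + 1L, ] <- list(v1, vt)
          }
          placed <- rbind(placed, pts)
          used_ang <- c(used_ang, a)
          done <- TRUE
          break
        }
        if (!done) break  # crowded bead: keep the sprouts accepted so far
      }
    }
    structure(list(mode = "FBA", seed = seed, size = size,
                   beads = data.frame(cy = ctr[, 1], cx = ctr[, 2],
                                      radius = radii),
                   vertices = vertices, edges = edges,
                   noise_sd = noise_sd, shading_amp = shading_amp,
                   rim_width = 4),
              class = "scene_spec")
  })
}

#' Random tube-formation-assay scene
#'
#' A jittered rectangular tiling with the requested number of cells
#' (prime counts are reached by removing interior walls of a larger grid),
#' optional dangling branches on the outer boundary and optional isolated
#' fragments floating clear of the network.
#'
#' @param seed integer seed.
#' @param n_cells mesh count, 1-12 (default: drawn from 1:12).
#' @param size image side, pixels.
#' @param n_dangling dangling outward branches (default 0-2, random).
#' @param fragment_lengths lengths of free-floating isolated fragments,
#'   pixels (default one fragment of 15-30 px).
#' @param noise_sd,shading_amp as in \code{\link{fba_scene}}.
#' @return a \code{scene_spec} list.
#' @export
etfa_scene <- function(seed, n_cells = NULL, size = 448, n_dangling = NULL,
                       fragment_lengths = NULL, noise_sd = 0.02,
                       shading_amp = 0.25) {
  with_seed(seed, {
    nc <- if (is.null(n_cells)) sample(1:12, 1) else n_cells
    stopifnot(nc >= 1, nc <= 12)
    shapes <- list(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(2, 3),
                   c(2, 4), c(2, 4), c(3, 3), c(2, 5), c(3, 4), c(3, 4))
    sh <- shapes[[nc]]
    rows <- sh[1]; cols <- sh[2]
    n_remove <- rows * cols - nc
    cell <- runif(1, 55, min(70, (size - 140) / max(rows, cols)))
    oy <- (size - rows * cell) / 2; ox <- (size - cols * cell) / 2
    vertices <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                           anchor = logical(0), bead = integer(0))
    vid_at <- matrix(0L, rows + 1, cols + 1)
    vid <- 0L
    for (i in 0:rows) for (j in 0:cols) {
      vid <- vid + 1L
      vertices[vid, ] <- list(vid, oy + i * cell + runif(1, -5, 5),
                              ox + j * cell + runif(1, -5, 5),
                              FALSE, NA_integer_)
      vid_at[i + 1, j + 1] <- vid
    }
    edges <- data.frame(v1 = integer(0), v2 = integer(0))
    interior <- logical(0)
    for (i in 0:rows) for (j in 0:cols) {
      if (j < cols) {  # horizontal wall
        edges[nrow(edges) + 1L, ] <- list(vid_at[i + 1, j + 1], vid_at[i + 1, j + 2])
        interior <- c(interior, i > 0 && i < rows)
      }
      if (i < rows) {  # vertical wall
        edges[nrow(edges) + 1L, ] <- list(vid_at[i + 1, j + 1], vid_at[i + 2, j + 1])
        interior <- c(interior, j > 0 && j < cols)
      }
    }
    if (n_remove > 0) {
      rem <- sample(which(interior), n_remove)
      edges <- edges[-rem, , drop = FALSE]
    }
    nd <- if (is.null(n_dangling)) sample(0:2, 1) else n_dangling
    if (nd > 0) {
      boundary <- c(vid_at[1, ], vid_at[rows + 1, ], vid_at[, 1], vid_at[, cols + 1])
      pick <- sample(unique(boundary), nd)
      cy <- oy + rows * cell / 2; cx <- ox + cols * cell / 2
      for (v in pick) {
        dir <- atan2(vertices$row[v] - cy, vertices$col[v] - cx) +
          runif(1, -0.4, 0.4)
        len <- runif(1, 25, 40)
        vid <- vid + 1L
        vertices[vid, ] <- list(vid, vertices$row[v] + len * sin(dir),
                                vertices$col[v] + len * cos(dir),
                                FALSE, NA_integer_)
        edges[nrow(edges) + 1L, ] <- list(v, vid)
      }
    }
    frag <- if (is.null(fragment_lengths)) runif(1, 15, 30) else fragment_lengths
    for (fl in frag) {
      if (fl <= 0) next
      # place in the strip above the tiling, well clear of the network
      r0 <- runif(1, 20, max(21, oy - 55))
      c0 <- runif(1, 20, size - 20 - fl)
      theta <- runif(1, -0.3, 0.3)  # near-horizontal so it stays in the strip
      vid <- vid + 1L
      vertices[vid, ] <- list(vid, r0, c0, FALSE, NA_integer_)
      vid <- vid + 1L
      vertices[vid, ] <- list(vid, r0 + fl * sin(theta),
                              c0 + fl * cos(theta), FALSE, NA_integer_)
      edges[nrow(edges) + 1L, ] <- list(vid - 1L, vid)
    }
    structure(list(mode = "ETFA", seed = seed, size = size,
                   beads = data.frame(cy = numeric(0), cx = numeric(0),
                                      radius = numeric(0)),
                   vertices = vertices, edges = edges,
                   noise_sd = noise_sd, shading_amp = shading_amp,
                   rim_width = 4),
              class = "scene_spec")
  })
}

# ---- rendering ------------------------------------------------------------

.render_scene <- function(spec) {
  size <- spec$size
  img <- matrix(0.55, size, size)
  centerline <- .rasterize_edges(spec$vertices, spec$edges, c(size, size))
  # filament ridge with phase-contrast halo: bright core, dark flanks
  D <- EBImage::distmap(1 - centerline)
  D <- matrix(as.numeric(D), size, size)
  w <- 1.4
  profile <- 0.55 * (exp(-D^2 / (2 * w^2)) - 0.45 * exp(-D^2 / (2 * (2.5 * w)^2)))
  img <- img + profile
  # beads drawn on top: dark interior, bright envelope
  for (b in seq_len(nrow(spec$beads))) {
    bd <- spec$beads[b, ]
    d <- sqrt(pixel_dist2(size, size, bd$cy, bd$cx))
    img[d <= bd$radius - spec$rim_width] <- 0.28
    img[d > bd$radius - spec$rim_width & d <= bd$radius] <- 0.90
  }
  img <- fft_gaussian_lowpass(img, 0.7)  # optical blur
  truth_filaments <- as_mask(D <= w)
  with_seed(spec$seed + 104729L, {
    dir <- runif(1, 0, 2 * pi)
    plane <- outer(seq_len(size) - size / 2, rep(1, size)) * sin(dir) +
      outer(rep(1, size), seq_len(size) - size / 2) * cos(dir)
    shade <- 1 + spec$shading_amp * plane / (size / 2)
    img <- img * shade
    img <- img + matrix(rnorm(size^2, 0, spec$noise_sd), size, size)
  })
  pmax(img, 0.001)
}

.scene_truth <- function(spec) {
  counts <- gt_reduce(spec$vertices, spec$edges)
  centerline <- .rasterize_edges(spec$vertices, spec$edges,
                                 c(spec$size, spec$size))
  per_bead <- NULL
  if (nrow(spec$beads) > 0) {
    per_bead <- do.call(rbind, lapply(seq_len(nrow(spec$beads)), function(b) {
      sel_v <- spec$vertices[which(spec$vertices$bead == b), , drop = FALSE]
      sel_e <- spec$edges[spec$edges$v1 %in% sel_v$id &
                            spec$edges$v2 %in% sel_v$id, , drop = FALSE]
      cc <- gt_reduce(sel_v, sel_e)
      data.frame(bead = b, AJN_S = cc$anchorage, JN_S = cc$junctions,
                 branches = cc$branches, segments = cc$segments)
    }))
  }
  list(circles = spec$beads, counts = counts, per_bead = per_bead,
       mesh_areas = if (spec$mode == "ETFA") .gt_mesh_areas(centerline)
       else numeric(0),
       centerline = centerline)
}

#' Render a fibrin-bead-assay scene
#'
#' @param spec a \code{scene_spec} from \code{\link{fba_scene}}.
#' @return list with \code{image} (matrix) and \code{truth} (circles,
#'   object counts overall and per bead, centreline mask).
#' @export
render_fba <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"), spec$mode == "FBA")
  list(image = .render_scene(spec), truth = .scene_truth(spec))
}

#' Render a tube-formation-assay scene
#'
#' @param spec a \code{scene_spec} from \code{\link{etfa_scene}}.
#' @return list with \code{image} and \code{truth} (counts, mesh areas
#'   from polygon rasterization, centreline mask).
#' @export
render_etfa <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"), spec$mode == "ETFA")
  list(image = .render_scene(spec), truth = .scene_truth(spec))
}

#' Render a scene under a sweep of perturbations
#'
#' Applies each perturbation (a named list of \code{scene_spec} field
#' overrides, e.g. \code{shading_amp} or \code{noise_sd}) and renders.
#' An empty perturbation list yields the base render alone.
#'
#' @param spec a \code{scene_spec}.
#' @param perturbations list of named lists of field overrides.
#' @return list of render results (image + truth).
#' @export
perturbation_suite <- function(spec, perturbations = list()) {
  render1 <- function(s) if (s$mode == "FBA") render_fba(s) else render_etfa(s)
  if (!length(perturbations)) return(list(render1(spec)))
  lapply(perturbations, function(pp) {
    s <- spec
    for (nm in names(pp)) s[[nm]] <- pp[[nm]]
    render1(s)
  })
}
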