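# Shared fixture builders: tiny rasters drawn in code, plus caches of a
# few rendered scenes so expensive renders happen once per test run.

blank_img <- function(n = 32, value = 0) matrix(value, n, n)

draw_disk <- function(m, cy, cx, r, value = 1) {
  d2 <- outer((seq_len(nrow(m)) - cy)^2, (seq_len(ncol(m)) - cx)^2, `+`)
  m[d2 <= r^2] <- value
  m
}

# 1-px straight line between two points (dense sampling, like Bresenham)
draw_line <- function(m, r0, c0, r1, c1, value = 1) {
  len <- max(abs(r1 - r0), abs(c1 - c0), 1)
  t <- seq(0, 1, length.out = len + 1)
  # floor(x + 0.5): round() would round half-to-even and jag diagonals
  px <- unique(cbind(floor(r0 + t * (r1 - r0) + 0.5),
                     floor(c0 + t * (c1 - c0) + 0.5)))
  m[px] <- value
  m
}

# Plus-shaped skeleton with arms of the given length
plus_skeleton <- function(arm = 5, pad = 4) {
  n <- 2 * (arm + pad) + 1
  c0 <- arm + pad + 1
  m <- matrix(0, n, n)
  m[c0, (c0 - arm):(c0 + arm)] <- 1
  m[(c0 - arm):(c0 + arm), c0] <- 1
  m
}

# Brute-force neighbour count of the centre of a 3x3 patch (oracle)
brute_neighbors <- function(patch) sum(patch) - patch[2, 2]

# Manually-constructed graph for fusion / pruning boundary tests: a chain
# of junctions at given column positions on one row, joined by straight
# horizontal segments, with one terminal branch on each side.
make_chain_graph <- function(cols, row = 50, dim = c(100, max(cols) + 40)) {
  nj <- length(cols)
  junctions <- data.frame(id = seq_len(nj), cy = row, cx = cols,
                          is_anchorage = FALSE, n_nodes = 1L,
                          circle_id = NA_integer_)
  jpix <- lapply(seq_len(nj), function(i) cbind(row, cols[i]))
  names(jpix) <- as.character(seq_len(nj))
  edges <- data.frame(id = integer(0), kind = character(0),
                      from_type = character(0), from_id = integer(0),
                      to_type = character(0), to_id = integer(0),
                      length = numeric(0))
  polylines <- list()
  eid <- 0L
  exts <- data.frame(id = integer(0), row = integer(0), col = integer(0))
  add_edge <- function(ft, fi, tt, ti, poly) {
    eid <<- eid + 1L
    edges[nrow(edges) + 1L, ] <<- list(eid, "segment", ft, fi, tt, ti,
                                       if (nrow(poly) > 1) nrow(poly) - 1 else 0)
    edges$kind[nrow(edges)] <<-
      if (ft == "junction" && tt == "junction") "segment"
      else if (ft == "extremity" && tt == "extremity") "isolated" else "branch"
    polylines[[as.character(eid)]] <<- poly
  }
  # segments between consecutive junctions
  for (i in seq_len(nj - 1)) {
    p <- cbind(row, (cols[i] + 1):(cols[i + 1] - 1))
    add_edge("junction", i, "junction", i + 1L, p)
  }
  # one long branch off each end so end junctions keep degree >= 2
  exts <- rbind(exts, data.frame(id = 1L, row = row - 30L, col = cols[1]),
                data.frame(id = 2L, row = row - 30L, col = cols[nj]))
  add_edge("junction", 1L, "extremity", 1L,
           cbind((row - 1):(row - 29), cols[1]))
  add_edge("junction", nj, "extremity", 2L,
           cbind((row - 1):(row - 29), cols[nj]))
  structure(list(junctions = junctions, junction_pixels = jpix,
                 extremities = exts, edges = edges, polylines = polylines,
                 meshes = data.frame(id = integer(0), area = numeric(0)),
                 mesh_edges = list(), circles = angiomorph:::empty_circles(),
                 mode = "ETFA", dim = dim,
                 skeleton = matrix(0, dim[1], dim[2])),
            class = "angio_graph")
}

# Cached renders (computed once per R session running the tests)
.fixture_cache <- new.env()
cached_fba <- function(seed, ...) {
  key <- paste0("fba", seed, paste(c(...), collapse = "_"))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- render_fba(fba_scene(seed, ...))
  .fixture_cache[[key]]
}
cached_etfa <- function(seed, ...) {
  key <- paste0("etfa", seed, paste(c(...), collapse = "_"))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- render_etfa(etfa_scene(seed, ...))
  .fixture_cache[[key]]
}

# Standard analysis configuration for rendered scenes: sigma is the bead
# diameter, edge_radius the rendered envelope width, edge_thickness the
# apparent envelope width including optical blur, and pruning is set just
# below the shortest true edge length.
scene_sphere_params <- function() sphere_params(sigma = 80, edge_radius = 4,
                                                edge_thickness = 6)
scene_filter_params <- function(sigma = 80) filter_params(sigma = sigma,
                                                          fft_v2 = sigma)
# prune just below the shortest true edge (25 px); the isolated-element
# filter includes the ~6 px halo broadening of skeleton lengths
scene_graph_params <- function() graph_params(prune_min_branch = 12,
                                              min_object_size = 16)

analyze_fba_scene <- function(render) {
  circ <- detect_spheres(render$image, scene_sphere_params())
  mask <- segment_network(render$image, scene_filter_params(80))
  sk <- skeletonize_network(mask, circ, twig_length = 12)
  build_graph(sk, scene_graph_params(), mode = "FBA")
}

analyze_etfa_scene <- function(render) {
  mask <- segment_network(render$image, scene_filter_params(400))
  sk <- skeletonize_network(mask, twig_length = 12)
  build_graph(sk, scene_graph_params(), mode = "ETFA")
}

graph_counts <- function(g) {
  c(ajn = sum(g$junctions$is_anchorage),
    jn = sum(!g$junctions$is_anchorage),
    branches = sum(g$edges$kind == "branch"),
    segments = sum(g$edges$kind == "segment"),
    isolated = sum(g$edges$kind == "isolated"))
}
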