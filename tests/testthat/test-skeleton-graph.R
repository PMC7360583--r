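test_that("pixel classification matches the brute-force neighbor oracle", {
  # all 256 possible 8-neighborhoods around a foreground centre pixel
  for (code in 0:255) {
    bits <- as.integer(intToBits(code))[1:8]
    patch <- matrix(0, 3, 3)
    patch[2, 2] <- 1
    patch[cbind(2 + angiomorph:::.N8[, 1], 2 + angiomorph:::.N8[, 2])] <- bits
    sk <- matrix(0, 7, 7)
    sk[3:5, 3:5] <- patch
    cls <- classify_pixels(sk)
    n <- brute_neighbors(patch)
    expect_equal(any(cls$nodes[, 1] == 4 & cls$nodes[, 2] == 4), n >= 3,
                 info = paste("code", code))
    expect_equal(any(cls$extremities[, 1] == 4 & cls$extremities[, 2] == 4),
                 n == 1, info = paste("code", code))
  }
})

test_that("plus shapes and lines classify as expected", {
  # the centre and the four arm-root pixels all have >= 3 neighbours; the
  # 7-px dots merge them into a single junction
  cls <- classify_pixels(plus_skeleton(5))
  expect_gte(nrow(cls$nodes), 1)
  expect_true(any(cls$nodes[, 1] == 10 & cls$nodes[, 2] == 10))
  expect_equal(nrow(cls$extremities), 4)
  ju <- build_junctions(cls$nodes, graph_params(), c(21, 21))
  expect_equal(nrow(ju$junctions), 1)

  line <- blank_img(16)
  line[8, 4:13] <- 1
  cls <- classify_pixels(line)
  expect_equal(nrow(cls$nodes), 0)
  expect_equal(nrow(cls$extremities), 2)
})

test_that("node dots merge exactly when centres are within diameter - 1", {
  p <- graph_params()
  two_nodes <- function(d) rbind(c(50, 20), c(50, 20 + d))
  expect_equal(nrow(build_junctions(two_nodes(30), p, c(100, 100))$junctions), 2)
  expect_equal(nrow(build_junctions(two_nodes(5), p, c(100, 100))$junctions), 1)
  expect_equal(nrow(build_junctions(two_nodes(6), p, c(100, 100))$junctions), 1)
  expect_equal(nrow(build_junctions(two_nodes(7), p, c(100, 100))$junctions), 2)
  # a tight 4-node cluster is a single junction
  cluster <- rbind(c(50, 50), c(50, 51), c(51, 50), c(51, 51))
  j <- build_junctions(cluster, p, c(100, 100))
  expect_equal(nrow(j$junctions), 1)
  expect_equal(j$junctions$n_nodes, 4L)
})

test_that("edge tracing classifies Y, H and diagonal configurations", {
  p <- graph_params()
  # Y: three 20-px arms from a centre
  y <- blank_img(64)
  y <- draw_line(y, 32, 32, 12, 32)
  y <- draw_line(y, 32, 32, 46, 18)
  y <- draw_line(y, 32, 32, 46, 46)
  g <- build_graph(y, p, mode = "ETFA")
  expect_equal(sum(!g$junctions$is_anchorage), 1)
  expect_equal(sum(g$edges$kind == "branch"), 3)
  expect_equal(sum(g$edges$kind == "segment"), 0)

  # H: two verticals joined by a crossbar
  h <- blank_img(80)
  h <- draw_line(h, 10, 20, 70, 20)
  h <- draw_line(h, 10, 60, 70, 60)
  h <- draw_line(h, 40, 21, 40, 59)
  g <- build_graph(h, p, mode = "ETFA")
  expect_equal(sum(!g$junctions$is_anchorage), 2)
  expect_equal(sum(g$edges$kind == "segment"), 1)
  expect_equal(sum(g$edges$kind == "branch"), 4)

  # 45-degree diagonal of 10 pixels: isolated element of length 9 sqrt(2)
  d <- blank_img(32)
  d[cbind(5:14, 5:14)] <- 1
  cls <- classify_pixels(d)
  ju <- build_junctions(cls$nodes, p, dim(d))
  g <- trace_edges(d, ju, cls$extremities)
  expect_equal(g$edges$kind, "isolated")
  expect_equal(g$edges$length, 9 * sqrt(2), tolerance = 1e-9)
})

test_that("every skeleton path pixel is traced into exactly one edge", {
  r <- cached_etfa(201)
  mask <- segment_network(r$image, scene_filter_params(400))
  sk <- skeletonize_network(mask, twig_length = 12)
  cls <- classify_pixels(sk)
  ju <- build_junctions(cls$nodes, graph_params(), dim(sk$pixels))
  g <- trace_edges(sk, ju, cls$extremities)
  blob <- matrix(FALSE, nrow(sk$pixels), ncol(sk$pixels))
  for (px in g$junction_pixels) blob[px] <- TRUE
  # isolated single pixels (no neighbour) are dropped by classification
  nb <- angiomorph:::neighbor_count(sk$pixels)
  n_path <- sum(sk$pixels == 1 & !blob & nb > 0)
  n_traced <- sum(vapply(g$polylines, nrow, integer(1)))
  expect_gt(n_traced, 0.95 * n_path)
  expect_lte(n_traced, n_path)
  # and total edge length tracks the pixel-step total
  steps <- sum(vapply(g$polylines, angiomorph:::.step_length, numeric(1)))
  expect_equal(sum(g$edges$length), steps, tolerance = 1e-9)
})

test_that("junction fusion follows the distance rule transitively", {
  p <- graph_params()
  # two junctions 15 px apart joined by a short segment: fused
  g <- make_chain_graph(c(20, 35))
  deg_before <- sum(graph_degrees(g))
  g2 <- fuse_close_junctions(g, p)
  expect_equal(nrow(g2$junctions), 1)
  expect_equal(sum(g2$edges$kind == "segment"), 0)
  expect_equal(nrow(g2$edges), 2)  # the two terminal branches survive

  # 25 px apart: unchanged
  g <- make_chain_graph(c(20, 45))
  g2 <- fuse_close_junctions(g, p)
  expect_equal(nrow(g2$junctions), 2)
  expect_equal(sum(g2$edges$kind == "segment"), 1)

  # boundary: centroids 19 px apart fuse, 21 px apart do not
  expect_equal(nrow(fuse_close_junctions(make_chain_graph(c(20, 39)), p)$junctions), 1)
  expect_equal(nrow(fuse_close_junctions(make_chain_graph(c(20, 41)), p)$junctions), 2)

  # chain of 3 junctions at 12-px spacing collapses transitively
  g <- make_chain_graph(c(20, 32, 44))
  g2 <- fuse_close_junctions(g, p)
  expect_equal(nrow(g2$junctions), 1)

  # idempotence at the fixed point
  expect_identical(fuse_close_junctions(g2, p)$edges, g2$edges)
})

test_that("iterative pruning removes spurs and dissolves junctions", {
  p <- graph_params()
  # main line with one 3-px spur
  m <- blank_img(64)
  m <- draw_line(m, 32, 5, 32, 60)
  m <- draw_line(m, 31, 30, 29, 28)
  g <- build_graph(m, p, mode = "ETFA")
  expect_equal(nrow(g$junctions), 0)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$kind, "isolated")

  # comb with three 3-px teeth: all removed, backbone intact
  m <- blank_img(64)
  m <- draw_line(m, 40, 5, 40, 60)
  for (cc in c(22, 32, 42)) m <- draw_line(m, 39, cc, 37, cc)
  g <- build_graph(m, p, mode = "ETFA")
  expect_equal(nrow(g$junctions), 0)
  expect_equal(nrow(g$edges), 1)
  expect_gt(g$edges$length, 45)

  # a branch of exactly the pruning threshold is kept (strict <)
  g <- make_chain_graph(c(20, 60))
  ext_id <- max(g$extremities$id) + 1L
  g$extremities <- rbind(g$extremities,
                         data.frame(id = ext_id, row = 60L, col = 20L))
  g$edges <- rbind(g$edges,
                   data.frame(id = max(g$edges$id) + 1L, kind = "branch",
                              from_type = "junction", from_id = 1L,
                              to_type = "extremity", to_id = ext_id,
                              length = p$prune_min_branch))
  g$polylines[[as.character(max(g$edges$id))]] <-
    cbind(51:60, 20L)
  g2 <- prune_small_branches(g, p)
  expect_true(any(g2$edges$length == p$prune_min_branch))
  # and one just below the threshold is removed
  g$edges$length[nrow(g$edges)] <- p$prune_min_branch - 0.5
  g3 <- prune_small_branches(g, p)
  expect_false(any(g3$edges$to_id == ext_id & g3$edges$to_type == "extremity"))
  # idempotence
  expect_identical(prune_small_branches(g2, p)$edges, g2$edges)
})

test_that("anchorage detection flags ring contacts and removes rim arcs", {
  p <- graph_params()
  circ <- data.frame(cx = 50, cy = 50, radius = 30, fit_residual = 0)
  # radial sprout leaving the rim: rim end becomes one anchorage junction
  m <- blank_img(120)
  m <- draw_line(m, 50, 81, 50, 110)
  cls <- classify_pixels(m)
  ju <- build_junctions(cls$nodes, p, dim(m))
  g <- trace_edges(m, ju, cls$extremities)
  g$circles <- circ
  g2 <- classify_anchorage(g, circ)
  expect_equal(sum(g2$junctions$is_anchorage), 1)
  expect_equal(g2$edges$kind, "branch")

  # residual arc of the rim itself: deleted as a circle piece
  theta <- seq(0, pi / 2, length.out = 200)
  arc <- blank_img(120)
  arc[unique(cbind(round(50 + 30 * sin(theta)), round(50 + 30 * cos(theta))))] <- 1
  arc <- thin_mask(arc)
  cls <- classify_pixels(arc)
  ju <- build_junctions(cls$nodes, p, dim(arc))
  g <- trace_edges(arc, ju, cls$extremities)
  g$circles <- circ
  g2 <- classify_anchorage(g, circ)
  expect_equal(nrow(g2$edges), 0)

  # junction far inside the tree is not anchorage
  m <- blank_img(160)
  m <- draw_line(m, 100, 81, 100, 140)   # but junction at (100, 120)
  m <- draw_line(m, 100, 120, 80, 120)
  cls <- classify_pixels(m)
  ju <- build_junctions(cls$nodes, p, dim(m))
  g <- trace_edges(m, ju, cls$extremities)
  circ_far <- data.frame(cx = 20, cy = 20, radius = 10, fit_residual = 0)
  g$circles <- circ_far
  g2 <- classify_anchorage(g, circ_far)
  expect_equal(sum(g2$junctions$is_anchorage), 0)

  expect_warning(classify_anchorage(g, angiomorph:::empty_circles()),
                 "without circles")
})

test_that("small isolated elements are removed with a strict boundary", {
  p <- graph_params()
  base <- make_chain_graph(c(20, 60))
  add_iso <- function(g, len) {
    ids <- max(g$extremities$id) + 1:2
    g$extremities <- rbind(g$extremities,
                           data.frame(id = ids, row = c(80L, 80L),
                                      col = c(5L, 5L + as.integer(len))))
    eid <- max(g$edges$id) + 1L
    g$edges <- rbind(g$edges,
                     data.frame(id = eid, kind = "isolated",
                                from_type = "extremity", from_id = ids[1],
                                to_type = "extremity", to_id = ids[2],
                                length = len))
    g$polylines[[as.character(eid)]] <- cbind(80L, 5:(5 + as.integer(len)))
    g
  }
  g <- add_iso(base, 9)
  expect_equal(sum(remove_small_isolated(g, p)$edges$kind == "isolated"), 0)
  g <- add_iso(base, 10)
  expect_equal(sum(remove_small_isolated(g, p)$edges$kind == "isolated"), 1)
  # a short branch is untouched by this filter
  g <- make_chain_graph(c(20, 60))
  g$edges$kind[g$edges$kind == "branch"][1] <- "branch"
  n_br <- sum(g$edges$kind == "branch")
  expect_equal(sum(remove_small_isolated(g, p)$edges$kind == "branch"), n_br)
})

test_that("meshes are the bounded faces of the skeleton complement", {
  p <- graph_params()
  # 2x2 grid: 3 horizontal + 3 vertical lines -> 4 meshes
  m <- blank_img(100)
  for (r in c(20, 50, 80)) m <- draw_line(m, r, 20, r, 80)
  for (c in c(20, 50, 80)) m <- draw_line(m, 20, c, 80, c)
  g <- build_graph(m, p, mode = "ETFA")
  expect_equal(nrow(g$meshes), 4)
  expect_equal(cyclomatic_number(g), 4)
  # flood-fill oracle on the complement agrees
  lab <- EBImage::bwlabel(angiomorph:::as_mask(m == 0))
  lab <- matrix(as.integer(lab), 100, 100)
  border <- unique(c(lab[1, ], lab[100, ], lab[, 1], lab[, 100]))
  expect_equal(length(setdiff(unique(lab[lab > 0]), border)), 4)

  # tree with no cycles -> 0 meshes
  g <- build_graph(plus_skeleton(20), p, mode = "ETFA")
  expect_equal(nrow(g$meshes), 0)

  # 100x100 square loop: one mesh of 98^2 interior pixels
  m <- blank_img(120)
  m <- draw_line(m, 10, 10, 10, 109); m <- draw_line(m, 109, 10, 109, 109)
  m <- draw_line(m, 10, 10, 109, 10); m <- draw_line(m, 10, 109, 109, 109)
  g <- build_graph(m, p, mode = "ETFA")
  expect_equal(nrow(g$meshes), 1)
  expect_equal(g$meshes$area, 98^2)
})

test_that("closed loops with no node become self-loop segments", {
  m <- blank_img(80)
  theta <- seq(0, 2 * pi, length.out = 400)
  m[unique(cbind(round(40 + 20 * sin(theta)), round(40 + 20 * cos(theta))))] <- 1
  m <- thin_mask(m)
  expect_message(g <- build_graph(m, graph_params(), mode = "ETFA"),
                 "self-loop")
  expect_equal(nrow(g$meshes), 1)
  expect_equal(cyclomatic_number(g), 1)
})

test_that("built graphs satisfy the handshake and mesh-cycle identities", {
  for (seed in c(201, 202, 203)) {
    g <- analyze_etfa_scene(cached_etfa(seed))
    expect_true(validate_graph(g))
    expect_equal(nrow(g$meshes), cyclomatic_number(g))
  }
  g <- analyze_fba_scene(cached_fba(101, shading_amp = 0))
  expect_true(validate_graph(g))
})

test_that("graph recovery is exact on rendered fixtures", {
  # FBA: a bifurcated multi-sprout scene
  r <- cached_fba(107)
  g <- analyze_fba_scene(r)
  tr <- r$truth$counts
  expect_equal(unname(graph_counts(g)[c("ajn", "jn", "branches", "segments")]),
               c(tr$anchorage, tr$junctions, tr$branches, tr$segments))
  # ETFA honeycomb-like tiling: Euler consistency V - E + F = 2
  r <- cached_etfa(205)
  g <- analyze_etfa_scene(r)
  expect_equal(nrow(g$meshes), r$truth$counts$meshes)
  v <- nrow(g$junctions) + nrow(g$extremities)
  comp <- graph_components(g)
  f <- nrow(g$meshes) + length(unique(comp))  # bounded faces + outer per comp
  expect_equal(v - nrow(g$edges) + f, 2 * length(unique(comp)))

  # empty skeleton -> empty graph
  g <- build_graph(blank_img(32), graph_params(), mode = "ETFA")
  expect_equal(nrow(g$edges), 0)
  expect_equal(nrow(g$junctions), 0)
})
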