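test_that("scene rendering is deterministic under a seed", {
  r1 <- render_fba(fba_scene(42))
  r2 <- render_fba(fba_scene(42))
  expect_identical(r1$image, r2$image)
  expect_identical(r1$truth$counts, r2$truth$counts)
  r3 <- render_etfa(etfa_scene(42))
  r4 <- render_etfa(etfa_scene(42))
  expect_identical(r3$image, r4$image)
  # different seeds differ
  expect_false(identical(r1$image, render_fba(fba_scene(43))$image))
  # rendering does not disturb the caller's RNG stream
  set.seed(99); a <- runif(3)
  set.seed(99); invisible(render_fba(fba_scene(7))); b <- runif(3)
  expect_identical(a, b)
})

test_that("ground truths are internally Euler-consistent", {
  for (seed in 301:312) {
    spec <- etfa_scene(seed)
    tr <- gt_reduce(spec$vertices, spec$edges)
    # mesh count from E - V + C equals the flood-fill area count
    r <- cached_etfa(seed)
    expect_equal(length(r$truth$mesh_areas), tr$meshes,
                 info = paste("seed", seed))
  }
  for (seed in 301:306) {
    spec <- fba_scene(seed)
    tr <- gt_reduce(spec$vertices, spec$edges)
    expect_equal(tr$meshes, 0)  # sprouting trees are acyclic
    expect_equal(tr$anchorage, sum(spec$vertices$anchor))
  }
})

test_that("the reducer classifies grids, trees and cycles correctly", {
  # 2x2 jittered grid: 5 junctions, 8 segments, 4 meshes
  spec <- etfa_scene(1, n_cells = 4, n_dangling = 0, fragment_lengths = 0)
  tr <- gt_reduce(spec$vertices, spec$edges)
  expect_equal(tr$junctions, 5)
  expect_equal(tr$segments, 8)
  expect_equal(tr$branches, 0)
  expect_equal(tr$meshes, 4)
  # single cell: a pure cycle -> synthetic junction with one self-loop
  spec <- etfa_scene(2, n_cells = 1, n_dangling = 0, fragment_lengths = 0)
  tr <- gt_reduce(spec$vertices, spec$edges)
  expect_equal(tr$meshes, 1)
  expect_equal(tr$junctions, 1)
  expect_equal(tr$segments, 1)
})

test_that("scene geometry honours the separation constraints", {
  for (seed in 401:415) {
    spec <- fba_scene(seed)
    b <- spec$beads
    if (nrow(b) > 1) {
      dd <- as.matrix(dist(cbind(b$cy, b$cx)))
      for (i in seq_len(nrow(b) - 1)) for (j in (i + 1):nrow(b))
        expect_gte(dd[i, j], b$radius[i] + b$radius[j] + max(b$radius[i], b$radius[j]))
    }
    # every true edge is at least 20 px long (fusion/pruning safe)
    v <- spec$vertices; e <- spec$edges
    lens <- sqrt((v$row[e$v1] - v$row[e$v2])^2 + (v$col[e$v1] - v$col[e$v2])^2)
    expect_true(all(lens >= 20))
  }
})

test_that("small isolated fragments are filtered out of built graphs", {
  # the halo blob of a fragment broadens its skeleton by several pixels,
  # so only clearly sub-cell debris falls below the 10-px filter
  spec <- etfa_scene(11, n_cells = 4, n_dangling = 0,
                     fragment_lengths = c(3, 6))
  r <- render_etfa(spec)
  g <- analyze_etfa_scene(r)
  expect_equal(sum(g$edges$kind == "isolated"), 0)
  # a pure tree has no mesh area
  spec <- structure(list(
    mode = "ETFA", seed = 12, size = 256,
    beads = data.frame(cy = numeric(0), cx = numeric(0), radius = numeric(0)),
    vertices = data.frame(id = 1:4, row = c(128, 128, 60, 196),
                          col = c(60, 128, 196, 196),
                          anchor = FALSE, bead = NA_integer_),
    edges = data.frame(v1 = c(1, 2, 2), v2 = c(2, 3, 4)),
    noise_sd = 0.005, shading_amp = 0, rim_width = 4), class = "scene_spec")
  r <- render_etfa(spec)
  g <- analyze_etfa_scene(r)
  expect_equal(measure_etfa(g)$TMA, 0)
})

test_that("perturbation sweeps render each override", {
  spec <- fba_scene(5, n_beads = 1)
  base <- perturbation_suite(spec)
  expect_length(base, 1)
  expect_identical(base[[1]]$image, render_fba(spec)$image)
  sweep <- perturbation_suite(spec, list(list(shading_amp = 0),
                                         list(shading_amp = 0.3),
                                         list(noise_sd = 0.04)))
  expect_length(sweep, 3)
  # shading sweep: detected centres drift under 3 px
  centres <- lapply(sweep[1:2], function(x)
    detect_spheres(x$image, scene_sphere_params()))
  expect_equal(nrow(centres[[1]]), nrow(centres[[2]]))
  expect_lt(abs(centres[[1]]$cy - centres[[2]]$cy) +
              abs(centres[[1]]$cx - centres[[2]]$cx), 3)
})
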