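# Internal pixel-grid helpers shared across the package. Images are plain
# numeric matrices indexed [row, col]; masks are 0/1 matrices of the same
# shape. All geometry is in pixel units.

#' @importFrom stats rnorm runif sd
NULL

.angio_eps <- function(img) {
  m <- max(img)
  if (!is.finite(m) || m <= 0) m <- 1
  1e-6 * m
}

check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (nrow(img) < 16 || ncol(img) < 16)
    stop(sprintf("'%s' must be at least 16 x 16 pixels", arg), call. = FALSE)
  if (any(!is.finite(img)))
    stop(sprintf("'%s' contains non-finite intensities", arg), call. = FALSE)
  invisible(img)
}

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask))
    stop(sprintf("'%s' must be a matrix", arg), call. = FALSE)
  invisible(mask)
}

as_mask <- function(x) {
  m <- (x > 0) * 1
  storage.mode(m) <- "double"
  m
}

# Discrete disc: pixels whose centre lies within 'r' of the kernel centre.
# r = 2 gives the 13-pixel neighbourhood.
disc_kernel <- function(r) {
  stopifnot(r >= 0)
  w <- floor(r)
  ix <- -w:w
  k <- outer(ix, ix, function(dy, dx) as.numeric(dy^2 + dx^2 <= r^2 + 1e-9))
  k
}

# Shift a matrix by (dr, dc), filling vacated cells.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) == 0 || length(cs) == 0) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

.N8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1,  0,  1, -1, 1, -1, 0, 1))

# Count of foreground 8-neighbours for every pixel.
neighbor_count <- function(mask) {
  acc <- matrix(0, nrow(mask), ncol(mask))
  for (k in seq_len(8))
    acc <- acc + shift_mat(mask, .N8[k, 1], .N8[k, 2])
  acc
}

# 8-connected labelling of a binary mask via run-length union-find.
# EBImage::bwlabel is 4-connected, which is what mesh faces need, but
# skeletons and bead masks are 8-connected objects.
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  runs_row <- integer(0); runs_cs <- integer(0); runs_ce <- integer(0)
  for (r in seq_len(nr)) {
    fc <- which(mask[r, ] > 0)
    if (!length(fc)) next
    starts <- fc[c(TRUE, diff(fc) > 1L)]
    ends   <- fc[c(diff(fc) > 1L, TRUE)]
    runs_row <- c(runs_row, rep.int(r, length(starts)))
    runs_cs <- c(runs_cs, starts)
    runs_ce <- c(runs_ce, ends)
  }
  n <- length(runs_row)
  if (n == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  prev_idx <- integer(0); prev_row <- -1L
  cur_start <- 1L
  i <- 1L
  while (i <= n) {
    r <- runs_row[i]
    j <- i
    while (j <= n && runs_row[j] == r) j <- j + 1L
    cur_idx <- i:(j - 1L)
    if (prev_row == r - 1L) {
      for (a in cur_idx) {
        for (b in prev_idx) {
          if (runs_cs[a] <= runs_ce[b] + 1L && runs_ce[a] >= runs_cs[b] - 1L) {
            ra <- find(a); rb <- find(b)
            if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
          }
        }
      }
    }
    prev_idx <- cur_idx; prev_row <- r
    i <- j
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  for (k in seq_len(n))
    lab[runs_row[k], runs_cs[k]:runs_ce[k]] <- ids[k]
  lab
}

# Coordinates (row, col) of foreground pixels.
mask_which <- function(mask) {
  idx <- which(mask > 0)
  cbind(row = ((idx - 1L) %% nrow(mask)) + 1L,
        col = ((idx - 1L) %/% nrow(mask)) + 1L)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Squared distance from every pixel centre to a point (row, col).
pixel_dist2 <- function(nr, nc, row, col) {
  outer((seq_len(nr) - row)^2, (seq_len(nc) - col)^2, `+`)
}
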