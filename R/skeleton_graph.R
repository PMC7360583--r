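# Conversion of a 1-px skeleton into the vectorial object model: node
# pixels and extremities, junctions (blobs of 7-px dots stamped on nodes),
# branches / segments / isolated elements, junction fusion, iterative
# pruning, anchorage junctions (FBA) and meshes (ETFA).

#' Graph extraction parameters
#'
#' @param node_dot_diameter diameter in pixels of the dot stamped on each
#'   node pixel (default 7); dots whose centres are closer than the
#'   diameter merge into one junction.
#' @param junction_fusion_distance junctions closer than this (centroid
#'   distance, pixels) joined by a short segment are fused (default 20,
#'   removing segments shorter than two aligned cells).
#' @param min_object_size isolated elements shorter than this are removed
#'   (default 10 px, the size of an isolated cell).
#' @param prune_min_branch branches shorter than this are pruned
#'   iteratively (default 10 px).
#' @return list of validated parameters, class \code{"graph_params"}.
#' @export
graph_params <- function(node_dot_diameter = 7, junction_fusion_distance = 20,
                         min_object_size = 10, prune_min_branch = 10) {
  p <- list(node_dot_diameter = node_dot_diameter,
            junction_fusion_distance = junction_fusion_distance,
            min_object_size = min_object_size,
            prune_min_branch = prune_min_branch)
  if (any(unlist(p) <= 0)) stop("all graph parameters must be positive")
  structure(p, class = "graph_params")
}

.skeleton_pixels <- function(sk) {
  if (inherits(sk, "angio_skeleton")) sk$pixels else as_mask(sk)
}

#' Classify skeleton pixels
#'
#' Every skeleton pixel is classified by its number of foreground
#' 8-neighbours: at least 3 makes a node pixel (minimal bifurcation unit),
#' exactly 1 an extremity, exactly 2 a path pixel. Isolated pixels with no
#' neighbour are dropped.
#'
#' @param sk skeleton (\code{"angio_skeleton"} or 0/1 matrix).
#' @return list with \code{nodes} and \code{extremities}, each a
#'   (row, col) matrix.
#' @export
classify_pixels <- function(sk) {
  m <- .skeleton_pixels(sk)
  nb <- neighbor_count(m)
  list(nodes = mask_which(as_mask(m == 1 & nb >= 3)),
       extremities = mask_which(as_mask(m == 1 & nb == 1)))
}

#' Group node pixels into junctions
#'
#' Each node pixel is replaced by a circular dot of
#' \code{node_dot_diameter} pixels; dots that overlap (centre distance at
#' most diameter - 1) form one junction blob, absorbing skeletonization
#' artifacts near bifurcations.
#'
#' @param nodes (row, col) matrix of node pixels.
#' @param p \code{\link{graph_params}}.
#' @param dim image dimensions c(nrow, ncol), used to clip the stamped dots.
#' @return list with \code{junctions} (data frame id, cy, cx, is_anchorage,
#'   n_nodes, circle_id) and \code{pixels} (list of blob pixel matrices,
#'   one per junction).
#' @export
build_junctions <- function(nodes, p, dim) {
  n <- nrow(nodes)
  empty <- data.frame(id = integer(0), cy = numeric(0), cx = numeric(0),
                      is_anchorage = logical(0), n_nodes = integer(0),
                      circle_id = integer(0))
  if (is.null(nodes) || n == 0) return(list(junctions = empty, pixels = list()))
  thr2 <- (p$node_dot_diameter - 1)^2
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) {
    d2 <- (nodes[(i + 1):n, 1] - nodes[i, 1])^2 + (nodes[(i + 1):n, 2] - nodes[i, 2])^2
    for (j in which(d2 <= thr2)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  gid <- match(roots, sort(unique(roots)))
  rad <- (p$node_dot_diameter - 1) / 2
  offs <- mask_which(disc_kernel(rad)) - (floor(rad) + 1)
  juncs <- empty
  pix_list <- list()
  for (g in sort(unique(gid))) {
    members <- nodes[gid == g, , drop = FALSE]
    px <- unique(do.call(rbind, lapply(seq_len(nrow(members)), function(k)
      cbind(members[k, 1] + offs[, 1], members[k, 2] + offs[, 2]))))
    px <- px[px[, 1] >= 1 & px[, 1] <= dim[1] & px[, 2] >= 1 & px[, 2] <= dim[2], , drop = FALSE]
    juncs <- rbind(juncs, data.frame(id = g, cy = mean(members[, 1]),
                                     cx = mean(members[, 2]),
                                     is_anchorage = FALSE,
                                     n_nodes = nrow(members),
                                     circle_id = NA_integer_))
    pix_list[[as.character(g)]] <- px
  }
  list(junctions = juncs, pixels = pix_list)
}

.step_length <- function(poly) {
  if (is.null(poly) || nrow(poly) < 2) return(0)
  d <- abs(diff(poly[, 1])) + abs(diff(poly[, 2]))
  sum(ifelse(d == 2, sqrt(2), 1))
}

.edge_kind <- function(ft, tt) {
  if (ft == "junction" && tt == "junction") "segment"
  else if (ft == "extremity" && tt == "extremity") "isolated"
  else "branch"
}

# Ordered walk through a chain of path pixels starting at 'start' (local
# index), using the local adjacency.
.walk_chain <- function(pix, start) {
  n <- nrow(pix)
  if (n == 1) return(1L)
  key <- paste(pix[, 1], pix[, 2])
  lookup <- new.env(hash = TRUE, size = n * 2)
  for (i in seq_len(n)) assign(key[i], i, envir = lookup)
  visited <- logical(n)
  order <- integer(n)
  cur <- start
  for (step in seq_len(n)) {
    order[step] <- cur
    visited[cur] <- TRUE
    nxt <- 0L
    for (k in seq_len(8)) {
      kk <- paste(pix[cur, 1] + .N8[k, 1], pix[cur, 2] + .N8[k, 2])
      j <- mget(kk, envir = lookup, ifnotfound = list(0L))[[1]]
      if (j > 0L && !visited[j]) { nxt <- j; break }
    }
    if (nxt == 0L) break
    cur <- nxt
  }
  order[order > 0L]
}

#' Trace edges between terminals
#'
#' Removes the junction blobs from the skeleton and walks the remaining
#' chains of path pixels. Each chain becomes one edge whose terminals are
#' the adjacent junction blobs or its own extremity pixels; the edge kind
#' follows the terminal types (junction + extremity = branch, two
#' junctions = segment, two extremities = isolated element). Lengths
#' accumulate 1 per axial and sqrt(2) per diagonal step. A closed chain
#' with no terminal is emitted as a self-loop segment on a synthetic
#' junction.
#'
#' @param sk skeleton.
#' @param junctions result of \code{\link{build_junctions}}.
#' @param extremities (row, col) matrix from \code{\link{classify_pixels}}.
#' @return an \code{"angio_graph"} object (junctions, extremities, edges,
#'   polylines); meshes are added later by \code{\link{detect_meshes}}.
#' @export
trace_edges <- function(sk, junctions, extremities) {
  m <- .skeleton_pixels(sk)
  nr <- nrow(m); nc <- ncol(m)
  juncs <- junctions$junctions
  jpix <- junctions$pixels
  jlab <- matrix(0L, nr, nc)
  for (id in names(jpix)) {
    px <- jpix[[id]]
    if (nrow(px)) jlab[px] <- as.integer(id)
  }
  ext_id <- matrix(0L, nr, nc)
  exts <- data.frame(id = integer(0), row = integer(0), col = integer(0))
  if (!is.null(extremities) && nrow(extremities)) {
    exts <- data.frame(id = seq_len(nrow(extremities)),
                       row = extremities[, 1], col = extremities[, 2])
    ext_id[extremities] <- exts$id
  }
  path <- as_mask(m == 1 & jlab == 0)
  chains <- label8(path)
  edges <- data.frame(id = integer(0), kind = character(0),
                      from_type = character(0), from_id = integer(0),
                      to_type = character(0), to_id = integer(0),
                      length = numeric(0))
  polylines <- list()
  next_eid <- 1L
  extra_pairs <- list()
  note_pair <- function(a, b) {
    extra_pairs[[paste(min(a, b), max(a, b))]] <<- c(min(a, b), max(a, b))
  }

  adj_junctions <- function(r, c) {
    rs <- max(1, r - 1):min(nr, r + 1)
    cs <- max(1, c - 1):min(nc, c + 1)
    v <- unique(as.vector(jlab[rs, cs]))
    v[v > 0L]
  }

  add_edge <- function(ft, fi, tt, ti, poly) {
    kind <- .edge_kind(ft, tt)
    edges[nrow(edges) + 1L, ] <<- list(next_eid, kind, ft, fi, tt, ti,
                                       .step_length(poly))
    polylines[[as.character(next_eid)]] <<- poly
    next_eid <<- next_eid + 1L
  }

  nchain <- max(chains)
  for (cid in seq_len(nchain)) {
    pix <- mask_which(as_mask(chains == cid))
    pix <- pix[order(pix[, 1], pix[, 2]), , drop = FALSE]
    n <- nrow(pix)
    # degree within chain
    deg <- integer(n)
    key <- paste(pix[, 1], pix[, 2])
    lookup <- new.env(hash = TRUE, size = n * 2)
    for (i in seq_len(n)) assign(key[i], i, envir = lookup)
    for (i in seq_len(n)) {
      for (k in seq_len(8)) {
        kk <- paste(pix[i, 1] + .N8[k, 1], pix[i, 2] + .N8[k, 2])
        if (mget(kk, envir = lookup, ifnotfound = list(0L))[[1]] > 0L)
          deg[i] <- deg[i] + 1L
      }
    }
    ends <- which(deg <= 1L)
    if (n == 1L) {
      r <- pix[1, 1]; c <- pix[1, 2]
      terms <- list()
      if (ext_id[r, c] > 0L)
        terms <- c(terms, list(list(type = "extremity", id = ext_id[r, c])))
      ja <- adj_junctions(r, c)
      for (j in ja)
        terms <- c(terms, list(list(type = "junction", id = j)))
      if (length(ja) > 2)
        for (q in 3:length(ja)) note_pair(ja[1], ja[q])
      if (length(terms) >= 2) {
        add_edge(terms[[1]]$type, terms[[1]]$id, terms[[2]]$type,
                 terms[[2]]$id, pix)
      } else if (length(terms) == 1 && terms[[1]]$type == "junction") {
        # one-pixel nub on a junction blob: absorbed into the blob
        jc <- as.character(terms[[1]]$id)
        jpix[[jc]] <- unique(rbind(jpix[[jc]], pix))
      }
      next
    }
    if (length(ends) == 0L) {
      # closed loop without any node: self-loop on a synthetic junction
      ord <- .walk_chain(pix, 1L)
      poly <- pix[ord, , drop = FALSE]
      jid <- if (nrow(juncs)) max(juncs$id) + 1L else 1L
      juncs <- rbind(juncs, data.frame(id = jid, cy = pix[1, 1], cx = pix[1, 2],
                                       is_anchorage = FALSE, n_nodes = 0L,
                                       circle_id = NA_integer_))
      jpix[[as.character(jid)]] <- pix[1, , drop = FALSE]
      message("closed loop without node: emitted as self-loop segment")
      add_edge("junction", jid, "junction", jid, poly)
      next
    }
    ord <- .walk_chain(pix, ends[1])
    poly <- pix[ord, , drop = FALSE]
    terminal_of <- function(p_row) {
      r <- p_row[1]; c <- p_row[2]
      if (ext_id[r, c] > 0L) return(list(type = "extremity", id = ext_id[r, c]))
      j <- adj_junctions(r, c)
      if (length(j)) {
        # an endpoint squeezed between several blobs connects them all
        if (length(j) > 1) for (q in 2:length(j)) note_pair(j[1], j[q])
        return(list(type = "junction", id = j[1]))
      }
      # dangling chain end with no terminal: promote to extremity
      nid <- if (nrow(exts)) max(exts$id) + 1L else 1L
      exts <<- rbind(exts, data.frame(id = nid, row = r, col = c))
      ext_id[r, c] <<- nid
      list(type = "extremity", id = nid)
    }
    t1 <- terminal_of(poly[1, ])
    t2 <- terminal_of(poly[nrow(poly), ])
    add_edge(t1$type, t1$id, t2$type, t2$id, poly)
  }
  # touching junctions: blobs whose pixels are 8-adjacent (or joined only
  # through a shared chain endpoint) but with no connecting chain get a
  # zero-length segment, so the graph keeps the skeleton's connectivity;
  # fusion merges them later and removes any sliver cycles this creates
  pairs <- extra_pairs
  bpx <- mask_which(as_mask(jlab > 0))
  for (i in seq_len(nrow(bpx))) {
    a <- jlab[bpx[i, 1], bpx[i, 2]]
    for (k in seq_len(8)) {
      rr <- bpx[i, 1] + .N8[k, 1]; cc <- bpx[i, 2] + .N8[k, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      b <- jlab[rr, cc]
      if (b > 0L && b != a)
        pairs[[paste(min(a, b), max(a, b))]] <- c(min(a, b), max(a, b))
    }
  }
  for (pr in pairs) {
    direct <- any(edges$from_type == "junction" & edges$to_type == "junction" &
                    pmin(edges$from_id, edges$to_id) == pr[1] &
                    pmax(edges$from_id, edges$to_id) == pr[2])
    if (!direct) {
      px1 <- jpix[[as.character(pr[1])]]
      add_edge("junction", pr[1], "junction", pr[2], px1[1, , drop = FALSE])
    }
  }
  # prune extremity records not referenced by any edge (absorbed in blobs)
  used <- unique(c(edges$from_id[edges$from_type == "extremity"],
                   edges$to_id[edges$to_type == "extremity"]))
  exts <- exts[exts$id %in% used, , drop = FALSE]
  structure(list(junctions = juncs, junction_pixels = jpix,
                 extremities = exts, edges = edges, polylines = polylines,
                 meshes = data.frame(id = integer(0), area = numeric(0)),
                 mesh_edges = list(),
                 circles = if (inherits(sk, "angio_skeleton")) sk$circles else empty_circles(),
                 mode = if (inherits(sk, "angio_skeleton")) sk$mode else "ETFA",
                 dim = c(nr, nc), skeleton = m),
            class = "angio_graph")
}

# ---- graph bookkeeping ----------------------------------------------------

#' Junction degrees
#'
#' Number of edge endpoints incident to each junction (a self-loop counts
#' twice).
#'
#' @param g an \code{"angio_graph"}.
#' @return named integer vector indexed by junction id.
#' @export
graph_degrees <- function(g) {
  ids <- g$junctions$id
  deg <- setNames(integer(length(ids)), as.character(ids))
  for (side in c("from", "to")) {
    tt <- g$edges[[paste0(side, "_type")]]
    ii <- g$edges[[paste0(side, "_id")]]
    tab <- table(ii[tt == "junction"])
    deg[names(tab)] <- deg[names(tab)] + as.integer(tab)
  }
  deg
}

.vertex_keys <- function(g) {
  c(paste0("j", g$junctions$id), paste0("e", g$extremities$id))
}

#' Connected components of the vectorial graph
#'
#' @param g an \code{"angio_graph"}.
#' @return named integer vector: component id per vertex key ("j<id>" for
#'   junctions, "e<id>" for extremities).
#' @export
graph_components <- function(g) {
  keys <- .vertex_keys(g)
  n <- length(keys)
  comp <- setNames(seq_len(n), keys)
  if (n == 0) return(comp)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  idx <- setNames(seq_len(n), keys)
  for (k in seq_len(nrow(g$edges))) {
    a <- idx[[paste0(substr(g$edges$from_type[k], 1, 1), g$edges$from_id[k])]]
    b <- idx[[paste0(substr(g$edges$to_type[k], 1, 1), g$edges$to_id[k])]]
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  setNames(match(roots, sort(unique(roots))), keys)
}

#' Cyclomatic number E - V + C of the vectorial graph
#'
#' Equals the number of independent cycles, hence the expected mesh count
#' of a planar network.
#'
#' @param g an \code{"angio_graph"}.
#' @return integer.
#' @export
cyclomatic_number <- function(g) {
  comp <- graph_components(g)
  nrow(g$edges) - length(comp) + length(unique(comp))
}

#' Check structural invariants of a graph
#'
#' Verifies that every edge endpoint resolves to an existing junction or
#' extremity and that the handshake identity holds: the junction degree sum
#' equals the number of junction-side edge endpoints.
#'
#' @param g an \code{"angio_graph"}.
#' @return TRUE invisibly; stops on violation.
#' @export
validate_graph <- function(g) {
  jids <- g$junctions$id; eids <- g$extremities$id
  for (side in c("from", "to")) {
    tt <- g$edges[[paste0(side, "_type")]]
    ii <- g$edges[[paste0(side, "_id")]]
    bad <- (tt == "junction" & !(ii %in% jids)) |
      (tt == "extremity" & !(ii %in% eids))
    if (any(bad)) stop("edge endpoint does not resolve")
  }
  njref <- sum(g$edges$from_type == "junction") + sum(g$edges$to_type == "junction")
  if (sum(graph_degrees(g)) != njref) stop("handshake identity violated")
  invisible(TRUE)
}

.drop_orphan_extremities <- function(g) {
  used <- unique(c(g$edges$from_id[g$edges$from_type == "extremity"],
                   g$edges$to_id[g$edges$to_type == "extremity"]))
  g$extremities <- g$extremities[g$extremities$id %in% used, , drop = FALSE]
  g
}

.reclassify_edges <- function(g) {
  if (nrow(g$edges))
    g$edges$kind <- mapply(.edge_kind, g$edges$from_type, g$edges$to_type)
  g
}

# ---- fusion ---------------------------------------------------------------

#' Fuse close junctions
#'
#' While any segment shorter than \code{junction_fusion_distance} connects
#' two junctions whose centroids are closer than that distance, the two
#' junctions are merged (centroid: node-count-weighted mean), the
#' connecting segment removed and the remaining edges reattached. Segments
#' shorter than two aligned cells cannot represent a real tube and are
#' treated as one bifurcation. Candidates are processed shortest first
#' (ties by edge id) and iterated to a fixed point.
#'
#' @param g an \code{"angio_graph"}.
#' @param p \code{\link{graph_params}}.
#' @return updated graph.
#' @export
fuse_close_junctions <- function(g, p) {
  repeat {
    e <- g$edges
    # self-loops below the fusion scale are collapsed artifacts (two
    # already-fused junctions joined by both sides of a pinhole loop)
    loops <- which(e$from_type == "junction" & e$to_type == "junction" &
                     e$from_id == e$to_id & e$length < p$junction_fusion_distance)
    if (length(loops)) {
      for (k in loops) g$polylines[[as.character(e$id[k])]] <- NULL
      g$edges <- e[-loops, , drop = FALSE]
      next
    }
    cand <- which(e$kind == "segment" & e$from_type == "junction" &
                    e$to_type == "junction" & e$from_id != e$to_id &
                    e$length < p$junction_fusion_distance)
    if (length(cand)) {
      j <- g$junctions
      ctr <- function(id) unlist(j[j$id == id, c("cy", "cx")])
      dist_ok <- vapply(cand, function(k) {
        a <- ctr(e$from_id[k]); b <- ctr(e$to_id[k])
        sqrt(sum((a - b)^2)) < p$junction_fusion_distance
      }, logical(1))
      cand <- cand[dist_ok]
    }
    if (!length(cand)) break
    k <- cand[order(e$length[cand], e$id[cand])][1]
    id1 <- min(e$from_id[k], e$to_id[k])
    id2 <- max(e$from_id[k], e$to_id[k])
    j <- g$junctions
    r1 <- which(j$id == id1); r2 <- which(j$id == id2)
    w1 <- max(j$n_nodes[r1], 1L); w2 <- max(j$n_nodes[r2], 1L)
    j$cy[r1] <- (j$cy[r1] * w1 + j$cy[r2] * w2) / (w1 + w2)
    j$cx[r1] <- (j$cx[r1] * w1 + j$cx[r2] * w2) / (w1 + w2)
    j$n_nodes[r1] <- j$n_nodes[r1] + j$n_nodes[r2]
    j$is_anchorage[r1] <- j$is_anchorage[r1] || j$is_anchorage[r2]
    if (is.na(j$circle_id[r1])) j$circle_id[r1] <- j$circle_id[r2]
    g$junction_pixels[[as.character(id1)]] <-
      unique(rbind(g$junction_pixels[[as.character(id1)]],
                   g$junction_pixels[[as.character(id2)]]))
    g$junction_pixels[[as.character(id2)]] <- NULL
    g$junctions <- j[j$id != id2, , drop = FALSE]
    # delete fused segment, reattach others
    g$polylines[[as.character(e$id[k])]] <- NULL
    g$edges <- e[-k, , drop = FALSE]
    sel <- g$edges$from_type == "junction" & g$edges$from_id == id2
    g$edges$from_id[sel] <- id1
    sel <- g$edges$to_type == "junction" & g$edges$to_id == id2
    g$edges$to_id[sel] <- id1
  }
  g
}

# ---- pruning --------------------------------------------------------------

.junction_side <- function(edge, jid) {
  if (edge$from_type == "junction" && edge$from_id == jid) "from" else "to"
}

#' Iteratively prune small branches
#'
#' Branches strictly shorter than \code{prune_min_branch} are removed;
#' after each pass junction degrees are re-evaluated: a junction left with
#' degree 2 dissolves and its two incident edges concatenate into one
#' (re-classified by its new endpoints), a junction of degree 1 becomes an
#' extremity and a junction of degree 0 is dropped. Repeated to a fixed
#' point, so spurs revealed by a previous pass are pruned too. Anchorage
#' junctions are never dissolved.
#'
#' @param g an \code{"angio_graph"}.
#' @param p \code{\link{graph_params}}.
#' @return pruned graph.
#' @export
prune_small_branches <- function(g, p) {
  repeat {
    changed <- FALSE
    del <- which(g$edges$kind == "branch" & g$edges$length < p$prune_min_branch)
    if (length(del)) {
      for (k in del) g$polylines[[as.character(g$edges$id[k])]] <- NULL
      g$edges <- g$edges[-del, , drop = FALSE]
      g <- .drop_orphan_extremities(g)
      changed <- TRUE
    }
    deg <- graph_degrees(g)
    jchanged <- FALSE
    for (jc in names(deg)) {
      jid <- as.integer(jc)
      jrow <- which(g$junctions$id == jid)
      if (!length(jrow)) next
      d <- deg[[jc]]
      # an anchorage junction with no surviving edge carries no sprout and
      # is dropped; otherwise anchorage junctions are never dissolved
      if (g$junctions$is_anchorage[jrow] && d > 0L) next
      inc <- which((g$edges$from_type == "junction" & g$edges$from_id == jid) |
                     (g$edges$to_type == "junction" & g$edges$to_id == jid))
      if (d == 0L) {
        g$junctions <- g$junctions[-jrow, , drop = FALSE]
        g$junction_pixels[[jc]] <- NULL
        jchanged <- TRUE
      } else if (d == 1L) {
        nid <- if (nrow(g$extremities)) max(g$extremities$id) + 1L else 1L
        g$extremities <- rbind(g$extremities,
                               data.frame(id = nid,
                                          row = round(g$junctions$cy[jrow]),
                                          col = round(g$junctions$cx[jrow])))
        k <- inc[1]
        side <- .junction_side(g$edges[k, ], jid)
        g$edges[[paste0(side, "_type")]][k] <- "extremity"
        g$edges[[paste0(side, "_id")]][k] <- nid
        g$junctions <- g$junctions[-jrow, , drop = FALSE]
        g$junction_pixels[[jc]] <- NULL
        jchanged <- TRUE
      } else if (d == 2L && length(inc) == 2L) {
        e1 <- g$edges[inc[1], ]; e2 <- g$edges[inc[2], ]
        s1 <- .junction_side(e1, jid); s2 <- .junction_side(e2, jid)
        p1 <- g$polylines[[as.character(e1$id)]]
        p2 <- g$polylines[[as.character(e2$id)]]
        if (s1 == "from" && !is.null(p1)) p1 <- p1[rev(seq_len(nrow(p1))), , drop = FALSE]
        if (s2 == "to" && !is.null(p2)) p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
        gap <- if (!is.null(p1) && !is.null(p2) && nrow(p1) && nrow(p2))
          sqrt(sum((p1[nrow(p1), ] - p2[1, ])^2)) else 0
        new_from_type <- if (s1 == "from") e1$to_type else e1$from_type
        new_from_id <- if (s1 == "from") e1$to_id else e1$from_id
        new_to_type <- if (s2 == "to") e2$from_type else e2$to_type
        new_to_id <- if (s2 == "to") e2$from_id else e2$to_id
        new_id <- min(e1$id, e2$id)
        poly <- rbind(p1, p2)
        g$polylines[[as.character(e1$id)]] <- NULL
        g$polylines[[as.character(e2$id)]] <- NULL
        g$edges <- g$edges[-inc, , drop = FALSE]
        g$edges[nrow(g$edges) + 1L, ] <-
          list(new_id, .edge_kind(new_from_type, new_to_type),
               new_from_type, new_from_id, new_to_type, new_to_id,
               e1$length + e2$length + gap)
        g$polylines[[as.character(new_id)]] <- poly
        g$junctions <- g$junctions[-jrow, , drop = FALSE]
        g$junction_pixels[[jc]] <- NULL
        jchanged <- TRUE
      }
      if (jchanged) break  # degrees are stale; restart the scan
    }
    if (!changed && !jchanged) break
  }
  g$edges <- g$edges[order(g$edges$id), , drop = FALSE]
  .reclassify_edges(g)
}

# ---- anchorage ------------------------------------------------------------

.ring_dist_points <- function(rows, cols, circles) {
  d <- matrix(Inf, length(rows), max(nrow(circles), 1))
  for (i in seq_len(nrow(circles))) {
    ci <- circles[i, ]
    d[, i] <- abs(sqrt((rows - ci$cy)^2 + (cols - ci$cx)^2) - ci$radius)
  }
  d
}

#' Detect anchorage junctions and remove circle-piece edges
#'
#' Edges whose polylines run along a detected circle (at least 80 percent
#' of pixels within 2 px of a ring) are residual arcs of the bead envelope
#' and are deleted. Junctions whose blob reaches a ring are flagged as
#' anchorage junctions, and edge endpoints (extremities) lying on a ring
#' become new anchorage junctions: these mark where a sprout leaves the
#' bead and are counted separately from ordinary junctions.
#'
#' @param g an \code{"angio_graph"}.
#' @param circles data frame of circles; empty input returns \code{g}
#'   unchanged with a warning.
#' @param tol ring tolerance for circle-piece removal, pixels (default 5,
#'   covering the thin interior margin the clearing step retains).
#' @param anchor_tol ring tolerance for anchorage detection, pixels.
#'   Default 5: the interior clearing keeps a thin margin inside the
#'   envelope (see \code{\link{skeletonize_network}}), so a sprout's cut
#'   end can sit a few pixels inside the ring.
#' @return updated graph.
#' @export
classify_anchorage <- function(g, circles = g$circles, tol = 5,
                               anchor_tol = tol) {
  if (is.null(circles) || nrow(circles) == 0) {
    warning("classify_anchorage called without circles; returning unchanged")
    return(g)
  }
  # 1. delete circle-piece edges
  if (nrow(g$edges)) {
    on_ring <- vapply(seq_len(nrow(g$edges)), function(k) {
      poly <- g$polylines[[as.character(g$edges$id[k])]]
      if (is.null(poly) || nrow(poly) == 0) return(0)
      d <- .ring_dist_points(poly[, 1], poly[, 2], circles)
      mean(apply(d, 1, min) <= tol)
    }, numeric(1))
    del <- which(on_ring >= 0.8)
    if (length(del)) {
      for (k in del) g$polylines[[as.character(g$edges$id[k])]] <- NULL
      g$edges <- g$edges[-del, , drop = FALSE]
      g <- .drop_orphan_extremities(g)
    }
  }
  # 2. flag junctions intercepting a ring
  for (r in seq_len(nrow(g$junctions))) {
    px <- g$junction_pixels[[as.character(g$junctions$id[r])]]
    if (is.null(px) || !nrow(px)) px <- cbind(g$junctions$cy[r], g$junctions$cx[r])
    d <- .ring_dist_points(px[, 1], px[, 2], circles)
    mins <- apply(d, 2, min)
    if (min(mins) <= anchor_tol) {
      g$junctions$is_anchorage[r] <- TRUE
      g$junctions$circle_id[r] <- which.min(mins)
    }
  }
  # 3. extremities on a ring become anchorage junctions
  if (nrow(g$extremities)) {
    d <- .ring_dist_points(g$extremities$row, g$extremities$col, circles)
    hit <- which(apply(d, 1, min) <= anchor_tol)
    for (i in hit) {
      eid <- g$extremities$id[i]
      jid <- if (nrow(g$junctions)) max(g$junctions$id) + 1L else 1L
      g$junctions <- rbind(g$junctions,
                           data.frame(id = jid, cy = g$extremities$row[i],
                                      cx = g$extremities$col[i],
                                      is_anchorage = TRUE, n_nodes = 0L,
                                      circle_id = which.min(d[i, ])))
      g$junction_pixels[[as.character(jid)]] <-
        cbind(g$extremities$row[i], g$extremities$col[i])
      for (side in c("from", "to")) {
        sel <- g$edges[[paste0(side, "_type")]] == "extremity" &
          g$edges[[paste0(side, "_id")]] == eid
        g$edges[[paste0(side, "_type")]][sel] <- "junction"
        g$edges[[paste0(side, "_id")]][sel] <- jid
      }
    }
    if (length(hit))
      g$extremities <- g$extremities[-hit, , drop = FALSE]
  }
  .reclassify_edges(g)
}

#' Remove small isolated elements
#'
#' Isolated elements (edges bounded by two extremities) strictly shorter
#' than \code{min_object_size} pixels are removed: they are smaller than a
#' single cell and cannot be capillary fragments. Branches and segments
#' are untouched.
#'
#' @param g an \code{"angio_graph"}.
#' @param p \code{\link{graph_params}}.
#' @return updated graph.
#' @export
remove_small_isolated <- function(g, p) {
  del <- which(g$edges$kind == "isolated" & g$edges$length < p$min_object_size)
  if (length(del)) {
    for (k in del) g$polylines[[as.character(g$edges$id[k])]] <- NULL
    g$edges <- g$edges[-del, , drop = FALSE]
    g <- .drop_orphan_extremities(g)
  }
  g
}

#' Detect meshes (closed areas of the network)
#'
#' Meshes are the bounded faces of the planar skeleton: 4-connected
#' components of the skeleton complement that do not touch the image
#' border. Areas are measured on the complement of the 1-px skeleton, so
#' they do not depend on how much the segmentation mask was dilated. Each
#' mesh records the edges bordering it.
#'
#' @param g an \code{"angio_graph"}.
#' @param sk the skeleton the graph was built from (defaults to the one
#'   stored in \code{g}).
#' @return graph with \code{meshes} (id, area) and \code{mesh_edges}
#'   filled.
#' @export
detect_meshes <- function(g, sk = NULL) {
  m <- if (is.null(sk)) g$skeleton else .skeleton_pixels(sk)
  comp <- as_mask(m == 0)
  lab <- EBImage::bwlabel(comp)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  border <- unique(c(lab[1, ], lab[nrow(m), ], lab[, 1], lab[, ncol(m)]))
  ids <- setdiff(sort(unique(lab[lab > 0])), border)
  meshes <- data.frame(id = integer(0), area = numeric(0))
  mesh_edges <- list()
  if (length(ids)) {
    remap <- setNames(seq_along(ids), ids)
    areas <- tabulate(lab, nbins = max(lab))[ids]
    meshes <- data.frame(id = seq_along(ids), area = as.numeric(areas))
    # which meshes does each edge touch?
    for (k in seq_len(nrow(g$edges))) {
      poly <- g$polylines[[as.character(g$edges$id[k])]]
      if (is.null(poly) || !nrow(poly)) next
      touched <- integer(0)
      for (dd in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
        rr <- poly[, 1] + dd[1]; cc <- poly[, 2] + dd[2]
        ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
        touched <- c(touched, lab[cbind(rr[ok], cc[ok])])
      }
      touched <- unique(touched[touched %in% ids])
      for (t in touched) {
        mc <- as.character(remap[[as.character(t)]])
        mesh_edges[[mc]] <- c(mesh_edges[[mc]], g$edges$id[k])
      }
    }
  }
  g$meshes <- meshes
  g$mesh_edges <- mesh_edges
  g
}

#' Build the full vectorial model from a skeleton
#'
#' Orchestrates pixel classification, junction building, edge tracing,
#' junction fusion, iterative pruning, then (FBA) anchorage detection or
#' (ETFA) mesh detection, and finally removal of small isolated elements.
#'
#' @param sk an \code{"angio_skeleton"} (or 0/1 matrix, treated as ETFA).
#' @param p \code{\link{graph_params}}.
#' @param mode \code{"FBA"} or \code{"ETFA"}; defaults to the skeleton's.
#' @return an \code{"angio_graph"}.
#' @export
build_graph <- function(sk, p = graph_params(), mode = NULL) {
  if (is.null(mode))
    mode <- if (inherits(sk, "angio_skeleton")) sk$mode else "ETFA"
  mode <- match.arg(mode, c("FBA", "ETFA"))
  cls <- classify_pixels(sk)
  m <- .skeleton_pixels(sk)
  juncs <- build_junctions(cls$nodes, p, dim(m))
  g <- trace_edges(sk, juncs, cls$extremities)
  g$mode <- mode
  # pruning first removes the skeletonization spurs whose node dots chop
  # real tubes into short pieces; fusion then sees clean junctions. The
  # pair is iterated to a joint fixed point since each step can expose
  # work for the other.
  repeat {
    before <- list(nrow(g$edges), nrow(g$junctions))
    g <- prune_small_branches(g, p)
    g <- fuse_close_junctions(g, p)
    g <- prune_small_branches(g, p)
    if (identical(before, list(nrow(g$edges), nrow(g$junctions)))) break
  }
  if (mode == "FBA" && nrow(g$circles) > 0) {
    g <- classify_anchorage(g, g$circles)
    # an anchored branch shorter than the fusion scale is less than two
    # aligned cells long: a residue of the bead envelope, not a sprout
    anch_ids <- g$junctions$id[g$junctions$is_anchorage]
    stub <- g$edges$kind == "branch" &
      g$edges$length < p$junction_fusion_distance &
      ((g$edges$from_type == "junction" & g$edges$from_id %in% anch_ids) |
         (g$edges$to_type == "junction" & g$edges$to_id %in% anch_ids))
    if (any(stub)) {
      for (k in which(stub)) g$polylines[[as.character(g$edges$id[k])]] <- NULL
      g$edges <- g$edges[!stub, , drop = FALSE]
      g <- .drop_orphan_extremities(g)
    }
    # rim artifacts shorter than the pruning scale only become branches
    # once their ring endpoint is an anchorage junction; prune again
    g <- prune_small_branches(g, p)
  }
  g <- remove_small_isolated(g, p)
  if (mode == "ETFA")
    g <- detect_meshes(g)
  validate_graph(g)
  g
}
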