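# Morphometric measurements of the vectorial model: mesh areas, segment
# and total lengths and junction counts, reported per image for the tube
# formation assay (ETFA) and per bead for the fibrin bead assay (FBA).
# All lengths and areas are in pixels unless a calibration factor
# (pixels per micron) is applied at output time.

.sum_len <- function(g, kinds) {
  sum(g$edges$length[g$edges$kind %in% kinds])
}

#' Per-image measurements for the tube formation assay
#'
#' MMS: mean mesh size; TMA: total mesh area; TSL: total segment length;
#' JN: junction count (anchorage junctions excluded); TL: total length of
#' branches plus segments. Isolated elements do not contribute to TL. When
#' the graph has no mesh, MMS and TMA are 0 and \code{no_mesh} is set.
#'
#' @param g an \code{"angio_graph"}.
#' @param image_id optional label.
#' @return one-row data frame (MMS, TMA, TSL, JN, TL, no_mesh).
#' @export
measure_etfa <- function(g, image_id = NA_character_) {
  nm <- nrow(g$meshes)
  data.frame(image_id = image_id,
             MMS = if (nm) mean(g$meshes$area) else 0,
             TMA = if (nm) sum(g$meshes$area) else 0,
             TSL = .sum_len(g, "segment"),
             JN = sum(!g$junctions$is_anchorage),
             TL = .sum_len(g, c("branch", "segment")),
             no_mesh = nm == 0)
}

# Map every vertex component of the graph to a circle: components holding
# an anchorage junction inherit its circle; others go to the circle whose
# centre is nearest to the component centroid (flagged).
.component_circles <- function(g) {
  comp <- graph_components(g)
  jkey <- paste0("j", g$junctions$id)
  circ_of_comp <- rep(NA_integer_, length(unique(comp)))
  flagged <- logical(length(circ_of_comp))
  anch <- which(g$junctions$is_anchorage & !is.na(g$junctions$circle_id))
  for (r in anch) {
    cc <- comp[[jkey[r]]]
    if (is.na(circ_of_comp[cc])) {
      circ_of_comp[cc] <- g$junctions$circle_id[r]
    } else if (circ_of_comp[cc] != g$junctions$circle_id[r]) {
      flagged[cc] <- TRUE  # tree touching two beads: keep first (nearest rim)
    }
  }
  # components without anchorage: nearest circle centre from any vertex
  for (cc in which(is.na(circ_of_comp))) {
    keys <- names(comp)[comp == cc]
    pos <- t(vapply(keys, function(k) {
      if (startsWith(k, "j")) {
        r <- which(g$junctions$id == as.integer(substring(k, 2)))
        c(g$junctions$cy[r], g$junctions$cx[r])
      } else {
        r <- which(g$extremities$id == as.integer(substring(k, 2)))
        c(g$extremities$row[r], g$extremities$col[r])
      }
    }, numeric(2)))
    ctr <- colMeans(pos)
    d <- sqrt((g$circles$cy - ctr[1])^2 + (g$circles$cx - ctr[2])^2)
    circ_of_comp[cc] <- which.min(d)
    flagged[cc] <- TRUE
  }
  list(comp = comp, circle = circ_of_comp, flagged = flagged)
}

#' Per-bead measurements for the fibrin bead assay
#'
#' Every tree component is assigned to its bead (via its anchorage
#' junctions; components touching no ring go to the nearest bead centre
#' and are flagged). One record is returned per detected bead, including
#' beads with no sprouts (each bead is an independent replicate): JN/S,
#' TSL/S, TL/S, AJN/S and the combined AJN/S + JN/S.
#'
#' @param g an \code{"angio_graph"} with at least one circle.
#' @param image_id optional label.
#' @return data frame, one row per bead.
#' @export
measure_fba <- function(g, image_id = NA_character_) {
  if (is.null(g$circles) || nrow(g$circles) == 0)
    stop("measure_fba needs a graph with detected circles")
  asg <- .component_circles(g)
  comp <- asg$comp
  ekey_comp <- function(k) comp[[paste0(substr(g$edges$from_type[k], 1, 1),
                                        g$edges$from_id[k])]]
  edge_circle <- if (nrow(g$edges))
    vapply(seq_len(nrow(g$edges)), function(k) asg$circle[ekey_comp(k)],
           integer(1)) else integer(0)
  j_circle <- if (nrow(g$junctions))
    asg$circle[comp[paste0("j", g$junctions$id)]] else integer(0)
  out <- do.call(rbind, lapply(seq_len(nrow(g$circles)), function(ci) {
    esel <- g$edges[which(edge_circle == ci), , drop = FALSE]
    jsel <- g$junctions[which(j_circle == ci), , drop = FALSE]
    data.frame(image_id = image_id, sphere_id = ci,
               cx = g$circles$cx[ci], cy = g$circles$cy[ci],
               radius = g$circles$radius[ci],
               JN_S = sum(!jsel$is_anchorage),
               AJN_S = sum(jsel$is_anchorage),
               TSL_S = sum(esel$length[esel$kind == "segment"]),
               TL_S = sum(esel$length[esel$kind %in% c("branch", "segment")]),
               flagged = any(asg$flagged[which(asg$circle == ci)]))
  }))
  out$AJN_JN_S <- out$AJN_S + out$JN_S
  out
}

#' Mean, SEM and n per group
#'
#' Aggregates measurement records (one row per image or bead) into group
#' means with standard errors, the form in which assay responses are
#' reported. SEM = sd / sqrt(n); a single record yields SEM 0 with
#' \code{n = 1}.
#'
#' @param records data frame of measurements.
#' @param grouping vector of group labels (recycled against rows), or the
#'   name of a column of \code{records}.
#' @param columns measurement columns to aggregate; defaults to all
#'   numeric columns except identifiers.
#' @return data frame with group, variable, mean, sem, n.
#' @export
summarize_batch <- function(records, grouping = rep("all", nrow(records)),
                            columns = NULL) {
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% names(records))
    grouping <- records[[grouping]]
  stopifnot(length(grouping) == nrow(records), nrow(records) > 0)
  if (is.null(columns)) {
    num <- vapply(records, is.numeric, logical(1))
    columns <- setdiff(names(records)[num],
                       c("sphere_id", "cx", "cy", "radius"))
  }
  out <- do.call(rbind, lapply(unique(grouping), function(gr) {
    sel <- records[grouping == gr, columns, drop = FALSE]
    do.call(rbind, lapply(columns, function(cn) {
      x <- sel[[cn]]
      n <- length(x)
      data.frame(group = gr, variable = cn, mean = mean(x),
                 sem = if (n > 1) sd(x) / sqrt(n) else 0, n = n)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Apply a spatial calibration to measurement records
#'
#' Converts pixel lengths to microns and pixel areas to square microns
#' with a pixels-per-micron factor. Counts are unchanged.
#'
#' @param records data frame from \code{\link{measure_etfa}} or
#'   \code{\link{measure_fba}}.
#' @param pixels_per_micron calibration factor (> 0).
#' @return calibrated copy of \code{records}.
#' @export
calibrate_records <- function(records, pixels_per_micron) {
  stopifnot(pixels_per_micron > 0)
  len_cols <- intersect(c("TSL", "TL", "TSL_S", "TL_S", "radius"),
                        names(records))
  area_cols <- intersect(c("MMS", "TMA"), names(records))
  for (cn in len_cols) records[[cn]] <- records[[cn]] / pixels_per_micron
  for (cn in area_cols) records[[cn]] <- records[[cn]] / pixels_per_micron^2
  records
}
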