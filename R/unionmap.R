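## Union maps and the bipartite conflict graph — the spatial anchors that
## link per-frame instance labels across time.

ikey <- function(t, k) sprintf("i%d.%d", t, k)
ukey <- function(pair, m) sprintf("u%d.%d", pair, m)

#' Build union maps from a registered series
#'
#' The union map is the voxelwise logical OR of registered instance masks,
#' relabeled by a second connected-component pass: objects from different
#' timepoints that overlap in the aligned space fall into the same union
#' component and are thereby candidates for being the same physical object.
#' Scenario S1 produces a single union map over the whole series (which is
#' what gives S1 its gap-closing ability); scenario S2 produces one union
#' map per consecutive frame pair `(t, t+1)`, each in the space of frame
#' `t` — frame `t` contributes its native labels and frame `t+1` its
#' registered labels.
#'
#' @param registered A [register_series()] result.
#' @param connectivity 8 (2D) or 26 (3D); defaults to match dimensionality.
#' @return A list of `union_map` objects, each with elements `binary`
#'   (logical array), `cc` (integer component map), `n_components`,
#'   `frame_span` and `pair` (pair index; 1 for the single S1 map).
#' @export
build_union_map <- function(registered, connectivity = NULL) {
  stopifnot(inherits(registered, "registered_series"))
  frames <- registered$registered
  d <- frames[[1L]]$dimensionality
  if (is.null(connectivity)) connectivity <- default_connectivity(d)
  check_connectivity(connectivity, d)
  dm <- dim(frames[[1L]]$labels)
  one_map <- function(arrs, span, pair) {
    u <- array(FALSE, dm)
    for (a in arrs) u <- u | (a > 0L)
    cc <- label_components(u, connectivity)
    structure(list(binary = u, cc = cc, n_components = max(cc, 0L),
                   frame_span = span, pair = pair),
              class = "union_map")
  }
  if (registered$scenario == "S1" || length(frames) == 1L) {
    ## a single-frame S2 series degenerates to one self-spanning map
    list(one_map(lapply(frames, `[[`, "labels"), seq_along(frames), 1L))
  } else {
    T_ <- length(frames)
    lapply(seq_len(max(T_ - 1L, 0L)), function(p) {
      one_map(list(registered$original[[p]]$labels, frames[[p + 1L]]$labels),
              c(p, p + 1L), p)
    })
  }
}

#' @export
print.union_map <- function(x, ...) {
  cat(sprintf("<union_map> pair %d, frames %s, %d component(s)\n",
              x$pair, paste(range(x$frame_span), collapse = "-"),
              x$n_components))
  invisible(x)
}

## overlap counts between the positive labels of 'labels_arr' and the
## positive components of 'cc' -> data.frame(k, m, overlap)
overlap_table <- function(labels_arr, cc) {
  idx <- which(labels_arr > 0L & cc > 0L)
  if (!length(idx)) {
    return(data.frame(k = integer(0), m = integer(0), overlap = integer(0)))
  }
  k <- labels_arr[idx]
  m <- cc[idx]
  agg <- rowsum(rep(1L, length(idx)), group = paste(k, m, sep = ":"))
  parts <- do.call(rbind, strsplit(rownames(agg), ":", fixed = TRUE))
  data.frame(k = as.integer(parts[, 1L]), m = as.integer(parts[, 2L]),
             overlap = as.integer(agg[, 1L]))
}

#' Build the conflict graph between initial IDs and union IDs
#'
#' The conflict graph is bipartite: one node per initial (per-frame)
#' instance ID and one per union component, with an edge wherever an
#' instance's aligned mask overlaps a union component by at least
#' `min_overlap` voxels. An instance connected to several union components
#' is a *conflict* — typically a thin structure fragmented by
#' nearest-neighbor resampling — and is repaired downstream by
#' [resolve_conflicts()]. Union IDs from distinct pairwise (S2) maps are
#' distinct nodes, so S2 chains frame-to-frame associations through shared
#' instances. Instances whose registered mask is empty (e.g. pushed fully
#' out of the field of view) are recorded as orphans, not as graph nodes.
#'
#' @param registered A [register_series()] result.
#' @param unions Result of [build_union_map()] on the same series.
#' @param min_overlap Minimum overlap in voxels for an edge (default 1: any
#'   intersection counts).
#' @return An object of class `conflict_graph` with `edges`
#'   (`timepoint`, `label`, `pair`, `component`, `overlap`), `instances`
#'   and `orphans` data frames.
#' @export
build_conflict_graph <- function(registered, unions, min_overlap = 1L) {
  stopifnot(inherits(registered, "registered_series"))
  T_ <- length(registered$original)
  s2 <- registered$scenario == "S2" && T_ > 1L
  rows <- list()
  for (t in seq_len(T_)) {
    if (s2) {
      ## fixed side of pair t, native labels
      if (t <= T_ - 1L) {
        ov <- overlap_table(registered$original[[t]]$labels, unions[[t]]$cc)
        if (nrow(ov)) {
          rows[[length(rows) + 1L]] <-
            data.frame(timepoint = t, label = ov$k, pair = t,
                       component = ov$m, overlap = ov$overlap)
        }
      }
      ## moving side of pair t-1, registered labels
      if (t >= 2L) {
        ov <- overlap_table(registered$registered[[t]]$labels,
                            unions[[t - 1L]]$cc)
        if (nrow(ov)) {
          rows[[length(rows) + 1L]] <-
            data.frame(timepoint = t, label = ov$k, pair = t - 1L,
                       component = ov$m, overlap = ov$overlap)
        }
      }
    } else {
      ov <- overlap_table(registered$registered[[t]]$labels, unions[[1L]]$cc)
      if (nrow(ov)) {
        rows[[length(rows) + 1L]] <-
          data.frame(timepoint = t, label = ov$k, pair = 1L,
                     component = ov$m, overlap = ov$overlap)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(timepoint = integer(0), label = integer(0), pair = integer(0),
               component = integer(0), overlap = integer(0))
  edges <- edges[edges$overlap >= min_overlap, , drop = FALSE]
  rownames(edges) <- NULL
  inst <- do.call(rbind, lapply(seq_len(T_), function(t) {
    ks <- frame_labels(registered$original[[t]])
    if (length(ks)) data.frame(timepoint = t, label = ks) else NULL
  }))
  if (is.null(inst)) inst <- data.frame(timepoint = integer(0),
                                        label = integer(0))
  has_edge <- paste(inst$timepoint, inst$label) %in%
    paste(edges$timepoint, edges$label)
  orphans <- inst[!has_edge, , drop = FALSE]
  rownames(orphans) <- NULL
  structure(list(edges = edges, instances = inst, orphans = orphans),
            class = "conflict_graph")
}

#' @export
print.conflict_graph <- function(x, ...) {
  n_conf <- sum(tapply(x$edges$component, paste(x$edges$timepoint,
                                                x$edges$label),
                       function(z) length(unique(z)) > 1L))
  cat(sprintf(
    "<conflict_graph> %d instance(s), %d edge(s), %d conflicted, %d orphan(s)\n",
    nrow(x$instances), nrow(x$edges), if (nrow(x$edges)) n_conf else 0L,
    nrow(x$orphans)))
  invisible(x)
}

#' Resolve conflicts into lineage identifiers
#'
#' Every connected group of the bipartite conflict graph — initial IDs plus
#' the union IDs they touch — is mapped to one lineage identifier. This
#' single operation both repairs resampling fragmentation (an instance
#' touching two union components pulls them into one group) and, in S2,
#' collapses the frame-to-frame chains of initial and union IDs into one
#' identifier per physical history. Lineages are numbered 1..Q in ascending
#' order of the earliest `(timepoint, label)` among their member instances,
#' so the numbering is deterministic.
#'
#' @param graph A [build_conflict_graph()] result.
#' @return An object of class `lineage_assignment` with `mapping`
#'   (`timepoint`, `label`, `lineage`), `n_lineages` and the pass-through
#'   `orphans` data frame.
#' @export
resolve_conflicts <- function(graph) {
  stopifnot(inherits(graph, "conflict_graph"))
  e <- graph$edges
  empty <- data.frame(timepoint = integer(0), label = integer(0),
                      lineage = integer(0))
  if (!nrow(e)) {
    return(structure(list(mapping = empty, n_lineages = 0L,
                          orphans = graph$orphans),
                     class = "lineage_assignment"))
  }
  iv <- ikey(e$timepoint, e$label)
  uv <- ukey(e$pair, e$component)
  verts <- unique(c(iv, uv))
  g <- igraph::make_undirected_graph(
    t(cbind(match(iv, verts), match(uv, verts))), n = length(verts))
  memb <- igraph::components(g)$membership
  inst_idx <- !duplicated(iv)
  inst <- data.frame(timepoint = e$timepoint[inst_idx],
                     label = e$label[inst_idx],
                     group = memb[match(iv[inst_idx], verts)])
  ## deterministic numbering: ascending by earliest (t, label) in the group
  ord <- order(inst$timepoint, inst$label)
  inst$lineage <- match(inst$group, unique(inst$group[ord]))
  mapping <- inst[order(inst$timepoint, inst$label),
                  c("timepoint", "label", "lineage")]
  rownames(mapping) <- NULL
  structure(list(mapping = mapping, n_lineages = max(mapping$lineage),
                 orphans = graph$orphans),
            class = "lineage_assignment")
}

#' @export
print.lineage_assignment <- function(x, ...) {
  cat(sprintf("<lineage_assignment> %d instance(s) in %d lineage(s), %d orphan(s)\n",
              nrow(x$mapping), x$n_lineages, nrow(x$orphans)))
  invisible(x)
}
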