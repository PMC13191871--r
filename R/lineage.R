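## Per-lineage morphogenetic graphs: initial IDs layered by timepoint,
## IoU-weighted forward edges, split/merge/appear/vanish event tags.

mask_iou <- function(a, b) {
  if (!length(a) || !length(b)) return(c(iou = 0, inter = 0))
  inter <- length(intersect(a, b))
  c(iou = inter / (length(a) + length(b) - inter), inter = inter)
}

## Per-frame masks used for IoU weighting, in the space of the relevant
## union map: S1 compares registered masks in the common reference space;
## S2 compares the parent's native mask with the child's mask registered
## into the parent's frame.
iou_masks <- function(registered) {
  s2 <- registered$scenario == "S2"
  list(
    parent = lapply(if (s2) registered$original else registered$registered,
                    instance_masks),
    child = lapply(registered$registered, instance_masks)
  )
}

## deterministic argmax over candidate edge rows: highest IoU, then largest
## intersection, then smallest (t,k) on the varying side
pick_best <- function(df, side) {
  o <- order(-df$iou, -df$inter, df[[paste0(side, "_k")]])
  df[o[1L], , drop = FALSE]
}

#' Build a lineage's morphogenetic graph
#'
#' Orders the lineage's member instances by timepoint and connects members
#' at each timepoint to members at the lineage's next occupied timepoint
#' with IoU-weighted directed edges. In S1 "next occupied" may skip frames
#' in which the lineage was not detected — the graph edge then bridges the
#' gap (disappearance/reappearance); in S2 edges only connect consecutive
#' frames, matching the pairwise union maps. Ambiguous many-to-many
#' connections are reduced: every child keeps its maximal-IoU incoming edge
#' and every parent left unmatched keeps its maximal-IoU outgoing edge, so
#' no node is stranded and a split/merge keeps all of its participating
#' edges. IoU ties break toward the larger intersection, then the smaller
#' instance label — deterministic.
#'
#' @param lineage Lineage identifier (from [resolve_conflicts()]).
#' @param assignment A `lineage_assignment`.
#' @param registered The [register_series()] result the assignment came from.
#' @param masks Internal precomputed mask cache; computed when `NULL`.
#' @return An object of class `lineage_graph` with `lineage`, `nodes`
#'   (`timepoint`, `label`) and `edges` (`from_t`, `from_k`, `to_t`, `to_k`,
#'   `iou`, `inter`) data frames.
#' @export
build_lineage_graph <- function(lineage, assignment, registered,
                                masks = NULL) {
  stopifnot(inherits(assignment, "lineage_assignment"))
  members <- assignment$mapping[assignment$mapping$lineage == lineage, ,
                                drop = FALSE]
  if (!nrow(members)) {
    stop(sprintf("lineage %s has no members: assignment invariant violated",
                 lineage), call. = FALSE)
  }
  if (is.null(masks)) masks <- iou_masks(registered)
  s2 <- registered$scenario == "S2"
  nodes <- members[order(members$timepoint, members$label),
                   c("timepoint", "label")]
  rownames(nodes) <- NULL
  ts <- sort(unique(nodes$timepoint))
  edge_rows <- list()
  for (j in seq_len(length(ts) - 1L)) {
    ta <- ts[j]; tb <- ts[j + 1L]
    if (s2 && tb != ta + 1L) next  # pairwise maps cannot bridge a gap
    parents <- nodes$label[nodes$timepoint == ta]
    children <- nodes$label[nodes$timepoint == tb]
    cand <- expand.grid(from_k = parents, to_k = children,
                        KEEP.OUT.ATTRS = FALSE)
    stats <- t(vapply(seq_len(nrow(cand)), function(i) {
      pm <- masks$parent[[ta]][[as.character(cand$from_k[i])]]
      cm <- masks$child[[tb]][[as.character(cand$to_k[i])]]
      mask_iou(pm, cm)
    }, c(iou = 0, inter = 0)))
    cand$iou <- stats[, "iou"]
    cand$inter <- stats[, "inter"]
    kept <- do.call(rbind, lapply(children, function(ck) {
      pick_best(cand[cand$to_k == ck, , drop = FALSE], "from")
    }))
    unmatched <- setdiff(parents, kept$from_k)
    if (length(unmatched)) {
      kept <- rbind(kept, do.call(rbind, lapply(unmatched, function(pk) {
        pick_best(cand[cand$from_k == pk, , drop = FALSE], "to")
      })))
    }
    kept <- unique(kept)
    edge_rows[[j]] <- data.frame(from_t = ta, from_k = kept$from_k,
                                 to_t = tb, to_k = kept$to_k,
                                 iou = kept$iou, inter = kept$inter)
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(from_t = integer(0), from_k = integer(0), to_t = integer(0),
               to_k = integer(0), iou = numeric(0), inter = numeric(0))
  edges <- edges[order(edges$from_t, edges$from_k, edges$to_k), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(lineage = lineage, nodes = nodes, edges = edges,
                 severed_children = NULL),
            class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat(sprintf("<lineage_graph> L%d: %d node(s) over t %s, %d edge(s)\n",
              x$lineage, nrow(x$nodes),
              paste(range(x$nodes$timepoint), collapse = "-"), nrow(x$edges)))
  invisible(x)
}

node_degrees <- function(graph) {
  key <- paste(graph$nodes$timepoint, graph$nodes$label)
  data.frame(
    timepoint = graph$nodes$timepoint, label = graph$nodes$label,
    indeg = as.integer(table(factor(paste(graph$edges$to_t, graph$edges$to_k),
                                    levels = key))),
    outdeg = as.integer(table(factor(paste(graph$edges$from_t,
                                           graph$edges$from_k),
                                     levels = key)))
  )
}

#' Sever disallowed merge events from a lineage graph
#'
#' When the tracked system cannot merge (e.g. cells), each node with several
#' incoming edges keeps only the incoming edge of maximal IoU — that parent
#' remains the sole parent — while the other incoming edges are removed, so
#' their parents' branches terminate. The affected children are recorded in
#' `severed_children`; they still begin fresh tracks in
#' [assign_tracked_ids()] because the (disallowed) interaction happened in
#' the data even though it is not represented as a merge.
#'
#' @param graph A [build_lineage_graph()] result.
#' @return The graph with merge edges severed.
#' @export
resolve_merges <- function(graph) {
  e <- graph$edges
  key_to <- paste(e$to_t, e$to_k)
  severed <- list()
  keep <- rep(TRUE, nrow(e))
  for (kk in unique(key_to[duplicated(key_to)])) {
    rows <- which(key_to == kk)
    sub <- e[rows, , drop = FALSE]
    o <- order(-sub$iou, -sub$inter, sub$from_k)
    keep[rows[o[-1L]]] <- FALSE
    severed[[length(severed) + 1L]] <-
      data.frame(timepoint = sub$to_t[1L], label = sub$to_k[1L])
  }
  graph$edges <- e[keep, , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph$severed_children <- if (length(severed)) do.call(rbind, severed) else
    data.frame(timepoint = integer(0), label = integer(0))
  graph
}

#' Classify morphogenetic events on a lineage graph
#'
#' Tags every node of the graph:
#' * `split_parent` — out-degree >= 2; its successors are `split_child`.
#' * `merge_child` — in-degree >= 2; its predecessors are `merge_parent`.
#' * `emerge` — node at the lineage's first occupied timepoint, unless that
#'   is the first frame of the series (`present_at_start`).
#' * `vanish` — node at the lineage's last occupied timepoint when that is
#'   before the series' final frame.
#' * `reappear` — node immediately after a gap in the lineage's occupied
#'   timepoints (S1 gap closing; cannot occur in S2).
#' * `continue` — none of the above.
#'
#' @param graph A [build_lineage_graph()] result.
#' @param total_timepoints Number of frames T in the series.
#' @return The graph with an `events` data frame (one row per node, logical
#'   tag columns) attached.
#' @export
classify_events <- function(graph, total_timepoints) {
  ev <- node_degrees(graph)
  ts <- sort(unique(ev$timepoint))
  first_t <- ts[1L]
  last_t <- ts[length(ts)]
  reappear_ts <- ts[which(diff(ts) > 1L) + 1L]  # occupied t right after a gap
  ev$split_parent <- ev$outdeg >= 2L
  ev$merge_child <- ev$indeg >= 2L
  sp_key <- paste(ev$timepoint, ev$label)[ev$split_parent]
  mc_key <- paste(ev$timepoint, ev$label)[ev$merge_child]
  e_from <- paste(graph$edges$from_t, graph$edges$from_k)
  e_to <- paste(graph$edges$to_t, graph$edges$to_k)
  ev$split_child <- paste(ev$timepoint, ev$label) %in% e_to[e_from %in% sp_key]
  ev$merge_parent <- paste(ev$timepoint, ev$label) %in% e_from[e_to %in% mc_key]
  ev$present_at_start <- ev$timepoint == first_t & first_t == 1L
  ev$emerge <- ev$timepoint == first_t & first_t > 1L
  ev$vanish <- ev$timepoint == last_t & last_t < total_timepoints
  ev$reappear <- ev$timepoint %in% reappear_ts
  tagcols <- c("split_parent", "split_child", "merge_child", "merge_parent",
               "emerge", "present_at_start", "vanish", "reappear")
  ev$continue <- !Reduce(`|`, ev[c("split_parent", "split_child",
                                   "merge_child", "merge_parent", "emerge",
                                   "vanish", "reappear")])
  graph$events <- ev[c("timepoint", "label", "indeg", "outdeg", tagcols,
                       "continue")]
  graph
}
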