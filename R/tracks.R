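## Tracked identifiers: one ID per maximal event-free segment of a
## morphogenetic graph, with parent links across split/merge events.

#' Assign temporally consistent tracked IDs
#'
#' Traverses every lineage graph from its roots, generating a fresh tracked
#' ID for each first-measured object and propagating it forward until a
#' split or merge occurs; the objects resulting from the event receive new
#' tracked IDs with parent links to the segment(s) ending at the event. With
#' `allow_merges = FALSE` (strict cell-style lineage) merge events are first
#' severed by IoU (see [resolve_merges()]): the max-IoU parent becomes the
#' sole parent, other incoming branches terminate, and the child still
#' starts a fresh track carrying that parent link — so parent links always
#' form a forest.
#'
#' @param graphs List of [build_lineage_graph()] results (ordered by
#'   lineage ID for deterministic numbering).
#' @param allow_merges Logical; `FALSE` enforces strict lineage (no fusion).
#' @return An object of class `track_table` with `table` (`track`, `start`,
#'   `end`, `parent`, `lineage`; `parent` 0 means none) and `mapping`
#'   (`timepoint`, `label`, `lineage`, `track`) data frames. For merge
#'   children the single `parent` is the max-IoU parent; all incoming
#'   parents are kept in `merge_parents`.
#' @export
assign_tracked_ids <- function(graphs, allow_merges = TRUE) {
  track_rows <- list()
  map_rows <- list()
  merge_parent_rows <- list()
  counter <- 0L
  for (graph in graphs) {
    if (!allow_merges && is.null(graph$severed_children)) {
      graph <- resolve_merges(graph)
    }
    nodes <- graph$nodes[order(graph$nodes$timepoint, graph$nodes$label), ,
                         drop = FALSE]
    e <- graph$edges
    deg <- node_degrees(graph)
    outdeg <- stats::setNames(deg$outdeg, paste(deg$timepoint, deg$label))
    severed <- if (is.null(graph$severed_children)) character(0) else
      paste(graph$severed_children$timepoint, graph$severed_children$label)
    node_track <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(nodes))) {
      t <- nodes$timepoint[i]; k <- nodes$label[i]
      key <- paste(t, k)
      inc <- e[e$to_t == t & e$to_k == k, , drop = FALSE]
      if (nrow(inc) == 0L) {
        counter <- counter + 1L
        tid <- counter; parent <- 0L
      } else if (nrow(inc) == 1L) {
        pkey <- paste(inc$from_t, inc$from_k)
        ptid <- get(pkey, node_track)
        if (outdeg[[pkey]] >= 2L || key %in% severed) {
          counter <- counter + 1L
          tid <- counter; parent <- ptid
        } else {
          tid <- ptid; parent <- NA_integer_  # continuation
        }
      } else {
        ## merge: fresh track; primary parent is the max-IoU incoming edge
        o <- order(-inc$iou, -inc$inter, inc$from_k)
        pkeys <- paste(inc$from_t, inc$from_k)[o]
        ptids <- vapply(pkeys, function(pk) get(pk, node_track), integer(1))
        counter <- counter + 1L
        tid <- counter; parent <- ptids[1L]
        merge_parent_rows[[length(merge_parent_rows) + 1L]] <-
          data.frame(track = tid, parent = ptids,
                     iou = inc$iou[o], row.names = NULL)
      }
      assign(key, tid, node_track)
      if (!is.na(parent)) {
        track_rows[[length(track_rows) + 1L]] <-
          data.frame(track = tid, start = t, end = t, parent = parent,
                     lineage = graph$lineage)
      }
      map_rows[[length(map_rows) + 1L]] <-
        data.frame(timepoint = t, label = k, lineage = graph$lineage,
                   track = tid)
    }
  }
  mapping <- if (length(map_rows)) do.call(rbind, map_rows) else
    data.frame(timepoint = integer(0), label = integer(0),
               lineage = integer(0), track = integer(0))
  tab <- if (length(track_rows)) do.call(rbind, track_rows) else
    data.frame(track = integer(0), start = integer(0), end = integer(0),
               parent = integer(0), lineage = integer(0))
  if (nrow(tab)) {
    ## extend each track's span over all its nodes
    for (i in seq_len(nrow(tab))) {
      ts <- mapping$timepoint[mapping$track == tab$track[i]]
      tab$start[i] <- min(ts); tab$end[i] <- max(ts)
    }
    tab <- tab[order(tab$track), , drop = FALSE]
    rownames(tab) <- NULL
  }
  mapping <- mapping[order(mapping$timepoint, mapping$label), , drop = FALSE]
  rownames(mapping) <- NULL
  structure(list(
    table = tab, mapping = mapping,
    merge_parents = if (length(merge_parent_rows))
      do.call(rbind, merge_parent_rows) else
      data.frame(track = integer(0), parent = integer(0), iou = numeric(0))
  ), class = "track_table")
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("<track_table> %d track(s) over %d instance(s)\n",
              nrow(x$table), nrow(x$mapping)))
  if (nrow(x$table)) print(utils::head(x$table, 10L))
  invisible(x)
}

#' Project lineage and tracked IDs back into native image space
#'
#' Relabels the original, unregistered frames: each voxel's value becomes
#' the lineage (respectively tracked) ID of the instance it belonged to, so
#' tracking results live in the native image geometry. Foreground support is
#' conserved exactly. Orphan instances — instances whose registered mask was
#' empty, e.g. objects pushed fully out of the field — receive fresh
#' singleton lineage and track IDs, with a warning.
#'
#' @param original List of the pre-registration [labeled_frame()]s.
#' @param assignment A [resolve_conflicts()] result.
#' @param tracks An [assign_tracked_ids()] result.
#' @return A list with `lineage_frames`, `track_frames` (lists of
#'   `labeled_frame`), and the completed `lineage_map` / `track_map` data
#'   frames (including orphan rows, flagged by the `orphan` column).
#' @export
project_back <- function(original, assignment, tracks) {
  stopifnot(inherits(assignment, "lineage_assignment"),
            inherits(tracks, "track_table"))
  original <- check_series(original)
  lmap <- assignment$mapping
  tmap <- tracks$mapping
  lmap$orphan <- logical(nrow(lmap))
  tmap$orphan <- logical(nrow(tmap))
  orph <- assignment$orphans
  if (nrow(orph)) {
    warning(sprintf(
      "%d orphan instance(s) (empty registered mask) assigned singleton IDs",
      nrow(orph)), call. = FALSE)
    next_l <- max(c(0L, lmap$lineage)) + seq_len(nrow(orph))
    next_t <- max(c(0L, tmap$track)) + seq_len(nrow(orph))
    lmap <- rbind(lmap, data.frame(timepoint = orph$timepoint,
                                   label = orph$label, lineage = next_l,
                                   orphan = TRUE))
    tmap <- rbind(tmap, data.frame(timepoint = orph$timepoint,
                                   label = orph$label,
                                   lineage = next_l, track = next_t,
                                   orphan = TRUE))
  }
  relabel <- function(frame, map, col) {
    sub <- map[map$timepoint == frame$timepoint, , drop = FALSE]
    ks <- frame_labels(frame)
    missing <- setdiff(ks, sub$label)
    if (length(missing)) {
      stop(sprintf(
        "frame t=%d: instance label(s) %s absent from assignment and orphans",
        frame$timepoint, paste(missing, collapse = ", ")), call. = FALSE)
    }
    lut <- integer(max(c(0L, ks)) + 1L)            # index = label + 1
    lut[sub$label + 1L] <- sub[[col]]
    labeled_frame(array(lut[frame$labels + 1L], dim(frame$labels)),
                  frame$timepoint)
  }
  list(
    lineage_frames = lapply(original, relabel, map = lmap, col = "lineage"),
    track_frames = lapply(original, relabel, map = tmap, col = "track"),
    lineage_map = lmap,
    track_map = tmap
  )
}
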