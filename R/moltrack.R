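#' Multi-object and lineage tracking of a segmented time series
#'
#' Runs the full training-free tracking pipeline on a time-ordered series of
#' instance- (or binary-) segmentation label images:
#'
#' 1. per-frame instance identification (connected components; skipped for
#'    instance input),
#' 2. affine registration — every frame to the reference frame under
#'    scenario `"S1"` (objects static relative to each other, global
#'    misalignment), or each frame to its predecessor under `"S2"`
#'    (independently moving objects, densely sampled),
#' 3. union-map construction and a second connected-component pass,
#' 4. graph-based conflict resolution mapping every initial ID to a lineage
#'    ID (this also repairs fragmentation artifacts of nearest-neighbor
#'    resampling),
#' 5. per-lineage morphogenetic graphs with IoU-resolved branching and
#'    split/merge/emerge/vanish/reappear event classification,
#' 6. tracked-ID assignment (new ID at every split or merge), and
#' 7. projection of lineage and tracked IDs back onto the original,
#'    unregistered frames.
#'
#' @param x List of label arrays or [labeled_frame()]s, one per timepoint.
#' @param scenario `"S1"` or `"S2"`.
#' @param raw Optional list of raw intensity arrays for registration.
#' @param registration A backend from [registration_backends], or one of
#'   the shorthand strings `"translation"`, `"identity"`.
#' @param reference Reference timepoint for S1 (default 1).
#' @param allow_merges `FALSE` enforces strict cell-style lineage: merge
#'   events are resolved by IoU and never appear in the output.
#' @param min_overlap Minimum voxel overlap for a conflict-graph edge.
#' @param connectivity 8 (2D) or 26 (3D); default matches dimensionality.
#' @return An object of class `moltrack`; see [summary.moltrack()],
#'   [track_table()], [lineage_table()], [event_counts()].
#' @examples
#' fr <- lapply(1:3, function(t) {
#'   m <- matrix(0L, 16, 16); m[4:6, 4:6] <- 1L; m[10:12, 10:12] <- 1L
#'   m
#' })
#' fit <- moltrack(fr, scenario = "S1", registration = "identity")
#' summary(fit)
#' @export
moltrack <- function(x, scenario = c("S1", "S2"), raw = NULL,
                     registration = reg_translation(), reference = 1L,
                     allow_merges = TRUE, min_overlap = 1L,
                     connectivity = NULL) {
  scenario <- match.arg(scenario)
  cl <- match.call()
  frames <- check_series(x)
  d <- frames[[1L]]$dimensionality
  if (is.null(connectivity)) connectivity <- default_connectivity(d)
  check_connectivity(connectivity, d)
  frames <- lapply(frames, identify_instances, connectivity = connectivity)
  reg <- register_series(frames, raw = raw, scenario = scenario,
                         backend = registration, reference = reference)
  unions <- build_union_map(reg, connectivity)
  cg <- build_conflict_graph(reg, unions, min_overlap = min_overlap)
  assignment <- resolve_conflicts(cg)
  masks <- iou_masks(reg)
  graphs <- lapply(seq_len(assignment$n_lineages), build_lineage_graph,
                   assignment = assignment, registered = reg, masks = masks)
  if (!allow_merges) graphs <- lapply(graphs, resolve_merges)
  graphs <- lapply(graphs, classify_events,
                   total_timepoints = length(frames))
  tracks <- assign_tracked_ids(graphs, allow_merges = allow_merges)
  projected <- project_back(frames, assignment, tracks)
  structure(list(
    frames = frames, registered = reg, union_maps = unions,
    conflict_graph = cg, assignment = assignment, lineage_graphs = graphs,
    tracks = tracks, projected = projected,
    config = list(scenario = scenario, reference = as.integer(reference),
                  allow_merges = allow_merges,
                  min_overlap = as.integer(min_overlap),
                  connectivity = as.integer(connectivity),
                  dimensionality = d,
                  backend = as_reg_backend(registration)$type),
    call = cl
  ), class = "moltrack")
}

#' Extract the tracked-ID table
#'
#' @param fit A [moltrack()] result.
#' @return Data frame with one row per tracked ID: `track`, `start`, `end`
#'   (1-based timepoints), `parent` (0 = none) and `lineage`.
#' @export
track_table <- function(fit) {
  stopifnot(inherits(fit, "moltrack"))
  fit$tracks$table
}

#' Extract the instance-to-lineage/track mapping
#'
#' @param fit A [moltrack()] result.
#' @return Data frame with one row per instance: `timepoint`, `label`,
#'   `lineage`, `track`, `orphan`.
#' @export
lineage_table <- function(fit) {
  stopifnot(inherits(fit, "moltrack"))
  fit$projected$track_map
}

#' Count classified morphogenetic events
#'
#' @param fit A [moltrack()] result.
#' @return Named integer vector: numbers of split, merge, emerge, vanish and
#'   reappear events across all lineages (splits counted as split-parent
#'   nodes, merges as merge-child nodes).
#' @export
event_counts <- function(fit) {
  stopifnot(inherits(fit, "moltrack"))
  ev <- do.call(rbind, lapply(fit$lineage_graphs, `[[`, "events"))
  if (is.null(ev)) {
    return(c(split = 0L, merge = 0L, emerge = 0L, vanish = 0L,
             reappear = 0L))
  }
  c(split = sum(ev$split_parent), merge = sum(ev$merge_child),
    emerge = sum(ev$emerge), vanish = sum(ev$vanish),
    reappear = sum(ev$reappear))
}

#' @export
print.moltrack <- function(x, ...) {
  cat(sprintf(
    "Multi-object lineage tracking (%s, %dD, backend '%s')\n",
    x$config$scenario, x$config$dimensionality, x$config$backend))
  cat(sprintf("  %d frame(s), %d instance(s), %d lineage(s), %d track(s)\n",
              length(x$frames), nrow(x$projected$track_map),
              max(c(0L, x$projected$lineage_map$lineage)),
              max(c(0L, x$projected$track_map$track))))
  invisible(x)
}

#' Summarize a tracking result
#'
#' @param object A [moltrack()] result.
#' @param ... Unused.
#' @return A `summary.moltrack` list with instance/lineage/track counts,
#'   event counts, orphan count and per-lineage sizes.
#' @export
summary.moltrack <- function(object, ...) {
  ev <- do.call(rbind, lapply(object$lineage_graphs, `[[`, "events"))
  counts <- if (is.null(ev)) {
    c(split = 0L, merge = 0L, emerge = 0L, vanish = 0L, reappear = 0L)
  } else {
    c(split = sum(ev$split_parent), merge = sum(ev$merge_child),
      emerge = sum(ev$emerge), vanish = sum(ev$vanish),
      reappear = sum(ev$reappear))
  }
  structure(list(
    scenario = object$config$scenario,
    n_frames = length(object$frames),
    n_instances = nrow(object$projected$track_map),
    n_lineages = max(c(0L, object$projected$lineage_map$lineage)),
    n_tracks = max(c(0L, object$projected$track_map$track)),
    n_orphans = nrow(object$assignment$orphans),
    events = counts,
    lineage_sizes = if (nrow(object$assignment$mapping))
      as.integer(table(object$assignment$mapping$lineage)) else integer(0)
  ), class = "summary.moltrack")
}

#' @export
print.summary.moltrack <- function(x, ...) {
  cat(sprintf("Tracking summary (%s): %d frames, %d instances\n",
              x$scenario, x$n_frames, x$n_instances))
  cat(sprintf("  lineages: %d   tracks: %d   orphans: %d\n",
              x$n_lineages, x$n_tracks, x$n_orphans))
  cat(sprintf("  events: %s\n",
              paste(sprintf("%s=%d", names(x$events), x$events),
                    collapse = " ")))
  invisible(x)
}

#' Plot a tracking result
#'
#' `type = "lineage"` draws the lineage forest: one horizontal line per
#' tracked ID spanning its timepoints, with parent links drawn at split and
#' merge events. `type = "frame"` shows one frame recolored by tracked ID
#' (2D frames; for 3D the central slice is shown).
#'
#' @param x A [moltrack()] result.
#' @param type `"lineage"` or `"frame"`.
#' @param timepoint Frame to display for `type = "frame"`.
#' @param ... Passed to the underlying base-graphics calls.
#' @export
plot.moltrack <- function(x, type = c("lineage", "frame"), timepoint = 1L,
                          ...) {
  type <- match.arg(type)
  if (type == "frame") {
    fr <- x$projected$track_frames[[timepoint]]$labels
    if (length(dim(fr)) == 3L) fr <- fr[, , ceiling(dim(fr)[3L] / 2)]
    n <- max(fr, 1L)
    graphics::image(t(fr[nrow(fr):1, , drop = FALSE]), axes = FALSE,
                    col = c("black", grDevices::hcl.colors(n, "Spectral")),
                    main = sprintf("tracked IDs, t = %d", timepoint), ...)
    return(invisible(x))
  }
  tab <- x$tracks$table
  if (!nrow(tab)) {
    graphics::plot.new()
    graphics::title("no tracks")
    return(invisible(x))
  }
  tab <- tab[order(tab$lineage, tab$track), , drop = FALSE]
  y <- stats::setNames(seq_len(nrow(tab)), tab$track)
  graphics::plot(NA, xlim = c(1, length(x$frames)),
                 ylim = c(0, nrow(tab) + 1), xlab = "timepoint",
                 ylab = "tracked ID", yaxt = "n", ...)
  graphics::axis(2, at = y, labels = tab$track, las = 1, cex.axis = 0.7)
  cols <- grDevices::hcl.colors(max(tab$lineage), "Dark 3")
  graphics::segments(tab$start, y, tab$end, y, lwd = 3,
                     col = cols[tab$lineage])
  graphics::points(tab$start, y, pch = 16, col = cols[tab$lineage])
  has_par <- tab$parent > 0L
  if (any(has_par)) {
    py <- y[as.character(tab$parent[has_par])]
    graphics::segments(tab$start[has_par] - 1L, py, tab$start[has_par],
                       y[has_par], lty = 2, col = "grey40")
  }
  invisible(x)
}
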