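#' Labeled frame
#'
#' Wraps one timepoint's integer label image. Label value 0 is background;
#' every positive value identifies one object instance within this frame
#' only (per-frame "initial" identifiers are not consistent across time —
#' making them consistent is the job of [moltrack()]).
#'
#' @param labels An integer matrix (2D) or 3D integer array. Values must be
#'   non-negative; non-integer numeric input is rejected.
#' @param timepoint 1-based timepoint index of this frame within its series.
#' @return An object of class `labeled_frame` with elements `labels`,
#'   `timepoint` and `dimensionality`.
#' @seealso [identify_instances()], [instance_masks()]
#' @export
labeled_frame <- function(labels, timepoint = 1L) {
  if (is.logical(labels)) {
    storage.mode(labels) <- "integer"
  }
  if (!is.numeric(labels)) {
    stop("'labels' must be a numeric/integer array", call. = FALSE)
  }
  dm <- dim(labels)
  if (is.null(dm) || !(length(dm) %in% c(2L, 3L))) {
    stop("'labels' must be a 2D matrix or a 3D array", call. = FALSE)
  }
  if (anyNA(labels)) stop("'labels' contains NA", call. = FALSE)
  if (any(labels < 0)) stop("'labels' contains negative values", call. = FALSE)
  if (is.double(labels)) {
    if (any(labels != round(labels))) {
      stop("'labels' contains non-integer values", call. = FALSE)
    }
    storage.mode(labels) <- "integer"
  }
  structure(
    list(labels = labels, timepoint = as.integer(timepoint),
         dimensionality = length(dm)),
    class = "labeled_frame"
  )
}

#' @export
print.labeled_frame <- function(x, ...) {
  labs <- frame_labels(x)
  cat(sprintf("<labeled_frame> t = %d, %s, %d instance(s)\n",
              x$timepoint, paste(dim(x$labels), collapse = "x"), length(labs)))
  invisible(x)
}

as_labeled_frame <- function(x, timepoint = 1L) {
  if (inherits(x, "labeled_frame")) return(x)
  labeled_frame(x, timepoint)
}

frame_labels <- function(frame) {
  v <- frame$labels
  sort(unique(v[v > 0L]))
}

default_connectivity <- function(dimensionality) {
  if (dimensionality == 2L) 8L else 26L
}

check_connectivity <- function(connectivity, dimensionality) {
  ok <- (dimensionality == 2L && connectivity == 8L) ||
    (dimensionality == 3L && connectivity == 26L)
  if (!ok) {
    stop(sprintf(
      "connectivity %d is invalid for %dD frames (use 8 for 2D, 26 for 3D)",
      connectivity, dimensionality), call. = FALSE)
  }
  invisible(connectivity)
}

## Offsets covering one half of the full (8- or 26-) neighbourhood; scanning
## them once per voxel enumerates every adjacent pair exactly once.
half_neighbourhood <- function(dimensionality) {
  g <- as.matrix(do.call(expand.grid, rep(list(-1L:1L), dimensionality)))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  first_nz <- apply(g, 1L, function(r) r[which(r != 0L)[1L]])
  unname(g[first_nz > 0L, , drop = FALSE])
}

## column-major linear index of coordinate rows (1-based)
linear_index <- function(coords, dm) {
  idx <- coords[, 1L]
  mult <- 1L
  for (j in seq_along(dm)[-1L]) {
    mult <- mult * dm[j - 1L]
    idx <- idx + (coords[, j] - 1L) * mult
  }
  idx
}

#' Label connected components of a binary array
#'
#' Labels each maximal connected foreground region with a distinct positive
#' integer. Adjacency is 8-connectivity in 2D and 26-connectivity in 3D
#' (edge- and corner-touching voxels are connected). Components are numbered
#' 1..N in ascending order of their first voxel in array (column-major) scan
#' order, so output labels are deterministic.
#'
#' @param x A logical or numeric 2D/3D array; non-zero entries are foreground.
#' @param connectivity 8 (2D) or 26 (3D); defaults to match dimensionality.
#' @return An integer array of the same shape with component labels.
#' @export
label_components <- function(x, connectivity = NULL) {
  dm <- dim(x)
  d <- length(dm)
  if (is.null(connectivity)) connectivity <- default_connectivity(d)
  check_connectivity(connectivity, d)
  out <- array(0L, dm)
  fg <- which(x != 0)
  n <- length(fg)
  if (n == 0L) return(out)
  pos <- array(0L, dm)
  pos[fg] <- seq_len(n)
  co <- arrayInd(fg, dm)
  offs <- half_neighbourhood(d)
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[i, ], n, d, byrow = TRUE)
    ok <- rep(TRUE, n)
    for (j in seq_len(d)) ok <- ok & nb[, j] >= 1L & nb[, j] <= dm[j]
    if (!any(ok)) next
    nbp <- pos[linear_index(nb[ok, , drop = FALSE], dm)]
    keep <- nbp > 0L
    if (any(keep)) {
      edges[[i]] <- cbind(seq_len(n)[ok][keep], nbp[keep])
    }
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0L) {
    out[fg] <- seq_len(n)
    return(out)
  }
  g <- igraph::make_undirected_graph(t(edges), n = n)
  memb <- igraph::components(g)$membership
  ## fg is ascending, so match() numbers components by first-voxel scan order
  out[fg] <- match(memb, unique(memb))
  out
}

#' Identify object instances in a frame
#'
#' Runs connected-component analysis on binary input (8-connectivity for 2D,
#' 26-connectivity for 3D) to assign one label per connected foreground
#' region. Input that already carries an instance segmentation — more than
#' one distinct positive label — is passed through unchanged; its labels are
#' only validated for connectedness and a warning is raised for any label
#' whose support is disconnected (such labels are kept as-is, never
#' re-split).
#'
#' @param frame A [labeled_frame()], or a bare array accepted by it.
#' @param connectivity 8 (2D) or 26 (3D); defaults to match dimensionality.
#' @return A `labeled_frame` whose positive labels are 1..N in scan order
#'   (for binary input) or the untouched input labels.
#' @export
identify_instances <- function(frame, connectivity = NULL) {
  frame <- as_labeled_frame(frame)
  d <- frame$dimensionality
  if (is.null(connectivity)) connectivity <- default_connectivity(d)
  check_connectivity(connectivity, d)
  labs <- frame_labels(frame)
  if (length(labs) > 1L) {
    cc <- label_components(frame$labels, connectivity)
    for (k in labs) {
      if (length(unique(cc[frame$labels == k])) > 1L) {
        warning(sprintf(
          "frame t=%d: label %d is disconnected under %d-connectivity; kept as one instance",
          frame$timepoint, k, connectivity), call. = FALSE)
      }
    }
    return(frame)
  }
  relab <- label_components(frame$labels, connectivity)
  labeled_frame(relab, frame$timepoint)
}

#' Extract per-instance voxel masks
#'
#' @param frame A [labeled_frame()].
#' @return A named list, one element per positive label (names are the label
#'   values), each an integer vector of linear voxel indices into the frame
#'   array. Masks are pairwise disjoint and their union is the foreground.
#' @export
instance_masks <- function(frame) {
  frame <- as_labeled_frame(frame)
  v <- frame$labels
  fg <- which(v > 0L)
  if (!length(fg)) return(structure(list(), names = character(0)))
  split(fg, v[fg])
}

## validate that a list of frames forms a series: shapes equal,
## timepoints 1..T
check_series <- function(frames) {
  if (!length(frames)) stop("empty series", call. = FALSE)
  frames <- lapply(seq_along(frames), function(t) {
    f <- as_labeled_frame(frames[[t]], t)
    f$timepoint <- as.integer(t)
    f
  })
  dm <- dim(frames[[1L]]$labels)
  for (f in frames[-1L]) {
    if (!identical(dim(f$labels), dm)) {
      stop(sprintf("frame t=%d shape (%s) differs from frame 1 (%s)",
                   f$timepoint, paste(dim(f$labels), collapse = "x"),
                   paste(dm, collapse = "x")), call. = FALSE)
    }
  }
  frames
}
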