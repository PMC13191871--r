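## File formats: per-frame (multi-page) TIFF label images, Cell Tracking
## Challenge track tables (res_track.txt / man_track.txt), lineage-graph
## JSON, YAML run configuration.

#' Read a label-image series from TIFF files
#'
#' One file per timepoint; multi-page files are stacked into 3D arrays.
#' Frame order is derived from the numeric component of the file names
#' (e.g. `mask000.tif`, `t001.tif`) and must be strictly increasing; the
#' frames are returned with timepoints 1..T.
#'
#' @param path A directory, a glob pattern, or a character vector of files.
#' @return A list of [labeled_frame()]s.
#' @export
read_label_series <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
               ignore.case = TRUE)
  } else if (length(path) == 1L && grepl("[*?]", path)) {
    Sys.glob(path)
  } else {
    path
  }
  if (!length(files)) stop("no TIFF files found", call. = FALSE)
  num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
  if (anyNA(num) || anyDuplicated(num)) {
    num <- seq_along(files)  # fall back to lexicographic order
    files <- sort(files)
  }
  files <- files[order(num)]
  frames <- vector("list", length(files))
  dm0 <- NULL
  for (i in seq_along(files)) {
    img <- tryCatch(tiff::readTIFF(files[i], all = TRUE, as.is = TRUE),
                    error = function(e) {
                      stop(sprintf("cannot read '%s': %s", files[i],
                                   conditionMessage(e)), call. = FALSE)
                    })
    arr <- if (length(img) == 1L) img[[1L]] else {
      array(unlist(img), c(dim(img[[1L]]), length(img)))
    }
    if (is.null(dm0)) dm0 <- dim(arr)
    if (!identical(dim(arr), dm0)) {
      stop(sprintf("frame shape mismatch in '%s' (%s, expected %s)",
                   files[i], paste(dim(arr), collapse = "x"),
                   paste(dm0, collapse = "x")), call. = FALSE)
    }
    frames[[i]] <- labeled_frame(arr, i)
  }
  frames
}

#' Write a label-image series as 16-bit TIFF files
#'
#' @param frames List of [labeled_frame()]s (or arrays).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `<prefix><ttt>.tif`, numbered
#'   from 0.
#' @return Invisibly, the written file paths.
#' @export
write_label_series <- function(frames, dir, prefix = "mask") {
  frames <- check_series(frames)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    arr <- frames[[i]]$labels
    if (max(arr) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
    paths[i] <- file.path(dir, sprintf("%s%03d.tif", prefix, i - 1L))
    img <- arr / 65535
    what <- if (length(dim(arr)) == 3L) {
      lapply(seq_len(dim(arr)[3L]), function(z) img[, , z])
    } else {
      img
    }
    tiff::writeTIFF(what, paths[i], bits.per.sample = 16L,
                    compression = "none", reduce = FALSE)
  }
  invisible(paths)
}

#' Read / write Cell Tracking Challenge track tables
#'
#' The CTC text format has one whitespace-separated row per track:
#' `label begin end parent`, with 0-based frame indices and parent 0
#' meaning none. Timepoints are converted to this package's 1-based
#' convention on read and back on write.
#'
#' @param file Path to `res_track.txt` / `man_track.txt`.
#' @return `read_ctc_tracks`: a data frame with columns `track`, `start`,
#'   `end`, `parent` (1-based timepoints).
#' @export
read_ctc_tracks <- function(file) {
  if (file.size(file) == 0L) {
    return(data.frame(track = integer(0), start = integer(0),
                      end = integer(0), parent = integer(0)))
  }
  tab <- utils::read.table(file, col.names = c("track", "start", "end",
                                               "parent"))
  tab$start <- tab$start + 1L
  tab$end <- tab$end + 1L
  tab
}

#' @rdname read_ctc_tracks
#' @param x A [moltrack()] fit, [assign_tracked_ids()] result, or a data
#'   frame with columns `track`, `start`, `end`, `parent`.
#' @export
write_ctc_tracks <- function(x, file) {
  if (inherits(x, "moltrack")) x <- x$tracks
  if (inherits(x, "track_table")) x <- x$table
  stopifnot(all(c("track", "start", "end", "parent") %in% names(x)))
  out <- data.frame(track = x$track, start = x$start - 1L, end = x$end - 1L,
                    parent = x$parent)
  utils::write.table(out, file, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Serialize lineage graphs to JSON
#'
#' Writes a node/edge document per lineage (node timepoints and labels,
#' IoU-weighted edges, event tags) plus the instance-to-lineage/track
#' mapping; [read_lineage_json()] restores the same structure.
#'
#' @param fit A [moltrack()] fit.
#' @param file Output path.
#' @export
write_lineage_json <- function(fit, file) {
  stopifnot(inherits(fit, "moltrack"))
  doc <- list(
    scenario = fit$config$scenario,
    n_frames = length(fit$frames),
    lineages = lapply(fit$lineage_graphs, function(g) {
      list(lineage = g$lineage, nodes = g$nodes, edges = g$edges,
           events = g$events)
    }),
    mapping = fit$projected$track_map,
    tracks = fit$tracks$table
  )
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}

#' @rdname write_lineage_json
#' @export
read_lineage_json <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  as_df <- function(cols) as.data.frame(cols, optional = TRUE)
  doc$mapping <- as_df(doc$mapping)
  doc$tracks <- as_df(doc$tracks)
  doc$lineages <- lapply(doc$lineages, function(g) {
    list(lineage = g$lineage, nodes = as_df(g$nodes),
         edges = as_df(g$edges), events = as_df(g$events))
  })
  doc
}

## ---- CTC-style evaluation inputs -------------------------------------------

#' Read a CTC-style result directory
#'
#' Expects per-frame label TIFFs in which each foreground voxel carries its
#' tracked ID, plus a `res_track.txt` or `man_track.txt` table.
#'
#' @param dir Directory path.
#' @return A list with `frames` (label frames, values = tracked IDs) and
#'   `table` (see [read_ctc_tracks()]).
#' @export
read_ctc_result <- function(dir) {
  tabfile <- c(file.path(dir, "res_track.txt"), file.path(dir, "man_track.txt"))
  tabfile <- tabfile[file.exists(tabfile)][1L]
  if (is.na(tabfile)) {
    stop(sprintf("no res_track.txt / man_track.txt in '%s'", dir),
         call. = FALSE)
  }
  list(frames = read_label_series(dir), table = read_ctc_tracks(tabfile))
}

#' Tracking graph and lineage partition of a CTC-style result
#'
#' `ctc_tracking_graph` builds the acyclic oriented graph: one node per
#' (frame, tracked ID) detection with its voxels, link edges between a
#' track's consecutive detections, parent edges from a parent track's last
#' detection to its child's first. `ctc_lineage_partition` groups tracks
#' connected by parent links into lineages.
#'
#' @param res A [read_ctc_result()] list.
#' @return A [tracking_graph()], respectively a lineage partition data
#'   frame (`timepoint`, `label`, `lineage`).
#' @export
ctc_tracking_graph <- function(res) {
  masks <- lapply(res$frames, instance_masks)
  nodes <- do.call(rbind, lapply(seq_along(masks), function(t) {
    ks <- as.integer(names(masks[[t]]))
    if (length(ks)) data.frame(timepoint = t, label = ks) else NULL
  }))
  if (is.null(nodes)) nodes <- data.frame(timepoint = integer(0),
                                          label = integer(0))
  nodes$track <- nodes$label
  nodes$voxels <- lapply(seq_len(nrow(nodes)), function(i) {
    masks[[nodes$timepoint[i]]][[as.character(nodes$label[i])]]
  })
  edges <- list()
  for (i in seq_len(nrow(res$table))) {
    tr <- res$table$track[i]
    ts <- sort(nodes$timepoint[nodes$label == tr])
    if (length(ts) > 1L) {
      edges[[length(edges) + 1L]] <-
        data.frame(from_t = ts[-length(ts)], from_k = tr, to_t = ts[-1L],
                   to_k = tr, semantics = "link")
    }
    p <- res$table$parent[i]
    if (p > 0L) {
      pts <- nodes$timepoint[nodes$label == p]
      if (length(pts) && length(ts)) {
        edges[[length(edges) + 1L]] <-
          data.frame(from_t = max(pts), from_k = p, to_t = min(ts),
                     to_k = tr, semantics = "parent")
      }
    }
  }
  tracking_graph(nodes, if (length(edges)) do.call(rbind, edges) else NULL)
}

#' @rdname ctc_tracking_graph
#' @export
ctc_lineage_partition <- function(res) {
  tab <- res$table
  ids <- tab$track
  root <- stats::setNames(ids, ids)
  find <- function(i) {
    while (root[[as.character(i)]] != i) i <- root[[as.character(i)]]
    i
  }
  for (i in seq_len(nrow(tab))) {
    if (tab$parent[i] > 0L && as.character(tab$parent[i]) %in% names(root)) {
      root[[as.character(find(ids[i]))]] <- find(tab$parent[i])
    }
  }
  lin_of <- vapply(ids, find, 0)
  lin_id <- match(lin_of, unique(lin_of))
  ## instances are keyed by their first voxel, not by the file's label
  ## values, so partitions from differently-labeled files (e.g. ground
  ## truth vs prediction over the same segmentation) stay comparable
  nodes <- do.call(rbind, lapply(seq_along(res$frames), function(t) {
    masks <- instance_masks(res$frames[[t]])
    if (!length(masks)) return(NULL)
    data.frame(timepoint = t,
               label = vapply(masks, min, 0L),
               file_label = as.integer(names(masks)))
  }))
  if (is.null(nodes)) {
    return(data.frame(timepoint = integer(0), label = integer(0),
                      lineage = integer(0)))
  }
  nodes$lineage <- lin_id[match(nodes$file_label, ids)]
  rownames(nodes) <- NULL
  nodes[c("timepoint", "label", "lineage")]
}

## ---- run configuration and the disk-level pipeline -------------------------

#' Read a YAML run configuration
#'
#' Fields mirror the [run_pipeline()] arguments; command-line flags override
#' file values in the `moltrack` script.
#'
#' @param file YAML path.
#' @return A named list.
#' @export
read_run_config <- function(file) {
  yaml::read_yaml(file)
}

#' Run the tracking pipeline on files
#'
#' Reads a label series (and optional raw series), runs [moltrack()], and
#' writes, in native image space: lineage-labeled frames
#' (`<out>/lineage/`), track-labeled frames (`<out>/tracks/`), the CTC
#' track table `res_track.txt`, the lineage-graph JSON, and a run log. On
#' error, partially written outputs are removed.
#'
#' @param config Named list (or YAML path): `labels` (dir/glob/files),
#'   optional `raw`, `scenario`, `registration` (`"translation"`,
#'   `"identity"`, or `"matrices"` with `matrices_dir` of per-frame
#'   plain-text homogeneous matrices named by timepoint), `reference`,
#'   `allow_merges`, `min_overlap`, `out`.
#' @return Invisibly, the [moltrack()] fit.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- list(scenario = "S1", registration = "translation",
                   reference = 1L, allow_merges = TRUE, min_overlap = 1L,
                   raw = NULL, matrices_dir = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$labels) || is.null(config$out)) {
    stop("config needs 'labels' and 'out'", call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  frames <- stage("input", read_label_series(config$labels))
  raw <- if (!is.null(config$raw)) {
    stage("input", lapply(read_label_series(config$raw),
                          function(f) f$labels))
  }
  backend <- stage("registration", {
    if (identical(config$registration, "matrices")) {
      files <- list.files(config$matrices_dir, full.names = TRUE)
      num <- as.integer(gsub("\\D", "", basename(files)))
      trs <- vector("list", length(frames))
      for (i in seq_along(files)) {
        trs[[num[i]]] <- read_affine_matrix(files[i])
      }
      reg_supplied(trs)
    } else {
      as_reg_backend(config$registration)
    }
  })
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written, recursive = TRUE), add = TRUE)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("moltrack run: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  note("scenario=%s backend=%s allow_merges=%s min_overlap=%d frames=%d",
       config$scenario, config$registration, config$allow_merges,
       as.integer(config$min_overlap), length(frames))
  orphan_warnings <- character(0)
  fit <- stage("tracking", withCallingHandlers(
    moltrack(frames, scenario = config$scenario, raw = raw,
             registration = backend, reference = config$reference,
             allow_merges = config$allow_merges,
             min_overlap = config$min_overlap),
    warning = function(w) {
      orphan_warnings <<- c(orphan_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  for (w in orphan_warnings) note("warning: %s", w)
  s <- summary(fit)
  note("instances=%d lineages=%d tracks=%d orphans=%d", s$n_instances,
       s$n_lineages, s$n_tracks, s$n_orphans)
  note("events: %s", paste(sprintf("%s=%d", names(s$events), s$events),
                           collapse = " "))
  stage("output", {
    written <<- c(written, file.path(out, c("lineage", "tracks")))
    write_label_series(fit$projected$lineage_frames,
                       file.path(out, "lineage"))
    write_label_series(fit$projected$track_frames, file.path(out, "tracks"))
    f1 <- file.path(out, "tracks", "res_track.txt")  # CTC result layout
    write_ctc_tracks(fit, f1)
    f2 <- file.path(out, "lineage_graphs.json")
    write_lineage_json(fit, f2)
    f3 <- file.path(out, "run_log.txt")
    writeLines(log, f3)
    written <<- c(written, f1, f2, f3)
  })
  ok <- TRUE
  invisible(fit)
}

#' Write a simulated scenario to disk
#'
#' Writes the perturbed label frames as TIFFs plus the ground truth as a
#' `man_track.txt`-style table, so synthetic fixtures are consumed through
#' the same readers as real data.
#'
#' @param truth A [simulate_scenario()] result.
#' @param dir Output directory.
#' @export
write_scenario <- function(truth, dir) {
  stopifnot(inherits(truth, "scenario_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tframes <- lapply(seq_along(truth$perturbed), function(t) {
    frame <- truth$perturbed[[t]]
    sub <- truth$track_map[truth$track_map$timepoint == t, , drop = FALSE]
    lut <- integer(max(c(0L, sub$label)) + 1L)
    lut[sub$label + 1L] <- sub$track
    labeled_frame(array(lut[frame$labels + 1L], dim(frame$labels)), t)
  })
  write_label_series(tframes, dir, prefix = "man_track")
  write_ctc_tracks(truth$track_table, file.path(dir, "man_track.txt"))
  invisible(dir)
}
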