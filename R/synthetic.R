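## Synthetic label-image time series with complete ground truth: ellipsoid
## blobs, a scheduled event system (split / merge / appear / vanish / gap),
## optional per-frame global affine jitter (S1) or per-object random-walk
## motion (S2). Everything is driven by one seeded RNG stream, so a spec
## replays bit-identically.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specify a synthetic tracking scenario
#'
#' Describes a 2D/3D time series of non-overlapping ellipsoid blobs with a
#' schedule of morphogenetic events and a known misalignment model. Under
#' `"S1"` blobs are static relative to each other and every frame after the
#' first can receive a random global affine jitter (bounded translation,
#' rotation and scale); under `"S2"` blobs perform independent random walks
#' with a small per-step displacement. Events reference seed objects (1 ..
#' `n_objects`); at most one event per object, which keeps scheduled event
#' counts identical to the event tags [classify_events()] should recover.
#'
#' @param scenario `"S1"` or `"S2"`.
#' @param shape Frame shape, length 2 or 3 (voxels).
#' @param n_frames Number of timepoints T.
#' @param n_objects Number of seed objects present at t = 1.
#' @param events List of events, each a list with `type` in `"split"`,
#'   `"merge"`, `"appear"`, `"vanish"`, `"gap"`, a timepoint `t`, and
#'   `object` (or `objects`, two IDs, for merges). Event timing: the
#'   post-event state first appears at frame `t` (children at `t`, object
#'   absent from `t` for vanish, absent exactly at `t` for gap).
#' @param jitter List with `translation` (max voxels per axis), `rotation`
#'   (max degrees) and `scale` (max relative deviation); S1 only.
#' @param step_sd Per-axis random-walk step standard deviation (voxels per
#'   frame); S2 only.
#' @param radius_range Ellipsoid radius range (voxels) for seed objects.
#' @param radius_jitter Per-frame multiplicative radius jitter (growth and
#'   shrinkage without topology change); kept at most 0.1.
#' @param min_spacing Minimum clearance between blob surfaces (voxels).
#' @param seed Integer seed driving all randomness of [simulate_scenario()].
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("S1", "S2"), shape = c(64, 64),
                          n_frames = 8L, n_objects = 10L, events = list(),
                          jitter = list(translation = 0, rotation = 0,
                                        scale = 0),
                          step_sd = 0, radius_range = c(3, 4.5),
                          radius_jitter = 0.05, min_spacing = 4,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(length(shape) %in% c(2L, 3L), all(shape >= 8L), n_frames >= 1L,
            n_objects >= 0L, radius_jitter >= 0, radius_jitter <= 0.1,
            length(radius_range) == 2L, radius_range[1L] >= 1)
  jitter <- utils::modifyList(list(translation = 0, rotation = 0, scale = 0),
                              as.list(jitter))
  spec <- structure(list(
    scenario = scenario, shape = as.integer(shape),
    n_frames = as.integer(n_frames), n_objects = as.integer(n_objects),
    events = events, jitter = jitter, step_sd = step_sd,
    radius_range = radius_range, radius_jitter = radius_jitter,
    min_spacing = min_spacing, seed = as.integer(seed)
  ), class = "scenario_spec")
  validate_scenario_spec(spec)
  spec
}

validate_scenario_spec <- function(spec) {
  T_ <- spec$n_frames
  seen <- integer(0)
  for (i in seq_along(spec$events)) {
    ev <- spec$events[[i]]
    bad <- function(msg) stop(sprintf("event %d (%s): %s", i,
                                      if (is.null(ev$type)) "?" else ev$type,
                                      msg), call. = FALSE)
    if (is.null(ev$type) ||
        !ev$type %in% c("split", "merge", "appear", "vanish", "gap")) {
      bad("unknown type")
    }
    if (is.null(ev$t) || ev$t < 2L) bad("timepoint must be >= 2")
    if (ev$type == "gap" && ev$t > T_ - 1L) {
      bad("gap timepoint must leave a frame after it")
    }
    if (ev$t > T_) bad("timepoint beyond the series")
    obj <- if (ev$type == "merge") ev$objects else ev$object
    if (ev$type == "appear") {
      if (!is.null(obj)) bad("appear events create their object")
    } else {
      if (is.null(obj)) bad("missing object reference")
      if (ev$type == "merge" && (length(obj) != 2L || obj[1L] == obj[2L])) {
        bad("merge needs two distinct objects")
      }
      if (any(obj < 1L | obj > spec$n_objects)) {
        bad("references a non-seed object")
      }
      if (any(obj %in% seen)) bad("object already used by another event")
      seen <- c(seen, obj)
    }
    if (ev$type == "merge" && spec$scenario == "S2") {
      bad("merges are not permissible for independently moving (cell-style) scenarios")
    }
  }
  invisible(spec)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s %s, T=%d, %d object(s), %d event(s), seed=%d\n",
              x$scenario, paste(x$shape, collapse = "x"), x$n_frames,
              x$n_objects, length(x$events), x$seed))
  invisible(x)
}

render_ellipsoid <- function(dm, center, radii) {
  d <- length(dm)
  lo <- pmax(1, floor(center - radii))
  hi <- pmin(dm, ceiling(center + radii))
  if (any(hi < lo)) return(integer(0))
  g <- as.matrix(do.call(expand.grid, lapply(seq_len(d),
                                             function(j) lo[j]:hi[j])))
  v <- rowSums(((g - matrix(center, nrow(g), d, byrow = TRUE)) /
                  matrix(radii, nrow(g), d, byrow = TRUE))^2)
  sort(linear_index(g[v <= 1, , drop = FALSE], dm))
}

## rotation matrix about a random coordinate axis (2D: the only one)
small_rotation <- function(d, max_deg) {
  th <- stats::runif(1, -max_deg, max_deg) * pi / 180
  R2 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  if (d == 2L) return(R2)
  ax <- sample.int(3L, 1L)
  R <- diag(3)
  ij <- setdiff(1:3, ax)
  R[ij, ij] <- R2
  R
}

#' Generate a synthetic scenario with ground truth
#'
#' Replays the event schedule of a [scenario_spec()] into rendered label
#' frames plus complete ground truth: the clean series, the jitter-perturbed
#' series that serves as pipeline input, the true per-frame affine
#' transforms (and their inverses, to feed the `reg_supplied` passthrough
#' backend), the instance-to-object and instance-to-lineage maps, the true
#' track table and scheduled event counts. Deterministic for a fixed spec
#' (including its seed). Blobs never overlap within a frame (placement
#' enforces surface clearance); S1 jitter draws are redrawn until every blob
#' keeps at least 80% of its voxels in the field of view.
#'
#' @param spec A [scenario_spec()].
#' @return An object of class `scenario_truth`; see Details.
#' @details The returned object has elements `spec`, `frames` (clean
#'   [labeled_frame()]s), `perturbed` (pipeline input; identical to `frames`
#'   when no jitter), `jitter_transforms`, `true_transforms` (inverse
#'   jitter, indexed by timepoint), `object_map` / `lineage_map`
#'   (`timepoint`, `label`, `object` / `lineage`), `objects` (one row per
#'   physical object: `object`, `birth`, `death`, `origin`, `parent1`,
#'   `parent2`), `track_table` (true tracks: objects are exactly the
#'   maximal event-free segments), and `event_counts` (named vector:
#'   `split`, `merge`, `emerge`, `vanish`, `reappear`).
#' @export
simulate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  validate_scenario_spec(spec)
  with_seed(spec$seed, {
    dm <- spec$shape
    d <- length(dm)
    T_ <- spec$n_frames
    rmax <- spec$radius_range[2L]
    margin <- ceiling(1.1 * rmax + spec$min_spacing / 2 +
                        spec$jitter$translation / 2 + 2)
    if (any(dm - 2 * margin < 2)) {
      stop("frame shape too small for the requested radii/jitter margins",
           call. = FALSE)
    }

    ## ---- objects: id, birth, death, gaps, base radii, center path -------
    objects <- list()
    new_object <- function(birth, death, center, radii, origin,
                           parents = integer(0)) {
      id <- length(objects) + 1L
      path <- matrix(rep(center, each = T_), T_, d)
      objects[[id]] <<- list(id = id, birth = birth, death = death,
                             gaps = integer(0), radii = radii, path = path,
                             origin = origin, parents = parents)
      id
    }
    ## objects scheduled to split need extra clearance: their children are
    ## displaced beyond the parent footprint, and two adjacent families
    ## must never become adjacent in the union (that would fuse lineages)
    split_sched <- vapply(spec$events, function(ev) {
      if (ev$type == "split") ev$object else NA_integer_
    }, 0)
    split_sched <- split_sched[!is.na(split_sched)]
    merge_sched <- unlist(lapply(spec$events, function(ev) {
      if (ev$type == "merge") ev$objects else NULL
    }))
    split_reach <- function(radii) 0.65 * max(radii) + 1.8
    ## a fused blob's cross-section follows the larger partner, so it can
    ## bulge past the smaller one by up to the radius-range width
    merge_reach <- function() diff(spec$radius_range) +
      0.1 * spec$radius_range[2L] + 0.5
    reach_extra <- function(id, radii) {
      if (id %in% split_sched) split_reach(radii)
      else if (id %in% merge_sched) merge_reach()
      else 0
    }
    clearance_ok <- function(center, radii, t_range, ignore = integer(0),
                             extra = 0) {
      for (o in objects) {
        if (o$id %in% ignore) next
        if (o$death < t_range[1L] || o$birth > t_range[2L]) next
        tt <- max(t_range[1L], o$birth)
        dist <- sqrt(sum((center - o$path[tt, ])^2))
        if (dist < 1.1 * (max(radii) + max(o$radii)) + extra +
              reach_extra(o$id, o$radii) + spec$min_spacing) {
          return(FALSE)
        }
      }
      TRUE
    }
    place_center <- function(radii, t_range, near = NULL, at_dist = NULL,
                             ignore = integer(0), extra = 0) {
      for (try in 1:2000) {
        if (is.null(near)) {
          center <- stats::runif(d, margin + 1, dm - margin)
        } else {
          u <- stats::rnorm(d); u <- u / sqrt(sum(u^2))
          center <- near + u * at_dist
          if (any(center < margin + 1 | center > dm - margin)) next
        }
        if (clearance_ok(center, radii, t_range, ignore, extra)) {
          return(center)
        }
      }
      NULL
    }

    ## merge partners must sit close enough for the fused blob to span both
    merge_pairs <- do.call(rbind, lapply(spec$events, function(ev) {
      if (ev$type == "merge") matrix(ev$objects, 1L) else NULL
    }))
    partner_of <- integer(0)
    if (!is.null(merge_pairs)) {
      ## constrain the later-placed partner toward the earlier-placed one
      partner_of <- stats::setNames(pmin(merge_pairs[, 1L], merge_pairs[, 2L]),
                                    as.character(pmax(merge_pairs[, 1L],
                                                      merge_pairs[, 2L])))
    }

    rr <- spec$radius_range
    third <- (rr[2L] - rr[1L]) / 3
    placed <- FALSE
    for (attempt in 1:25) {  # sequential packing can dead-end; restart
      objects <- list()
      ok <- TRUE
      for (i in seq_len(spec$n_objects)) {
        ## merge partners get clearly distinct sizes, so the dominant-parent
        ## relation at the fusion is well-defined (not a knife-edge tie)
        radii <- if (i %in% partner_of) {
          stats::runif(d, rr[1L], rr[1L] + third)
        } else if (i %in% as.integer(names(partner_of))) {
          stats::runif(d, rr[2L] - third, rr[2L])
        } else {
          stats::runif(d, rr[1L], rr[2L])
        }
        near <- NULL; at_dist <- NULL; ign <- integer(0)
        p <- partner_of[as.character(i)]
        if (length(p) && !is.na(p)) {
          po <- objects[[p]]
          near <- po$path[1L, ]
          at_dist <- 1.1 * (max(radii) + max(po$radii)) +
            spec$min_spacing + 0.5
          ign <- po$id  # the pair-internal distance is intentional
        }
        center <- place_center(radii, c(1L, T_), near, at_dist, ign,
                               extra = reach_extra(i, radii))
        if (is.null(center)) {
          ok <- FALSE
          break
        }
        new_object(1L, T_, center, radii, "seed")
      }
      if (ok) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place the seed blobs with the requested spacing; enlarge the frame or reduce n_objects",
           call. = FALSE)
    }

    ## ---- replay the event schedule --------------------------------------
    n_events <- c(split = 0L, merge = 0L, emerge = 0L, vanish = 0L,
                  reappear = 0L)
    evs <- spec$events[order(vapply(spec$events, `[[`, 0, "t"))]
    for (ev in evs) {
      t <- as.integer(ev$t)
      switch(ev$type,
        split = {
          p <- objects[[ev$object]]
          if (p$death < t - 1L) stop("split references a dead object",
                                     call. = FALSE)
          objects[[p$id]]$death <- t - 1L
          cr <- p$radii * 2^(-1 / d)
          ax <- sample.int(d, 1L)
          delta <- cr[ax] + 1.2
          for (s in c(-1, 1)) {
            center <- p$path[t, ]
            center[ax] <- center[ax] + s * delta
            id <- new_object(t, T_, center, cr, "split", p$id)
            objects[[id]]$anchor_offset <- center - p$path[t, ]
          }
          n_events["split"] <- n_events["split"] + 1L
        },
        merge = {
          pa <- objects[[ev$objects[1L]]]
          pb <- objects[[ev$objects[2L]]]
          if (pa$death < t - 1L || pb$death < t - 1L) {
            stop("merge references a dead object", call. = FALSE)
          }
          objects[[pa$id]]$death <- t - 1L
          objects[[pb$id]]$death <- t - 1L
          mid <- (pa$path[t, ] + pb$path[t, ]) / 2
          half <- sqrt(sum((pa$path[t, ] - pb$path[t, ])^2)) / 2
          radii <- pmax(pa$radii, pb$radii)
          ax <- which.max(abs(pa$path[t, ] - pb$path[t, ]))
          radii[ax] <- half + max(pa$radii[ax], pb$radii[ax])
          new_object(t, T_, mid, radii, "merge", c(pa$id, pb$id))
          n_events["merge"] <- n_events["merge"] + 1L
        },
        appear = {
          radii <- stats::runif(d, spec$radius_range[1L],
                                spec$radius_range[2L])
          center <- place_center(radii, c(t, T_))
          if (is.null(center)) {
            stop("could not place an appearing blob with the requested spacing",
                 call. = FALSE)
          }
          new_object(t, T_, center, radii, "appear")
          n_events["emerge"] <- n_events["emerge"] + 1L
        },
        vanish = {
          objects[[ev$object]]$death <- t - 1L
          n_events["vanish"] <- n_events["vanish"] + 1L
        },
        gap = {
          objects[[ev$object]]$gaps <- c(objects[[ev$object]]$gaps, t)
          n_events["reappear"] <- n_events["reappear"] + 1L
        })
    }

    ## ---- S2 random-walk motion ------------------------------------------
    if (spec$scenario == "S2" && spec$step_sd > 0) {
      for (t in 2:max(T_, 2L)) {
        if (T_ < 2L) break
        for (id in seq_along(objects)) {
          ## children born at t are re-anchored to the parent's walked
          ## position (its path rows carry the last pre-death position)
          o <- objects[[id]]
          if (o$birth == t && length(o$parents) &&
              !is.null(o$anchor_offset)) {
            p <- objects[[o$parents[1L]]]
            cand <- pmin(pmax(p$path[t, ] + o$anchor_offset, margin + 1),
                         dm - margin)
            objects[[id]]$path[t:T_, ] <-
              matrix(rep(cand, each = T_ - t + 1L), T_ - t + 1L, d)
            next
          }
          if (o$birth >= t || o$death < t || o$origin %in% "merge") next
          ok <- FALSE
          for (try in 1:25) {
            step <- stats::rnorm(d, 0, spec$step_sd)
            cand <- pmin(pmax(o$path[t - 1L, ] + step, margin + 1),
                         dm - margin)
            if (clearance_ok(cand, o$radii, c(t, t), ignore = id)) {
              ok <- TRUE
              break
            }
          }
          objects[[id]]$path[t:T_, ] <-
            matrix(rep(if (ok) cand else o$path[t - 1L, ], each = T_ - t + 1L),
                   T_ - t + 1L, d)
          ## children keep tracking their (possibly moved) parent footprint
        }
      }
    }

    present <- function(o, t) o$birth <= t && o$death >= t && !(t %in% o$gaps)

    ## ---- render clean frames --------------------------------------------
    frames <- vector("list", T_)
    map_rows <- list()
    for (t in seq_len(T_)) {
      vox <- list(); ids <- integer(0)
      for (o in objects) {
        if (!present(o, t)) next
        rf <- stats::runif(1, 1 - spec$radius_jitter, 1 + spec$radius_jitter)
        m <- render_ellipsoid(dm, o$path[t, ], o$radii * rf)
        if (!length(m)) stop("object rendered empty", call. = FALSE)
        vox[[length(vox) + 1L]] <- m
        ids <- c(ids, o$id)
      }
      arr <- array(0L, dm)
      if (length(vox)) {
        if (length(unique(unlist(vox))) != length(unlist(vox))) {
          stop("blob overlap within a frame: spacing constraint violated",
               call. = FALSE)
        }
        ord <- order(vapply(vox, min, 0L))  # labels in scan order
        for (j in seq_along(ord)) {
          arr[vox[[ord[j]]]] <- j
          map_rows[[length(map_rows) + 1L]] <-
            data.frame(timepoint = t, label = j, object = ids[ord[j]])
        }
      }
      frames[[t]] <- labeled_frame(arr, t)
    }
    object_map <- if (length(map_rows)) do.call(rbind, map_rows) else
      data.frame(timepoint = integer(0), label = integer(0),
                 object = integer(0))

    ## ---- S1 global affine jitter ----------------------------------------
    jitter_transforms <- lapply(seq_len(T_), function(t) {
      identity_transform(d, t, t)
    })
    perturbed <- frames
    jit <- spec$jitter
    if (spec$scenario == "S1" &&
        (jit$translation > 0 || jit$rotation > 0 || jit$scale > 0)) {
      ctr <- (dm - 1) / 2
      for (t in 2:T_) {
        for (try in 1:50) {
          R <- small_rotation(d, jit$rotation)
          s <- stats::runif(1, 1 - jit$scale, 1 + jit$scale)
          tau <- stats::runif(d, -jit$translation, jit$translation)
          L <- s * R
          b <- ctr + tau - L %*% ctr
          J <- affine_transform(L, b, moving_index = t, fixed_index = t)
          cand <- apply_to_labels(frames[[t]], J)
          keep <- TRUE
          for (k in frame_labels(frames[[t]])) {
            if (sum(cand$labels == k) < 0.8 * sum(frames[[t]]$labels == k)) {
              keep <- FALSE
              break
            }
          }
          if (keep) break
        }
        if (!keep) stop("could not draw jitter keeping 80% of each blob in-field",
                        call. = FALSE)
        jitter_transforms[[t]] <- J
        perturbed[[t]] <- cand
      }
    }
    true_transforms <- lapply(jitter_transforms, function(J) {
      K <- invert_transform(J)
      K$moving_index <- J$moving_index
      K$fixed_index <- J$fixed_index
      K
    })

    ## ---- true lineages: union-find over interaction parentage -----------
    n_obj <- length(objects)
    root <- seq_len(n_obj)
    find <- function(i) { while (root[i] != i) i <- root[i]; i }
    for (o in objects) {
      for (p in o$parents) root[find(o$id)] <- find(p)
    }
    lin_of_obj <- vapply(seq_len(n_obj), find, 0L)
    object_map$lineage <- match(lin_of_obj, unique(lin_of_obj[
      order(vapply(objects, `[[`, 0L, "birth"))]))[object_map$object]
    lineage_map <- object_map[c("timepoint", "label", "lineage")]

    ## ---- true tracks: one per object (objects are event-free segments) --
    obj_df <- data.frame(
      object = vapply(objects, `[[`, 0L, "id"),
      birth = vapply(objects, `[[`, 0L, "birth"),
      death = vapply(objects, `[[`, 0L, "death"),
      origin = vapply(objects, `[[`, "", "origin"),
      parent1 = vapply(objects, function(o) {
        if (length(o$parents)) o$parents[1L] else 0L
      }, 0L),
      parent2 = vapply(objects, function(o) {
        if (length(o$parents) > 1L) o$parents[2L] else 0L
      }, 0L)
    )
    ord <- order(obj_df$birth, obj_df$object)
    track_id <- integer(n_obj)
    track_id[obj_df$object[ord]] <- seq_len(n_obj)
    primary_parent <- function(o) {
      if (!length(o$parents)) return(0L)
      if (length(o$parents) == 1L) return(track_id[o$parents[1L]])
      ## max-IoU parent at the merge boundary, same rule as the tracker
      t0 <- o$birth
      cm <- object_map[object_map$timepoint == t0 &
                         object_map$object == o$id, ]
      child_mask <- instance_masks(frames[[t0]])[[as.character(cm$label)]]
      best <- o$parents[1L]; best_iou <- -1; best_inter <- -1
      for (p in o$parents) {
        pm <- object_map[object_map$timepoint == t0 - 1L &
                           object_map$object == p, ]
        pmask <- instance_masks(frames[[t0 - 1L]])[[as.character(pm$label)]]
        st <- mask_iou(pmask, child_mask)
        if (st["iou"] > best_iou ||
            (st["iou"] == best_iou && st["inter"] > best_inter)) {
          best <- p; best_iou <- st["iou"]; best_inter <- st["inter"]
        }
      }
      track_id[best]
    }
    track_table <- data.frame(
      track = track_id,
      start = obj_df$birth,
      end = obj_df$death,
      parent = vapply(objects, primary_parent, 0L),
      lineage = lineage_map$lineage[match(obj_df$object,
                                          object_map$object)]
    )
    track_table <- track_table[order(track_table$track), ]
    rownames(track_table) <- NULL
    track_map <- object_map
    track_map$track <- track_id[track_map$object]

    structure(list(
      spec = spec, frames = frames, perturbed = perturbed,
      jitter_transforms = jitter_transforms,
      true_transforms = true_transforms,
      objects = obj_df, object_map = object_map,
      lineage_map = lineage_map, track_map = track_map,
      track_table = track_table, event_counts = n_events
    ), class = "scenario_truth")
  })
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat(sprintf(
    "<scenario_truth> %s, T=%d, %d object(s), %d lineage(s), events: %s\n",
    x$spec$scenario, x$spec$n_frames, nrow(x$objects),
    max(c(0L, x$lineage_map$lineage)),
    paste(sprintf("%s=%d", names(x$event_counts), x$event_counts),
          collapse = " ")))
  invisible(x)
}

#' Ground-truth tracking graph of a simulated scenario
#'
#' @param truth A [simulate_scenario()] result.
#' @param use `"clean"` attaches voxel masks from the clean frames,
#'   `"perturbed"` from the jittered pipeline-input frames.
#' @return A [tracking_graph()] with link edges along each object's
#'   detections (bridging scheduled gaps) and parent edges at splits and
#'   merges.
#' @export
truth_tracking_graph <- function(truth, use = c("clean", "perturbed")) {
  use <- match.arg(use)
  frames <- if (use == "clean") truth$frames else truth$perturbed
  masks <- lapply(frames, instance_masks)
  om <- truth$object_map
  nodes <- truth$track_map[c("timepoint", "label", "track")]
  nodes$voxels <- lapply(seq_len(nrow(nodes)), function(i) {
    masks[[nodes$timepoint[i]]][[as.character(nodes$label[i])]]
  })
  node_of <- function(obj, t) om[om$object == obj & om$timepoint == t, ]
  edges <- list()
  for (i in seq_len(nrow(truth$objects))) {
    o <- truth$objects[i, ]
    ts <- sort(om$timepoint[om$object == o$object])
    if (length(ts) > 1L) {
      for (j in seq_len(length(ts) - 1L)) {
        a <- node_of(o$object, ts[j]); b <- node_of(o$object, ts[j + 1L])
        edges[[length(edges) + 1L]] <-
          data.frame(from_t = a$timepoint, from_k = a$label,
                     to_t = b$timepoint, to_k = b$label, semantics = "link")
      }
    }
    pids <- c(o$parent1, o$parent2)
    pids <- pids[pids > 0L]
    for (p in pids) {
      a <- node_of(p, max(om$timepoint[om$object == p]))
      b <- node_of(o$object, min(om$timepoint[om$object == o$object]))
      edges[[length(edges) + 1L]] <-
        data.frame(from_t = a$timepoint, from_k = a$label,
                   to_t = b$timepoint, to_k = b$label, semantics = "parent")
    }
  }
  tracking_graph(nodes, if (length(edges)) do.call(rbind, edges) else NULL)
}

#' Corrupt a simulated series with segmentation-style errors
#'
#' Emulates upstream segmentation defects: each instance detection is
#' dropped independently with probability `dropout`, and each surviving
#' instance's boundary is eroded or dilated by a random integer radius up to
#' `boundary_noise`. Dilation never bridges two distinct objects into one
#' label (candidate voxels adjacent to another label are not added).
#'
#' @param truth A [simulate_scenario()] result.
#' @param dropout Per-detection removal probability in \[0, 1\].
#' @param boundary_noise Maximum erosion/dilation radius (voxels).
#' @param seed Integer seed (independent of the generator's).
#' @return A list with `frames` (the corrupted perturbed series) and
#'   `removed` (data frame of dropped detections).
#' @export
corrupt_series <- function(truth, dropout = 0, boundary_noise = 0,
                           seed = 1L) {
  stopifnot(inherits(truth, "scenario_truth"), dropout >= 0, dropout <= 1)
  with_seed(seed, {
    frames <- truth$perturbed
    dm <- dim(frames[[1L]]$labels)
    d <- length(dm)
    conn <- default_connectivity(d)
    removed <- list()
    out <- vector("list", length(frames))
    for (t in seq_along(frames)) {
      arr <- frames[[t]]$labels
      masks <- instance_masks(frames[[t]])
      new_arr <- array(0L, dm)
      for (k in names(masks)) {
        if (stats::runif(1) < dropout) {
          removed[[length(removed) + 1L]] <-
            data.frame(timepoint = t, label = as.integer(k))
          next
        }
        m <- masks[[k]]
        if (boundary_noise > 0) {
          r <- sample.int(2L * boundary_noise + 1L, 1L) - boundary_noise - 1L
          if (r < 0) {
            for (j in seq_len(-r)) m <- erode_indices(m, dm)
          } else if (r > 0) {
            others <- setdiff(which(arr > 0L), masks[[k]])
            forbid <- unique(c(others, grow_indices(others, dm)))
            for (j in seq_len(r)) {
              m <- union(m, setdiff(setdiff(grow_indices(m, dm), forbid),
                                    m))
            }
          }
        }
        new_arr[m] <- as.integer(k)
      }
      out[[t]] <- labeled_frame(new_arr, t)
    }
    list(frames = out,
         removed = if (length(removed)) do.call(rbind, removed) else
           data.frame(timepoint = integer(0), label = integer(0)))
  })
}

## full-neighbourhood expansion of a voxel index set
grow_indices <- function(idx, dm) {
  if (!length(idx)) return(integer(0))
  d <- length(dm)
  co <- arrayInd(idx, dm)
  offs <- half_neighbourhood(d)
  offs <- rbind(offs, -offs)
  res <- idx
  for (i in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[i, ], nrow(co), d, byrow = TRUE)
    ok <- rep(TRUE, nrow(nb))
    for (j in seq_len(d)) ok <- ok & nb[, j] >= 1L & nb[, j] <= dm[j]
    res <- c(res, linear_index(nb[ok, , drop = FALSE], dm))
  }
  sort(unique(res))
}

erode_indices <- function(idx, dm) {
  if (!length(idx)) return(integer(0))
  d <- length(dm)
  inside <- array(FALSE, dm)
  inside[idx] <- TRUE
  co <- arrayInd(idx, dm)
  offs <- half_neighbourhood(d)
  offs <- rbind(offs, -offs)
  keep <- rep(TRUE, length(idx))
  for (i in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[i, ], nrow(co), d, byrow = TRUE)
    ok <- rep(TRUE, length(idx))
    for (j in seq_len(d)) ok <- ok & nb[, j] >= 1L & nb[, j] <= dm[j]
    nbin <- rep(FALSE, length(idx))
    nbin[ok] <- inside[linear_index(nb[ok, , drop = FALSE], dm)]
    keep <- keep & nbin  # boundary voxels (incl. image border) are eroded
  }
  idx[keep]
}
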