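## Evaluation metrics: lineage reconstruction (LNR) with Hungarian matching
## under an IoU cost, and TRA as normalized acyclic oriented graph matching
## (AOGM) cost.

## Kuhn-Munkres / Jonker-style O(n^3) solver for the square linear
## assignment problem (minimization). Returns, for each row, the assigned
## column. Column n+1 acts as the virtual root of the augmenting path.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) ans[p[j]] <- j
  ans
}

## coerce the accepted representations of "partition of instances into
## lineages" to a data.frame(timepoint, label, lineage)
as_lineage_partition <- function(x) {
  if (inherits(x, "moltrack")) x <- x$projected$lineage_map
  if (inherits(x, "lineage_assignment")) x <- x$mapping
  if (inherits(x, "scenario_truth")) x <- x$lineage_map
  if (!is.data.frame(x) ||
      !all(c("timepoint", "label", "lineage") %in% names(x))) {
    stop("expected a data.frame with columns timepoint, label, lineage",
         call. = FALSE)
  }
  x[order(x$timepoint, x$label), c("timepoint", "label", "lineage")]
}

#' Match predicted to ground-truth lineages
#'
#' One-to-one matching between ground-truth and predicted lineages that
#' maximizes the summed IoU of their instance sets (Hungarian algorithm on
#' cost 1 - IoU, with dummy padding when the lineage counts differ). Pairs
#' whose IoU is zero are discarded as unmatched rather than credited as
#' arbitrary pairings.
#'
#' @param gt,pred Lineage partitions over the *same* instance universe: a
#'   data frame with columns `timepoint`, `label`, `lineage`, or a
#'   [moltrack()] fit / `lineage_assignment` / `scenario_truth`.
#' @return A list with `matches` (`gt_lineage`, `pred_lineage`, `iou`),
#'   `unmatched_gt` and `unmatched_pred` lineage IDs.
#' @export
match_lineages <- function(gt, pred) {
  gt <- as_lineage_partition(gt)
  pred <- as_lineage_partition(pred)
  gkey <- paste(gt$timepoint, gt$label)
  pkey <- paste(pred$timepoint, pred$label)
  if (!identical(sort(gkey), sort(pkey)) || anyDuplicated(gkey)) {
    stop("gt and pred must partition the same instance universe",
         call. = FALSE)
  }
  gl <- split(gkey, gt$lineage)
  pl <- split(pkey, pred$lineage)
  ng <- length(gl); np <- length(pl)
  iou <- matrix(0, ng, np)
  for (a in seq_len(ng)) {
    for (b in seq_len(np)) {
      inter <- length(intersect(gl[[a]], pl[[b]]))
      if (inter) {
        iou[a, b] <- inter / (length(gl[[a]]) + length(pl[[b]]) - inter)
      }
    }
  }
  n <- max(ng, np)
  cost <- matrix(1, n, n)
  cost[seq_len(ng), seq_len(np)] <- 1 - iou
  assign <- solve_assignment(cost)
  rows <- list()
  for (a in seq_len(ng)) {
    b <- assign[a]
    if (b <= np && iou[a, b] > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        gt_lineage = as.integer(names(gl)[a]),
        pred_lineage = as.integer(names(pl)[b]),
        iou = iou[a, b])
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gt_lineage = integer(0), pred_lineage = integer(0),
               iou = numeric(0))
  list(matches = matches,
       unmatched_gt = setdiff(as.integer(names(gl)), matches$gt_lineage),
       unmatched_pred = setdiff(as.integer(names(pl)), matches$pred_lineage))
}

#' Lineage reconstruction score (LNR)
#'
#' After Hungarian matching of lineages ([match_lineages()]), the score is
#'
#' \deqn{LNR = \max\left(0,\ 1 - \frac{N_{unmatched} + N_{misassigned}}
#'   {|L_{gt}| + N_{instances}}\right)}
#'
#' where `N_unmatched` counts lineages left unmatched on either side,
#' `N_misassigned` counts instances whose predicted lineage is not the match
#' of their ground-truth lineage (instances of entirely unmatched lineages
#' included), and the denominator is the maximal number of corrections
#' needed to rebuild the ground-truth lineage forest from scratch. 1 is
#' perfect reconstruction; the max() clamps degenerate predictions at 0.
#'
#' @inheritParams match_lineages
#' @return An object of class `lnr_report`: `score`, `n_unmatched`,
#'   `n_misassigned`, `n_gt_lineages`, `n_instances`, `matching`.
#' @export
lnr <- function(gt, pred) {
  gt <- as_lineage_partition(gt)
  pred <- as_lineage_partition(pred)
  m <- match_lineages(gt, pred)
  key <- paste(gt$timepoint, gt$label)
  pred_of <- stats::setNames(pred$lineage, paste(pred$timepoint, pred$label))
  matched_pred <- stats::setNames(m$matches$pred_lineage, m$matches$gt_lineage)
  expected <- matched_pred[as.character(gt$lineage)]  # NA for unmatched gt
  mis <- is.na(expected) | pred_of[key] != expected
  n_unmatched <- length(m$unmatched_gt) + length(m$unmatched_pred)
  n_mis <- sum(mis)
  n_gt <- length(unique(gt$lineage))
  n_inst <- nrow(gt)
  structure(list(
    score = max(0, 1 - (n_unmatched + n_mis) / (n_gt + n_inst)),
    n_unmatched = n_unmatched, n_misassigned = n_mis,
    n_gt_lineages = n_gt, n_instances = n_inst, matching = m
  ), class = "lnr_report")
}

#' @export
print.lnr_report <- function(x, ...) {
  cat(sprintf(
    "LNR = %.4f  (unmatched lineages: %d, misassigned instances: %d, |L_gt| = %d, N = %d)\n",
    x$score, x$n_unmatched, x$n_misassigned, x$n_gt_lineages, x$n_instances))
  invisible(x)
}

## ---- tracking graphs and AOGM/TRA ------------------------------------------

#' Acyclic oriented tracking graph
#'
#' The graph representation both tracking results and ground truth are
#' compared in: one node per detected instance `(timepoint, label)`, with
#' directed edges forward in time. Edge semantics distinguish `"link"`
#' (same tracked object continuing) from `"parent"` (division/fusion
#' parentage).
#'
#' @param nodes Data frame with columns `timepoint`, `label`, optionally a
#'   list column `voxels` (linear voxel indices, used for detection
#'   matching) and `track`.
#' @param edges Data frame with columns `from_t`, `from_k`, `to_t`, `to_k`
#'   and optionally `semantics` (`"link"`/`"parent"`, default `"link"`).
#' @return An object of class `tracking_graph`.
#' @export
tracking_graph <- function(nodes, edges = NULL) {
  stopifnot(all(c("timepoint", "label") %in% names(nodes)))
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(from_t = integer(0), from_k = integer(0),
                        to_t = integer(0), to_k = integer(0),
                        semantics = character(0))
  }
  if (is.null(edges$semantics)) edges$semantics <- "link"
  if (any(edges$to_t <= edges$from_t)) {
    stop("tracking graph must be acyclic: every edge must go strictly forward in time",
         call. = FALSE)
  }
  nkey <- paste(nodes$timepoint, nodes$label)
  if (anyDuplicated(nkey)) stop("duplicate nodes", call. = FALSE)
  bad <- !(paste(edges$from_t, edges$from_k) %in% nkey) |
    !(paste(edges$to_t, edges$to_k) %in% nkey)
  if (any(bad)) stop("edge references unknown node", call. = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "tracking_graph")
}

#' @export
print.tracking_graph <- function(x, ...) {
  cat(sprintf("<tracking_graph> %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a tracking result to a tracking graph
#'
#' @param fit A [moltrack()] result.
#' @return A [tracking_graph()] with instance voxel masks (native space)
#'   attached and edge semantics derived from tracked IDs (`"link"` within
#'   a track, `"parent"` across an event).
#' @export
as_tracking_graph <- function(fit) {
  stopifnot(inherits(fit, "moltrack"))
  tmap <- fit$projected$track_map
  masks <- lapply(fit$frames, instance_masks)
  nodes <- tmap[c("timepoint", "label", "track")]
  nodes$voxels <- lapply(seq_len(nrow(nodes)), function(i) {
    masks[[nodes$timepoint[i]]][[as.character(nodes$label[i])]]
  })
  e <- do.call(rbind, lapply(fit$lineage_graphs, `[[`, "edges"))
  if (is.null(e)) e <- data.frame(from_t = integer(0), from_k = integer(0),
                                  to_t = integer(0), to_k = integer(0))
  track_of <- stats::setNames(tmap$track, paste(tmap$timepoint, tmap$label))
  if (nrow(e)) {
    e$semantics <- ifelse(
      track_of[paste(e$from_t, e$from_k)] == track_of[paste(e$to_t, e$to_k)],
      "link", "parent")
  }
  tracking_graph(nodes, e[, setdiff(names(e), c("iou", "inter")),
                          drop = FALSE])
}

#' TRA score via acyclic oriented graph matching (AOGM)
#'
#' Computes the weighted operation cost of transforming the predicted graph
#' into the reference graph — node splits (NS), false-negative (FN) and
#' false-positive (FP) vertices, redundant (ED), missing (EA) and
#' wrongly-labeled (EC) edges — and normalizes it by the cost
#' \eqn{AOGM_0} of building the reference graph from an empty prediction:
#'
#' \deqn{TRA = 1 - \min(AOGM, AOGM_0) / AOGM_0}
#'
#' Detection correspondence uses the standard majority rule: a predicted
#' node matches a reference node at the same timepoint when it covers more
#' than half of the reference node's voxels (so each reference node has at
#' most one matcher, while one predicted node may absorb several reference
#' nodes, each absorption beyond the first costing one NS operation). When
#' either graph carries no voxel masks, nodes are matched by identical
#' `(timepoint, label)` instead.
#'
#' @param gt,pred [tracking_graph()]s (or [moltrack()] fits for `pred`).
#' @param weights Named operation weights; the defaults are the Cell
#'   Tracking Challenge convention.
#' @param variant `"full"` scores vertex and edge operations; `"edges"` is
#'   the detection-fixed variant scoring only edge operations.
#' @return An object of class `aogm_tra`: `tra`, `aogm`, `aogm_0`, `ops`
#'   (operation counts), `weights`, `variant`.
#' @export
aogm_tra <- function(gt, pred,
                     weights = c(NS = 5, FN = 10, FP = 1, ED = 1, EA = 1.5,
                                 EC = 1),
                     variant = c("full", "edges")) {
  variant <- match.arg(variant)
  if (inherits(gt, "moltrack")) gt <- as_tracking_graph(gt)
  if (inherits(pred, "moltrack")) pred <- as_tracking_graph(pred)
  stopifnot(inherits(gt, "tracking_graph"), inherits(pred, "tracking_graph"))
  w <- weights[c("NS", "FN", "FP", "ED", "EA", "EC")]
  gk <- paste(gt$nodes$timepoint, gt$nodes$label)
  pk <- paste(pred$nodes$timepoint, pred$nodes$label)
  have_voxels <- !is.null(gt$nodes$voxels) && !is.null(pred$nodes$voxels)
  match_of <- stats::setNames(rep(NA_character_, length(gk)), gk)
  if (have_voxels) {
    for (i in seq_along(gk)) {
      t <- gt$nodes$timepoint[i]
      gv <- gt$nodes$voxels[[i]]
      cand <- which(pred$nodes$timepoint == t)
      for (j in cand) {
        if (length(intersect(gv, pred$nodes$voxels[[j]])) > length(gv) / 2) {
          match_of[i] <- pk[j]
          break
        }
      }
    }
  } else {
    match_of[gk %in% pk] <- gk[gk %in% pk]
  }
  n_matched_per_pred <- table(match_of[!is.na(match_of)])
  FN <- sum(is.na(match_of))
  FP <- sum(!pk %in% names(n_matched_per_pred))
  NS <- sum(pmax(as.integer(n_matched_per_pred) - 1L, 0L))
  ## edges: reference edges mapped through the matching
  ekey <- function(e, from, to) {
    if (!nrow(e)) return(character(0))
    paste(e[[from[1]]], e[[from[2]]], "->", e[[to[1]]], e[[to[2]]])
  }
  ge <- gt$edges; pe <- pred$edges
  pred_ekey <- ekey(pe, c("from_t", "from_k"), c("to_t", "to_k"))
  pred_sem <- stats::setNames(pe$semantics, pred_ekey)
  EA <- 0L; EC <- 0L
  corresponding <- character(0)
  if (nrow(ge)) {
    for (i in seq_len(nrow(ge))) {
      a <- match_of[[paste(ge$from_t[i], ge$from_k[i])]]
      b <- match_of[[paste(ge$to_t[i], ge$to_k[i])]]
      if (is.na(a) || is.na(b)) { EA <- EA + 1L; next }
      key <- paste(a, "->", b)
      if (!key %in% pred_ekey) { EA <- EA + 1L; next }
      corresponding <- c(corresponding, key)
      if (pred_sem[[key]] != ge$semantics[i]) EC <- EC + 1L
    }
  }
  ED <- sum(!pred_ekey %in% corresponding)
  ops <- c(NS = NS, FN = FN, FP = FP, ED = ED, EA = EA, EC = EC)
  if (variant == "edges") {
    aogm <- sum(w[c("ED", "EA", "EC")] * ops[c("ED", "EA", "EC")])
    aogm0 <- w[["EA"]] * nrow(ge)
  } else {
    aogm <- sum(w * ops)
    aogm0 <- w[["FN"]] * length(gk) + w[["EA"]] * nrow(ge)
  }
  tra <- if (aogm0 == 0) as.numeric(aogm == 0) else 1 - min(aogm, aogm0) / aogm0
  structure(list(tra = tra, aogm = unname(aogm), aogm_0 = unname(aogm0),
                 ops = ops, weights = w, variant = variant),
            class = "aogm_tra")
}

#' @export
print.aogm_tra <- function(x, ...) {
  cat(sprintf("TRA = %.4f  (AOGM = %g, AOGM_0 = %g; %s)\n",
              x$tra, x$aogm, x$aogm_0,
              paste(sprintf("%s=%d", names(x$ops), x$ops), collapse = " ")))
  invisible(x)
}
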