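# Independent oracles and fixture builders used across the suite.
# These reimplement the checked operations by different means (BFS flood
# fill, explicit union-find, exhaustive enumeration) and stay independent
# of the package internals they verify.

# Brute-force flood fill over the full 8-/26-neighbourhood; labels in the
# order seeds are encountered in linear scan order.
flood_fill_labels <- function(x) {
  dm <- dim(x)
  d <- length(dm)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1L:1L), d)))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  out <- array(0L, dm)
  lab <- 0L
  for (start in which(x != 0)) {
    if (out[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    out[start] <- lab
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      co <- arrayInd(cur, dm)
      for (i in seq_len(nrow(offs))) {
        nb <- co + offs[i, ]
        if (any(nb < 1L) || any(nb > dm)) next
        lin <- nb[1L]
        mult <- 1L
        for (j in seq_along(dm)[-1L]) {
          mult <- mult * dm[j - 1L]
          lin <- lin + (nb[j] - 1L) * mult
        }
        if (x[lin] != 0 && out[lin] == 0L) {
          out[lin] <- lab
          queue <- c(queue, lin)
        }
      }
    }
  }
  out
}

# Plain union-find over arbitrary string node ids.
uf_groups <- function(edges_a, edges_b) {
  nodes <- unique(c(edges_a, edges_b))
  parent <- stats::setNames(nodes, nodes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  for (j in seq_along(edges_a)) {
    parent[[find(edges_a[j])]] <- find(edges_b[j])
  }
  vapply(nodes, find, "")
}

# Exhaustive minimal-cost assignment by permutation enumeration (n <= 7).
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  min(vapply(perms(seq_len(n)), function(p) {
    sum(cost[cbind(seq_len(n), p)])
  }, 0))
}

# Exhaustive LNR evaluation: enumerate every one-to-one lineage matching,
# keep the one maximizing summed IoU, discard zero-IoU pairs, then apply
# the correction-count formula directly.
brute_lnr <- function(gt, pred) {
  gkey <- paste(gt$timepoint, gt$label)
  gl <- split(gkey, gt$lineage)
  pl <- split(paste(pred$timepoint, pred$label), pred$lineage)
  ng <- length(gl)
  np <- length(pl)
  iou <- function(a, b) {
    i <- length(intersect(a, b))
    if (i == 0) 0 else i / (length(a) + length(b) - i)
  }
  subsets_perms <- function(from, k) {
    # all injective maps of 1..k into 'from'
    if (k == 0L) return(list(integer(0)))
    do.call(c, lapply(seq_along(from), function(i) {
      lapply(subsets_perms(from[-i], k - 1L), function(rest) c(from[i], rest))
    }))
  }
  k <- min(ng, np)
  best <- NULL
  best_sum <- -1
  for (rows in utils::combn(ng, k, simplify = FALSE)) {
    for (cols in subsets_perms(seq_len(np), k)) {
      s <- sum(vapply(seq_len(k), function(i) iou(gl[[rows[i]]],
                                                  pl[[cols[i]]]), 0))
      if (s > best_sum) {
        best_sum <- s
        best <- cbind(rows, cols)
      }
    }
  }
  keep <- vapply(seq_len(nrow(best)), function(i) {
    iou(gl[[best[i, 1L]]], pl[[best[i, 2L]]]) > 0
  }, TRUE)
  best <- best[keep, , drop = FALSE]
  n_unmatched <- (ng - nrow(best)) + (np - nrow(best))
  match_of <- stats::setNames(rep(NA_integer_, ng), names(gl))
  match_of[names(gl)[best[, 1L]]] <- best[, 2L]
  pred_of <- stats::setNames(pred$lineage, paste(pred$timepoint, pred$label))
  n_mis <- 0L
  for (i in seq_len(nrow(gt))) {
    m <- match_of[[as.character(gt$lineage[i])]]
    plab <- pred_of[[gkey[i]]]
    if (is.na(m) || names(pl)[m] != as.character(plab)) n_mis <- n_mis + 1L
  }
  max(0, 1 - (n_unmatched + n_mis) / (ng + nrow(gt)))
}

# All partitions of n items into at most kmax blocks (restricted growth).
all_partitions <- function(n, kmax) {
  res <- list()
  rec <- function(assign, used) {
    i <- length(assign) + 1L
    if (i > n) {
      res[[length(res) + 1L]] <<- assign
      return()
    }
    for (b in seq_len(min(used + 1L, kmax))) {
      rec(c(assign, b), max(used, b))
    }
  }
  rec(integer(0), 0L)
  res
}

# Random binary image fixture.
random_binary <- function(dm, p = 0.35) {
  array(stats::runif(prod(dm)) < p, dm)
}

# Frame from filled boxes: each element of 'boxes' is a list of per-axis
# ranges; value = its index (or 1 for binary).
box_frame <- function(dm, boxes, binary = TRUE) {
  a <- array(0L, dm)
  for (i in seq_along(boxes)) {
    a[as.vector(do.call(`[`, c(list(array(seq_len(prod(dm)), dm)), boxes[[i]])))] <-
      if (binary) 1L else i
  }
  a
}

# A dumbbell with a one-voxel-wide bridge: fragments under nearest-neighbor
# rotation, reproducing the resampling artifact.
thin_bridge_frame <- function(dm = c(48L, 48L)) {
  a <- array(0L, dm)
  a[20:28, 8:14] <- 1L
  a[20:28, 34:40] <- 1L
  a[24, 15:33] <- 1L
  a
}

rotation2d <- function(deg, dm, scale = 1) {
  th <- deg * pi / 180
  R <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  ctr <- (dm - 1) / 2
  affine_transform(R, ctr - R %*% ctr)
}

# Deterministic small S1 scenario used by several tests.
demo_events <- list(
  list(type = "split", t = 4, object = 1),
  list(type = "merge", t = 5, objects = c(2, 3)),
  list(type = "gap", t = 3, object = 4),
  list(type = "vanish", t = 4, object = 5),
  list(type = "appear", t = 3)
)

demo_truth <- function(seed = 11, jitter = list(translation = 0,
                                                rotation = 0, scale = 0)) {
  simulate_scenario(scenario_spec(
    "S1", shape = c(72L, 72L), n_frames = 6L, n_objects = 8L,
    events = demo_events, jitter = jitter, seed = seed))
}

# Partition / chain-graph fixtures shared by metric tests.
part_df <- function(lineages) {
  data.frame(timepoint = 1L, label = seq_along(lineages),
             lineage = as.integer(lineages))
}

chain_graph <- function(n, label = 1L, semantics = "link") {
  tracking_graph(
    data.frame(timepoint = seq_len(n), label = label),
    if (n > 1) data.frame(from_t = seq_len(n - 1), from_k = label,
                          to_t = 2:n, to_k = label,
                          semantics = semantics) else NULL)
}

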