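reg_from_frames <- function(frames, scenario = "S1") {
  register_series(frames, scenario = scenario, backend = reg_identity())
}

test_that("S1 builds one union map; overlap decides component counts", {
  blob <- box_frame(c(20, 20), list(list(5:9, 5:9)))
  um <- build_union_map(reg_from_frames(list(blob, blob)))
  expect_length(um, 1L)
  expect_equal(um[[1]]$n_components, 1L)
  two <- list(blob, box_frame(c(20, 20), list(list(14:18, 14:18))))
  um2 <- build_union_map(reg_from_frames(two))
  expect_equal(um2[[1]]$n_components, 2L)
  expect_equal(um2[[1]]$frame_span, 1:2)
})

test_that("S2 builds one union map per consecutive pair, each a voxelwise OR", {
  frames <- lapply(0:2, function(t) {
    box_frame(c(24, 24), list(list((5:8) + 2 * t, 5:8)))
  })
  um <- build_union_map(reg_from_frames(frames, "S2"))
  expect_length(um, 2L)
  for (p in 1:2) {
    oracle <- (frames[[p]] > 0) | (frames[[p + 1]] > 0)
    expect_identical(um[[p]]$binary, oracle)
    expect_equal(um[[p]]$frame_span, c(p, p + 1L))
  }
})

test_that("conflict graph edges match exhaustive mask-component intersection", {
  set.seed(13)
  for (rep in 1:50) {
    frames <- lapply(1:3, function(t) {
      identify_instances(random_binary(c(14, 14), p = 0.2))$labels
    })
    reg <- reg_from_frames(frames)
    um <- build_union_map(reg)
    cg <- build_conflict_graph(reg, um)
    # oracle: enumerate every (instance mask) x (component) pair directly
    oracle <- list()
    for (t in 1:3) {
      m <- instance_masks(labeled_frame(frames[[t]], t))
      for (k in names(m)) {
        for (u in seq_len(um[[1]]$n_components)) {
          ov <- sum(um[[1]]$cc[m[[k]]] == u)
          if (ov >= 1) {
            oracle[[length(oracle) + 1L]] <-
              data.frame(timepoint = t, label = as.integer(k),
                         component = u, overlap = ov)
          }
        }
      }
    }
    oracle <- do.call(rbind, oracle)
    got <- cg$edges[order(cg$edges$timepoint, cg$edges$label,
                          cg$edges$component),
                    c("timepoint", "label", "component", "overlap")]
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0L)
    } else {
      oracle <- oracle[order(oracle$timepoint, oracle$label,
                             oracle$component), ]
      rownames(got) <- rownames(oracle) <- NULL
      expect_equal(got, oracle)
    }
  }
})

test_that("min_overlap filters weak edges and creates orphans", {
  a <- box_frame(c(12, 12), list(list(2:3, 2:3)))
  reg <- reg_from_frames(list(a, a))
  um <- build_union_map(reg)
  cg <- build_conflict_graph(reg, um, min_overlap = 5L)
  expect_equal(nrow(cg$edges), 0L)
  expect_equal(nrow(cg$orphans), 2L)
})

test_that("a fragmented instance maps to multiple union ids and one lineage", {
  # frame 1 holds the two end blobs as separate instances; frame 2 holds
  # the bridged dumbbell, whose thin bridge breaks during nearest-neighbor
  # resampling. The fragmented initial ID then touches two union
  # components (the impermissible mapping), and conflict resolution
  # reunites everything into a single lineage.
  ends <- thin_bridge_frame()
  ends[24, 15:33] <- 0L  # drop the bridge -> two instances at t = 1
  dumbbell <- thin_bridge_frame()
  tr <- rotation2d(5, dim(dumbbell), scale = 1.08)
  reg <- register_series(list(ends, dumbbell), scenario = "S1",
                         backend = reg_supplied(list(NULL, tr)))
  expect_gte(max(label_components(reg$registered[[2]]$labels)), 2L)
  um <- build_union_map(reg)
  expect_gte(um[[1]]$n_components, 2L)
  cg <- build_conflict_graph(reg, um)
  e2 <- cg$edges[cg$edges$timepoint == 2, ]
  expect_gte(length(unique(e2$component)), 2L)  # the invalid mapping pattern
  assignment <- resolve_conflicts(cg)
  expect_equal(assignment$n_lineages, 1L)
})

test_that("conflict-free graphs give one lineage per union component", {
  frames <- list(
    box_frame(c(20, 20), list(list(3:6, 3:6), list(13:17, 12:16)),
              binary = FALSE),
    box_frame(c(20, 20), list(list(3:6, 3:6), list(13:17, 12:16)),
              binary = FALSE)
  )
  reg <- reg_from_frames(frames)
  cg <- build_conflict_graph(reg, build_union_map(reg))
  a <- resolve_conflicts(cg)
  expect_equal(a$n_lineages, 2L)
  # deterministic numbering: lineage 1 holds the earliest (t, label)
  expect_equal(a$mapping$lineage[a$mapping$timepoint == 1 &
                                   a$mapping$label == 1], 1L)
})

test_that("the worked conflict structure resolves into two lineages", {
  # two connected groups: {i_{1,2}, i_{1,5}, i_{2,3}, i_{2,1}, i_{3,1}, u_5}
  # and {i_{1,1}, i_{2,2}, i_{3,2}, u_1, u_7} (i_{2,2} split across u_1, u_7)
  edges <- data.frame(
    timepoint = c(1, 1, 2, 2, 3, 1, 2, 2, 3),
    label = c(2, 5, 3, 1, 1, 1, 2, 2, 2),
    pair = 1L,
    component = c(5, 5, 5, 5, 5, 1, 1, 7, 7),
    overlap = 1L
  )
  inst <- unique(edges[c("timepoint", "label")])
  g <- structure(list(edges = edges, instances = inst,
                      orphans = inst[0, ]), class = "conflict_graph")
  a <- resolve_conflicts(g)
  expect_equal(a$n_lineages, 2L)
  m <- a$mapping
  lin_of <- function(t, k) m$lineage[m$timepoint == t & m$label == k]
  expect_equal(lin_of(1, 1), lin_of(2, 2))
  expect_equal(lin_of(1, 1), lin_of(3, 2))
  expect_equal(lin_of(1, 2), lin_of(3, 1))
  expect_false(lin_of(1, 1) == lin_of(1, 2))
})

test_that("conflict resolution agrees with a union-find oracle on random graphs", {
  set.seed(99)
  for (rep in 1:250) {
    n_i <- sample(1:12, 1)
    n_u <- sample(1:8, 1)
    n_e <- sample(1:(2 * (n_i + n_u)), 1)
    it <- sample(1:4, n_i, replace = TRUE)
    ik <- integer(n_i)
    for (t in unique(it)) ik[it == t] <- seq_len(sum(it == t))
    ei <- sample(n_i, n_e, replace = TRUE)
    eu <- sample(n_u, n_e, replace = TRUE)
    edges <- data.frame(timepoint = it[ei], label = ik[ei], pair = 1L,
                        component = eu, overlap = 1L)
    edges <- unique(edges)
    inst <- data.frame(timepoint = it, label = ik)
    g <- structure(list(edges = edges, instances = inst,
                        orphans = inst[0, ]), class = "conflict_graph")
    a <- resolve_conflicts(g)
    oracle <- uf_groups(paste0("i", edges$timepoint, ".", edges$label),
                        paste0("u", edges$component))
    ikeys <- paste0("i", a$mapping$timepoint, ".", a$mapping$label)
    # identical partitions up to relabeling
    pairs <- paste(a$mapping$lineage, oracle[ikeys])
    expect_equal(length(unique(pairs)), a$n_lineages)
    expect_equal(length(unique(oracle[ikeys])), a$n_lineages)
  }
})
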