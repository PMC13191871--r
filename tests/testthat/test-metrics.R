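test_that("the assignment solver matches exhaustive enumeration", {
  set.seed(5)
  for (rep in 1:150) {
    n <- sample(1:6, 1)
    cost <- matrix(stats::runif(n * n), n)
    a <- moltrack:::solve_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]),
                 brute_assignment_cost(cost), tolerance = 1e-12)
  }
})

test_that("lineage matching maximizes summed IoU and discards zero-IoU pairs", {
  # identical partitions: identity matching at IoU 1
  m <- match_lineages(part_df(c(1, 1, 2)), part_df(c(1, 1, 2)))
  expect_equal(m$matches$iou, c(1, 1))
  expect_length(m$unmatched_gt, 0)
  # gt {A:{1,2}, B:{3}}, pred {X:{1}, Y:{2,3}}: both matchings tie at
  # IoU 1/2 + 1/2; the solver must return one of them, never a zero pair
  m2 <- match_lineages(part_df(c(1, 1, 2)), part_df(c(1, 2, 2)))
  expect_equal(nrow(m2$matches), 2L)
  expect_equal(sum(m2$matches$iou), 1)
  # one extra pred lineage stays unmatched
  m3 <- match_lineages(part_df(c(1, 1, 1)), part_df(c(1, 1, 2)))
  expect_equal(nrow(m3$matches), 1L)
  expect_length(m3$unmatched_pred, 1L)
  expect_error(match_lineages(part_df(c(1, 1)), part_df(c(1, 1, 2))),
               "universe")
})

test_that("LNR is exact on canonical cases", {
  expect_equal(lnr(part_df(c(1, 1, 2, 2)), part_df(c(1, 1, 2, 2)))$score, 1)
  # one lineage of 4 vs all singletons: oracle evaluates the formula after
  # exhaustive matching
  gt <- part_df(c(1, 1, 1, 1))
  pred <- part_df(c(1, 2, 3, 4))
  expect_equal(lnr(gt, pred)$score, brute_lnr(gt, pred))
  r <- lnr(gt, pred)
  expect_equal(r$n_unmatched, 3L)  # three surplus singletons
  expect_equal(r$n_misassigned, 3L)
  expect_equal(r$score, max(0, 1 - 6 / 5))
  expect_equal(r$score, 0)  # the clamp case
})

test_that("LNR matches brute force on all small partition pairs", {
  for (n in 2:5) {
    parts <- all_partitions(n, 3L)
    for (g in parts) {
      for (p in parts) {
        gt <- part_df(g)
        pred <- part_df(p)
        expect_equal(lnr(gt, pred)$score, brute_lnr(gt, pred),
                     tolerance = 1e-12,
                     info = sprintf("gt=%s pred=%s", paste(g, collapse = ""),
                                    paste(p, collapse = "")))
      }
    }
  }
  # spot checks at n = 6 (full cross-product is redundant at this size)
  parts6 <- all_partitions(6L, 3L)
  set.seed(8)
  idx <- sample(length(parts6), 12)
  for (i in idx) {
    for (j in sample(length(parts6), 6)) {
      gt <- part_df(parts6[[i]])
      pred <- part_df(parts6[[j]])
      expect_equal(lnr(gt, pred)$score, brute_lnr(gt, pred),
                   tolerance = 1e-12)
    }
  }
})

test_that("LNR is invariant under relabeling and monotone under corruption", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 8
    gt <- part_df(sample(1:3, n, replace = TRUE))
    pred <- gt
    perm <- sample(100, 3)
    pred$lineage <- perm[pred$lineage]
    expect_equal(lnr(gt, pred)$score, 1)
    # corrupt one instance
    pred2 <- pred
    pred2$lineage[1] <- max(pred$lineage) + 1L
    expect_lte(lnr(gt, pred2)$score, 1)
    expect_gte(lnr(gt, pred2)$score, 0)
  }
})

test_that("AOGM operation costs match hand-counted cases", {
  w <- c(NS = 5, FN = 10, FP = 1, ED = 1, EA = 1.5, EC = 1)
  # 1) identical 3-chain: zero cost
  g <- chain_graph(3)
  expect_equal(aogm_tra(g, g)$aogm, 0)
  expect_equal(aogm_tra(g, g)$tra, 1)
  # 2) two nodes, missing link edge: AOGM = EA = 1.5, AOGM_0 = 2*10 + 1.5
  g2 <- chain_graph(2)
  p2 <- tracking_graph(g2$nodes)
  r2 <- aogm_tra(g2, p2)
  expect_equal(r2$aogm, 1.5)
  expect_equal(r2$aogm_0, 21.5)
  expect_equal(r2$tra, 1 - 1.5 / 21.5)
  # 3) missing node in a 3-chain: FN + 2 missing edges = 10 + 3
  g3 <- chain_graph(3)
  p3 <- tracking_graph(g3$nodes[-2, ], NULL)
  r3 <- aogm_tra(g3, p3)
  expect_equal(unname(r3$ops["FN"]), 1L)
  expect_equal(unname(r3$ops["EA"]), 2L)
  expect_equal(r3$aogm, 10 + 2 * 1.5)
  # 4) spurious extra node with a redundant edge: FP + ED = 1 + 1
  g4 <- chain_graph(2)
  p4 <- tracking_graph(rbind(g4$nodes, data.frame(timepoint = 1, label = 9)),
                       rbind(g4$edges,
                             data.frame(from_t = 1, from_k = 9, to_t = 2,
                                        to_k = 1, semantics = "link")))
  r4 <- aogm_tra(g4, p4)
  expect_equal(unname(r4$ops["FP"]), 1L)
  expect_equal(unname(r4$ops["ED"]), 1L)
  expect_equal(r4$aogm, 2)
  # 5) division edge labeled as a plain link: EC = 1
  g5 <- tracking_graph(
    data.frame(timepoint = c(1, 2, 2), label = c(1, 1, 2)),
    data.frame(from_t = c(1, 1), from_k = 1, to_t = 2, to_k = c(1, 2),
               semantics = "parent"))
  p5 <- tracking_graph(
    g5$nodes,
    data.frame(from_t = c(1, 1), from_k = 1, to_t = 2, to_k = c(1, 2),
               semantics = c("parent", "link")))
  r5 <- aogm_tra(g5, p5)
  expect_equal(unname(r5$ops["EC"]), 1L)
  expect_equal(r5$aogm, 1)
  expect_equal(r5$tra, 1 - 1 / (3 * 10 + 2 * 1.5))
})

test_that("TRA clamps at zero for empty predictions", {
  g <- chain_graph(4)
  p <- tracking_graph(data.frame(timepoint = integer(0), label = integer(0)))
  r <- aogm_tra(g, p)
  expect_equal(r$tra, 0)
  expect_gte(r$aogm, r$aogm_0)
})

test_that("voxel-based node matching follows the majority rule and counts NS", {
  # gt: two nodes at t = 1; pred: one node covering both -> 1 NS, no FN
  gt <- tracking_graph(data.frame(timepoint = c(1, 1), label = c(1, 2)))
  gt$nodes$voxels <- list(1:10, 21:30)
  pred <- tracking_graph(data.frame(timepoint = 1, label = 1))
  pred$nodes$voxels <- list(c(1:10, 21:30))
  r <- aogm_tra(gt, pred)
  expect_equal(unname(r$ops["NS"]), 1L)
  expect_equal(unname(r$ops["FN"]), 0L)
  # a pred node covering less than half of the gt node does not match
  g1 <- tracking_graph(data.frame(timepoint = 1, label = 1))
  g1$nodes$voxels <- list(1:10)
  pred2 <- tracking_graph(data.frame(timepoint = 1, label = 1))
  pred2$nodes$voxels <- list(1:4)
  r2 <- aogm_tra(g1, pred2)
  expect_equal(unname(r2$ops["FN"]), 1L)
  expect_equal(unname(r2$ops["FP"]), 1L)
})

test_that("TRA is invariant under relabeling of predicted IDs", {
  truth <- demo_truth()
  fit <- moltrack(truth$perturbed, scenario = "S1",
                  registration = reg_identity())
  pg <- as_tracking_graph(fit)
  pg_relab <- pg
  pg_relab$nodes$track <- pg$nodes$track + 100L
  gt <- truth_tracking_graph(truth)
  expect_equal(aogm_tra(gt, pg)$tra, aogm_tra(gt, pg_relab)$tra)
})

test_that("the detection-fixed variant scores edges only", {
  g <- chain_graph(3)
  p <- tracking_graph(g$nodes, g$edges[-1, ])
  r <- aogm_tra(g, p, variant = "edges")
  expect_equal(r$aogm, 1.5)
  expect_equal(r$aogm_0, 3)
})
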