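test_that("a static object with no events gives identical frames and one track", {
  spec <- scenario_spec("S1", shape = c(32, 32), n_frames = 3, n_objects = 1,
                        radius_jitter = 0, seed = 2)
  truth <- simulate_scenario(spec)
  expect_identical(truth$frames[[1]]$labels, truth$frames[[2]]$labels)
  expect_identical(truth$frames[[1]]$labels, truth$frames[[3]]$labels)
  expect_equal(max(truth$lineage_map$lineage), 1L)
  expect_equal(nrow(truth$track_table), 1L)
  expect_equal(truth$track_table$parent, 0L)
})

test_that("a scheduled split appears as an out-degree-2 node in the truth graph", {
  spec <- scenario_spec("S1", shape = c(48, 48), n_frames = 3, n_objects = 1,
                        events = list(list(type = "split", t = 2,
                                           object = 1)), seed = 4)
  truth <- simulate_scenario(spec)
  g <- truth_tracking_graph(truth)
  out1 <- sum(g$edges$from_t == 1)
  expect_equal(out1, 2L)
  expect_true(all(g$edges$semantics[g$edges$from_t == 1] == "parent"))
  expect_equal(nrow(truth$track_table), 3L)
  expect_equal(sum(truth$track_table$parent > 0), 2L)
})

test_that("generation is bit-reproducible for a fixed seed", {
  a <- demo_truth(seed = 11)
  b <- demo_truth(seed = 11)
  expect_identical(lapply(a$frames, `[[`, "labels"),
                   lapply(b$frames, `[[`, "labels"))
  expect_identical(a$lineage_map, b$lineage_map)
  expect_identical(a$track_table, b$track_table)
  c_ <- demo_truth(seed = 12)
  expect_false(identical(lapply(a$frames, `[[`, "labels"),
                         lapply(c_$frames, `[[`, "labels")))
})

test_that("infeasible schedules are rejected with the offending event named", {
  expect_error(scenario_spec("S1", n_objects = 2, events = list(
    list(type = "split", t = 1, object = 1))), "event 1")
  expect_error(scenario_spec("S1", n_objects = 2, events = list(
    list(type = "split", t = 3, object = 5))), "non-seed")
  expect_error(scenario_spec("S1", n_objects = 2, events = list(
    list(type = "merge", t = 3, objects = c(1, 1)))), "distinct")
  expect_error(scenario_spec("S1", n_objects = 3, events = list(
    list(type = "split", t = 3, object = 1),
    list(type = "vanish", t = 4, object = 1))), "already used")
  expect_error(scenario_spec("S2", n_objects = 3, events = list(
    list(type = "merge", t = 3, objects = c(1, 2)))), "not permissible")
  expect_error(scenario_spec("S1", n_frames = 5, n_objects = 1, events = list(
    list(type = "gap", t = 5, object = 1))), "gap")
})

test_that("blobs stay disjoint and jitter keeps blobs mostly in-field", {
  truth <- demo_truth(jitter = list(translation = 6, rotation = 4,
                                    scale = 0.02))
  for (t in seq_along(truth$frames)) {
    labs <- truth$frames[[t]]$labels
    # every label is a single connected blob
    for (k in unique(labs[labs > 0])) {
      expect_equal(max(label_components(labs == k)), 1L)
    }
    # perturbed frames keep >= 80% of each blob's voxels
    pl <- truth$perturbed[[t]]$labels
    for (k in unique(labs[labs > 0])) {
      expect_gte(sum(pl == k), 0.8 * sum(labs == k))
    }
  }
})

test_that("true inverse transforms undo the jitter up to resampling loss", {
  truth <- demo_truth(jitter = list(translation = 6, rotation = 4,
                                    scale = 0.02))
  for (t in 2:length(truth$frames)) {
    back <- apply_to_labels(truth$perturbed[[t]], truth$true_transforms[[t]])
    clean <- truth$frames[[t]]$labels
    agree <- sum(back$labels == clean & clean > 0)
    expect_gte(agree, 0.7 * sum(clean > 0))
  }
})

test_that("corruption is the identity at zero settings and empties at dropout 1", {
  truth <- demo_truth()
  c0 <- corrupt_series(truth, dropout = 0, boundary_noise = 0, seed = 9)
  expect_identical(lapply(c0$frames, `[[`, "labels"),
                   lapply(truth$perturbed, `[[`, "labels"))
  expect_equal(nrow(c0$removed), 0L)
  c1 <- corrupt_series(truth, dropout = 1, seed = 9)
  expect_true(all(vapply(c1$frames, function(f) all(f$labels == 0L), TRUE)))
})

test_that("dropout is reproducible and binomially plausible", {
  truth <- demo_truth()
  n_inst <- nrow(truth$object_map)
  again <- corrupt_series(truth, dropout = 0.1, seed = 42)
  expect_identical(corrupt_series(truth, dropout = 0.1, seed = 42)$removed,
                   again$removed)
  removed <- vapply(1:50, function(s) {
    nrow(corrupt_series(truth, dropout = 0.1, seed = s)$removed)
  }, 0)
  total <- sum(removed)
  # total ~ Binomial(50 * n_inst, 0.1); allow +-5 sd
  expect_gt(total, 0.1 * 50 * n_inst - 5 * sqrt(50 * n_inst * 0.09))
  expect_lt(total, 0.1 * 50 * n_inst + 5 * sqrt(50 * n_inst * 0.09))
})

test_that("boundary noise never fuses two labels into one region", {
  spec <- scenario_spec("S1", shape = c(48, 48), n_frames = 3, n_objects = 3,
                        min_spacing = 3, seed = 6)
  truth <- simulate_scenario(spec)
  for (s in 1:5) {
    cc <- corrupt_series(truth, boundary_noise = 2, seed = s)
    for (f in cc$frames) {
      labs <- unique(f$labels[f$labels > 0])
      # connected components of the union must be >= number of labels
      expect_gte(max(label_components(f$labels > 0), 0L), length(labs))
    }
  }
})

test_that("the pipeline closes over the generator: perfect scores on clean input", {
  truth <- demo_truth()
  fit <- moltrack(truth$perturbed, scenario = "S1",
                  registration = reg_identity())
  expect_equal(lnr(truth, fit)$score, 1)
  expect_equal(aogm_tra(truth_tracking_graph(truth),
                        as_tracking_graph(fit))$tra, 1)
  expect_equal(summary(fit)$events, truth$event_counts)
})

test_that("an S2 dropout fragments exactly one extra tracklet", {
  # static scene processed as S2; one interior detection removed
  spec <- scenario_spec("S2", shape = c(64, 64), n_frames = 5, n_objects = 4,
                        step_sd = 0, radius_jitter = 0, seed = 13)
  truth <- simulate_scenario(spec)
  fit0 <- moltrack(truth$perturbed, scenario = "S2",
                   registration = reg_identity())
  frames <- lapply(truth$perturbed, function(f) f$labels)
  drop_k <- truth$object_map$label[truth$object_map$timepoint == 3 &
                                     truth$object_map$object == 1]
  frames[[3]][frames[[3]] == drop_k] <- 0L
  fit1 <- moltrack(frames, scenario = "S2", registration = reg_identity())
  n_tracks_obj <- function(fit, obj) {
    om <- truth$object_map[truth$object_map$object == obj, ]
    om <- om[om$timepoint != 3, ]
    keys <- paste(om$timepoint, om$label)
    map <- fit$tracks$mapping
    length(unique(map$track[paste(map$timepoint, map$label) %in% keys]))
  }
  expect_equal(n_tracks_obj(fit1, 1), n_tracks_obj(fit0, 1) + 1L)
})
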