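test_that("self-registration returns (near-)identity", {
  a <- box_frame(c(20, 20), list(list(4:9, 5:11)))
  tr <- estimate_affine(a, a, reg_translation())
  expect_lt(sqrt(sum(tr$translation^2)), 0.5)
  expect_equal(tr$linear, diag(2))
})

test_that("translation estimator recovers integer shifts exactly", {
  # pull convention: content shifted by s needs source coordinate x + s
  fixed <- box_frame(c(24, 24), list(list(4:8, 5:10)))
  shifts <- list(c(5, -3), c(-3, 6), c(0, 7))
  for (s in shifts) {
    moving <- array(0L, dim(fixed))
    moving[(4:8) + s[1], (5:10) + s[2]] <- 1L
    tr <- estimate_affine(moving, fixed, reg_translation())
    expect_equal(as.numeric(tr$translation), s)
    # cross-check with an exhaustive shift-search oracle
    best <- NULL
    best_ov <- -1
    for (dy in -8:8) {
      for (dx in -8:8) {
        shifted <- array(0L, dim(fixed))
        src_y <- (4:8) + s[1] - dy
        src_x <- (5:10) + s[2] - dx
        if (all(src_y >= 1) && all(src_y <= 24) && all(src_x >= 1) &&
            all(src_x <= 24)) {
          shifted[src_y, src_x] <- 1L
        }
        ov <- sum(shifted & fixed)
        if (ov > best_ov) {
          best_ov <- ov
          best <- c(dy, dx)
        }
      }
    }
    expect_equal(as.numeric(tr$translation), best)
    # applying the transform realigns the content exactly
    expect_identical(apply_to_labels(moving, tr)$labels, fixed)
  }
})

test_that("supplied matrices pass through verbatim and externals are contract-checked", {
  tr_in <- affine_transform(matrix(c(1, 0.1, 0, 1), 2), c(2.5, -1),
                            moving_index = 2L, fixed_index = 1L)
  backend <- reg_supplied(list(NULL, tr_in))
  got <- estimate_affine(matrix(0L, 4, 4), matrix(0L, 4, 4), backend,
                         moving_index = 2L, fixed_index = 1L)
  expect_equal(got$linear, tr_in$linear)
  expect_equal(got$translation, tr_in$translation)
  expect_error(
    estimate_affine(matrix(0L, 4, 4), matrix(0L, 4, 4),
                    reg_external("no-such-registration-tool", function(m, f) diag(3)),
                    moving_index = 2L, fixed_index = 1L),
    "no-such-registration-tool")
  # plain-text homogeneous matrix round trip (the adapter interchange format)
  f <- tempfile()
  write_affine_matrix(tr_in, f)
  back <- read_affine_matrix(f)
  expect_equal(back$linear, tr_in$linear)
  expect_equal(back$translation, tr_in$translation)
})

test_that("label resampling conserves label values and identity is exact", {
  a <- box_frame(c(16, 16), list(list(3:6, 3:6), list(10:13, 9:14)),
                 binary = FALSE)
  expect_identical(apply_to_labels(a, identity_transform(2))$labels, a)
  out <- apply_to_labels(a, affine_transform(diag(2), c(4, -2)))
  expect_true(all(unique(as.vector(out$labels)) %in% c(0L, 1L, 2L)))
  # pure integer translation equals an index shift with 0-padding
  oracle <- array(0L, c(16, 16))
  oracle[pmax(1, 1 - 4):(16 - 4), (1 + 2):16] <-
    a[(1 + 4):16, 1:(16 - 2)]
  expect_identical(out$labels, oracle)
  expect_error(apply_to_labels(a, affine_transform(matrix(0, 2, 2), c(0, 0))),
               "singular")
})

test_that("affine resampling fragments a thin bridge while keeping one label value", {
  a <- thin_bridge_frame()
  # small rotation plus slight scale, as a real affine registration returns
  rot <- apply_to_labels(a, rotation2d(5, dim(a), scale = 1.08))
  expect_identical(sort(unique(as.vector(rot$labels))), c(0L, 1L))
  n_cc <- max(label_components(rot$labels))
  expect_gte(n_cc, 2L)  # the resampling artifact conflict resolution fixes
})

test_that("transform then inverse recovers the frame away from boundaries", {
  a <- box_frame(c(30, 30), list(list(10:20, 8:22)))
  tr <- rotation2d(9, dim(a))
  back <- apply_to_labels(apply_to_labels(a, tr), invert_transform(tr))
  interior <- array(FALSE, dim(a))
  interior[12:18, 10:20] <- TRUE  # > 1 voxel from the label boundary
  expect_identical(back$labels[interior], a[interior])
})

test_that("register_series aligns S1 shifts and recovers S2 steps", {
  f1 <- box_frame(c(26, 26), list(list(8:12, 8:12)))
  shifts <- list(c(0, 0), c(3, -2), c(-4, 5))
  frames <- lapply(seq_along(shifts), function(t) {
    a <- array(0L, c(26, 26))
    a[(8:12) + shifts[[t]][1], (8:12) + shifts[[t]][2]] <- 1L
    a
  })
  reg <- register_series(frames, scenario = "S1",
                         backend = reg_translation())
  expect_true(is_id <- max(abs(reg$transforms[[1]]$translation)) == 0)
  for (t in 2:3) {
    expect_identical(reg$registered[[t]]$labels, frames[[1]])
  }
  # S2: a blob moving 2 voxels per frame; each pairwise transform recovers
  # the per-step displacement
  frames2 <- lapply(0:3, function(t) {
    a <- array(0L, c(30, 30))
    a[(5:9) + 2 * t, 10:14] <- 1L
    a
  })
  reg2 <- register_series(frames2, scenario = "S2",
                          backend = reg_translation())
  for (t in 2:4) {
    expect_equal(as.numeric(reg2$transforms[[t]]$translation), c(2, 0))
  }
  expect_error(register_series(frames2, raw = list(1, 2), scenario = "S2"),
               "length")
  single <- register_series(frames2[1], scenario = "S1")
  expect_length(single$transforms, 1L)
  expect_equal(single$transforms[[1]]$linear, diag(2))
})

test_that("shape mismatches and empty-frame fallback are handled", {
  expect_error(estimate_affine(matrix(0L, 4, 4), matrix(0L, 5, 5)),
               "shape")
  expect_warning(
    tr <- estimate_affine(matrix(0L, 6, 6), box_frame(c(6, 6),
                                                      list(list(2:3, 2:3))),
                          reg_translation()),
    "identity")
  expect_equal(tr$translation, c(0, 0))
})
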