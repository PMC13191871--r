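#' Affine transform between two frames
#'
#' Transforms use the pull (resampling) convention: for an output voxel at
#' 0-based coordinate `x` in the fixed frame's grid, the sampled source
#' coordinate in the moving frame is `linear %*% x + translation`. Voxel
#' coordinates follow the array's native (column-major) axis order and are
#' 0-based; translations are in voxel units.
#'
#' @param linear d x d invertible matrix.
#' @param translation length-d numeric vector.
#' @param moving_index timepoint of the moving frame.
#' @param fixed_index timepoint of the fixed (target) frame.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(linear, translation,
                             moving_index = NA_integer_,
                             fixed_index = NA_integer_) {
  linear <- as.matrix(linear)
  d <- nrow(linear)
  if (ncol(linear) != d) stop("'linear' must be square", call. = FALSE)
  if (length(translation) != d) {
    stop("'translation' length must match 'linear' dimension", call. = FALSE)
  }
  if (abs(det(linear)) < .Machine$double.eps * 10) {
    stop("singular 'linear' matrix: affine transform must be invertible",
         call. = FALSE)
  }
  structure(
    list(linear = linear, translation = as.numeric(translation),
         moving_index = as.integer(moving_index),
         fixed_index = as.integer(fixed_index)),
    class = "affine_transform"
  )
}

#' @rdname affine_transform
#' @param d Dimensionality (2 or 3).
#' @export
identity_transform <- function(d, moving_index = NA_integer_,
                               fixed_index = NA_integer_) {
  affine_transform(diag(d), numeric(d), moving_index, fixed_index)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> t=%s -> t=%s\n",
              x$moving_index, x$fixed_index))
  print(cbind(x$linear, x$translation))
  invisible(x)
}

is_identity_transform <- function(tr, tol = 1e-12) {
  d <- nrow(tr$linear)
  max(abs(tr$linear - diag(d))) < tol && max(abs(tr$translation)) < tol
}

#' Invert an affine transform
#'
#' Swaps the roles of moving and fixed frame: if `x` maps fixed coordinates
#' to moving coordinates, `invert_transform(x)` maps moving to fixed.
#'
#' @param transform An [affine_transform()].
#' @export
invert_transform <- function(transform) {
  Li <- solve(transform$linear)
  affine_transform(Li, -Li %*% transform$translation,
                   moving_index = transform$fixed_index,
                   fixed_index = transform$moving_index)
}

compose_transforms <- function(outer, inner) {
  ## apply 'inner' first, then 'outer' (both pull maps): x -> inner(outer(x))
  ## source = L_i (L_o x + b_o) + b_i
  affine_transform(inner$linear %*% outer$linear,
                   inner$linear %*% outer$translation + inner$translation)
}

#' Resample a label frame through an affine transform
#'
#' Applies a pull-convention affine transform with nearest-neighbor
#' interpolation, the only interpolation admissible for label images: every
#' output value is one of the input label values or 0, never an invented
#' blend. Voxels whose source coordinate falls outside the image domain
#' become background. Note that nearest-neighbor resampling of a rotated
#' frame can break thin structures into several connected components while
#' they keep a single label value — the conflict-resolution stage of
#' [moltrack()] exists to repair exactly this artifact.
#'
#' @param frame A [labeled_frame()] (or bare array).
#' @param transform An [affine_transform()] of matching dimensionality.
#' @return A `labeled_frame` on the same grid.
#' @export
apply_to_labels <- function(frame, transform) {
  frame <- as_labeled_frame(frame)
  d <- frame$dimensionality
  if (nrow(transform$linear) != d) {
    stop("transform dimensionality does not match frame", call. = FALSE)
  }
  if (is_identity_transform(transform)) {
    return(labeled_frame(frame$labels, frame$timepoint))
  }
  dm <- dim(frame$labels)
  coords <- arrayInd(seq_len(prod(dm)), dm) - 1L       # 0-based, n x d
  src <- coords %*% t(transform$linear) +
    matrix(transform$translation, nrow(coords), d, byrow = TRUE)
  src <- round(src) + 1L                               # nearest neighbor
  ok <- rep(TRUE, nrow(src))
  for (j in seq_len(d)) ok <- ok & src[, j] >= 1L & src[, j] <= dm[j]
  out <- array(0L, dm)
  out[ok] <- frame$labels[linear_index(src[ok, , drop = FALSE], dm)]
  labeled_frame(out, frame$timepoint)
}

## ---- registration backends -------------------------------------------------

#' Registration backends
#'
#' A backend estimates the affine transform aligning a moving frame to a
#' fixed frame. Four backends are provided:
#'
#' * `reg_identity()` — returns the identity; use when the series is already
#'   aligned.
#' * `reg_translation()` — built-in integer-translation estimator using
#'   discrete (FFT) cross-correlation of the binarized frames; dependency
#'   free and exact for pure integer shifts.
#' * `reg_supplied(transforms)` — passthrough of user-supplied
#'   [affine_transform()]s (e.g. computed by any external registration tool
#'   or known ground truth); `transforms` is a list indexed by moving
#'   timepoint.
#' * `reg_external(command, fn)` — adapter contract for an external affine
#'   registration executable working on raw images. `fn(moving, fixed)` must
#'   run the tool and return a d+1 square homogeneous matrix (see
#'   [read_affine_matrix()]); `command` is checked on `PATH` first and a
#'   configuration error naming the backend is raised when missing.
#'
#' If a backend fails on a frame pair, [estimate_affine()] falls back to the
#' identity transform with a warning rather than aborting the series.
#'
#' @param transforms List of [affine_transform()], indexed by moving
#'   timepoint.
#' @param command Name of the external executable.
#' @param fn Function `(moving_array, fixed_array) -> (d+1) x (d+1)`
#'   homogeneous matrix (pull convention, voxel units).
#' @name registration_backends
NULL

#' @rdname registration_backends
#' @export
reg_identity <- function() structure(list(type = "identity"),
                                     class = "reg_backend")

#' @rdname registration_backends
#' @export
reg_translation <- function() structure(list(type = "translation"),
                                        class = "reg_backend")

#' @rdname registration_backends
#' @export
reg_supplied <- function(transforms) {
  stopifnot(is.list(transforms))
  structure(list(type = "supplied", transforms = transforms),
            class = "reg_backend")
}

#' @rdname registration_backends
#' @export
reg_external <- function(command, fn) {
  stopifnot(is.function(fn))
  structure(list(type = "external", command = command, fn = fn),
            class = "reg_backend")
}

as_reg_backend <- function(x) {
  if (inherits(x, "reg_backend")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(switch(x,
      identity = reg_identity(),
      translation = reg_translation(),
      stop(sprintf("unknown registration backend '%s'", x), call. = FALSE)))
  }
  stop("'registration' must be a reg_* backend or backend name",
       call. = FALSE)
}

## signed circular shift from an FFT cross-correlation peak
xcorr_shift <- function(moving, fixed) {
  dm <- dim(fixed)
  A <- array(as.numeric(fixed != 0), dm)
  B <- array(as.numeric(moving != 0), dm)
  if (!any(A != 0) || !any(B != 0)) {
    stop("cannot cross-correlate an empty frame", call. = FALSE)
  }
  cc <- Re(stats::fft(stats::fft(B) * Conj(stats::fft(A)), inverse = TRUE))
  peak <- arrayInd(which.max(cc), dm) - 1L
  ifelse(peak > dm / 2, peak - dm, peak)
}

#' Estimate the affine transform aligning two frames
#'
#' @param moving,fixed Arrays or [labeled_frame()]s of identical shape; raw
#'   intensity or (binarized) label content, whichever the backend expects.
#' @param backend A backend from [registration_backends].
#' @param moving_index,fixed_index Timepoints recorded on the result (and
#'   used by `reg_supplied` to look up its transform).
#' @return An [affine_transform()] mapping fixed-frame voxel coordinates to
#'   moving-frame coordinates (pull convention).
#' @export
estimate_affine <- function(moving, fixed, backend = reg_translation(),
                            moving_index = NA_integer_,
                            fixed_index = NA_integer_) {
  backend <- as_reg_backend(backend)
  marr <- if (inherits(moving, "labeled_frame")) moving$labels else moving
  farr <- if (inherits(fixed, "labeled_frame")) fixed$labels else fixed
  if (!identical(dim(marr), dim(farr))) {
    stop("moving and fixed frames differ in shape", call. = FALSE)
  }
  d <- length(dim(farr))
  tr <- switch(backend$type,
    identity = identity_transform(d),
    translation = tryCatch({
      s <- xcorr_shift(marr, farr)
      affine_transform(diag(d), s)
    }, error = function(e) {
      warning(sprintf("translation backend failed (%s); using identity",
                      conditionMessage(e)), call. = FALSE)
      identity_transform(d)
    }),
    supplied = {
      tr <- backend$transforms[[moving_index]]
      if (is.null(tr)) {
        stop(sprintf("no supplied transform for moving timepoint %d",
                     moving_index), call. = FALSE)
      }
      tr
    },
    external = {
      if (!nzchar(Sys.which(backend$command))) {
        stop(sprintf(
          "registration backend 'external': executable '%s' not found on PATH",
          backend$command), call. = FALSE)
      }
      tryCatch({
        H <- backend$fn(marr, farr)
        homogeneous_to_transform(H)
      }, error = function(e) {
        warning(sprintf("external backend failed (%s); using identity",
                        conditionMessage(e)), call. = FALSE)
        identity_transform(d)
      })
    },
    stop("unknown backend type", call. = FALSE))
  tr$moving_index <- as.integer(moving_index)
  tr$fixed_index <- as.integer(fixed_index)
  tr
}

homogeneous_to_transform <- function(H) {
  H <- as.matrix(H)
  d <- nrow(H) - 1L
  affine_transform(H[seq_len(d), seq_len(d), drop = FALSE], H[seq_len(d), d + 1L])
}

transform_to_homogeneous <- function(tr) {
  d <- nrow(tr$linear)
  H <- diag(d + 1L)
  H[seq_len(d), seq_len(d)] <- tr$linear
  H[seq_len(d), d + 1L] <- tr$translation
  H
}

#' Read / write plain-text homogeneous affine matrices
#'
#' A transform is stored as a (d+1) x (d+1) homogeneous matrix, one
#' whitespace-separated row per line — the interchange format used by
#' command-line registration tools.
#'
#' @param file Path to the matrix file.
#' @export
read_affine_matrix <- function(file) {
  H <- as.matrix(utils::read.table(file))
  dimnames(H) <- NULL
  homogeneous_to_transform(H)
}

#' @rdname read_affine_matrix
#' @param transform An [affine_transform()].
#' @export
write_affine_matrix <- function(transform, file) {
  utils::write.table(transform_to_homogeneous(transform), file,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

## ---- series registration ---------------------------------------------------

#' Register a label series
#'
#' Aligns every frame of the series. Under scenario `"S1"` each frame is
#' registered directly to the reference frame (default: the first), putting
#' the whole series into one common space; under `"S2"` each frame is
#' registered to its immediate predecessor, and the pairwise transforms are
#' deliberately never composed into a global space (independently moving
#' objects from different times could otherwise collide in the union map).
#' When raw intensity frames are provided the transform is estimated on
#' those; otherwise on the binarized labels. Labels themselves are always
#' resampled with nearest-neighbor interpolation.
#'
#' @param frames List of [labeled_frame()]s (or arrays), timepoints 1..T.
#' @param raw Optional parallel list of raw intensity arrays.
#' @param scenario `"S1"` or `"S2"`.
#' @param backend A backend from [registration_backends].
#' @param reference 1-based reference timepoint (S1 only).
#' @return An object of class `registered_series`: `original` and
#'   `registered` frame lists, `transforms`, `scenario`, `reference`.
#' @export
register_series <- function(frames, raw = NULL, scenario = c("S1", "S2"),
                            backend = reg_translation(), reference = 1L) {
  scenario <- match.arg(scenario)
  frames <- check_series(frames)
  T_ <- length(frames)
  if (!is.null(raw) && length(raw) != T_) {
    stop(sprintf("raw series length (%d) does not match labels (%d)",
                 length(raw), T_), call. = FALSE)
  }
  reference <- as.integer(reference)
  if (scenario == "S1" && (reference < 1L || reference > T_)) {
    stop("reference index out of range", call. = FALSE)
  }
  src <- function(t) if (!is.null(raw)) raw[[t]] else (frames[[t]]$labels > 0L)
  transforms <- vector("list", T_)
  registered <- vector("list", T_)
  for (t in seq_len(T_)) {
    fixed_t <- if (scenario == "S1") reference else t - 1L
    if ((scenario == "S1" && t == reference) || (scenario == "S2" && t == 1L)) {
      transforms[[t]] <- identity_transform(frames[[t]]$dimensionality,
                                            moving_index = t, fixed_index = t)
      registered[[t]] <- frames[[t]]
    } else {
      tr <- estimate_affine(src(t), src(fixed_t), backend,
                            moving_index = t, fixed_index = fixed_t)
      transforms[[t]] <- tr
      registered[[t]] <- apply_to_labels(frames[[t]], tr)
    }
  }
  structure(
    list(original = frames, registered = registered, transforms = transforms,
         scenario = scenario, reference = reference),
    class = "registered_series"
  )
}

#' @export
print.registered_series <- function(x, ...) {
  cat(sprintf("<registered_series> %s, %d frame(s), reference t=%d\n",
              x$scenario, length(x$original),
              if (x$scenario == "S1") x$reference else NA_integer_))
  invisible(x)
}
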