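#' Line profile along the right-left axis
#'
#' A 1D sequence of CT numbers along the RL axis at a fixed SI slice and AP
#' row, together with its anchor coordinates. Profiles are the 1D
#' abstraction the whole overlap search runs on: instead of comparing 3D
#' blocks, two horizontal lines through the spine are compared.
#'
#' @param values numeric vector of intensities (length >= 2).
#' @param slice,row 1-based anchor indices in the source volume.
#' @param side side label inherited from the source volume.
#' @return A `line_profile` object.
#' @export
line_profile <- function(values, slice, row, side = "full") {
  if (length(values) < 2L)
    stop("a line profile needs at least 2 samples", call. = FALSE)
  structure(list(values = as.double(values), slice = as.integer(slice),
                 row = as.integer(row), side = side),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> length %d at (slice %d, row %d), side=%s\n",
              length(x$values), x$slice, x$row, x$side))
  invisible(x)
}

#' @export
length.line_profile <- function(x) length(x$values)

#' Extract a line profile from a volume
#'
#' `values[i] = voxels[slice_index, row_index, i]` for every column; the
#' volume is untouched.
#'
#' @param volume a [ct_volume()].
#' @param slice_index,row_index 1-based SI slice and AP row.
#' @return A [line_profile()].
#' @export
extract_profile <- function(volume, slice_index, row_index) {
  stopifnot_volume(volume)
  if (slice_index < 1L || slice_index > n_slices(volume))
    stop(sprintf("slice index %d out of bounds [1, %d]",
                 slice_index, n_slices(volume)), call. = FALSE)
  if (row_index < 1L || row_index > n_rows(volume))
    stop(sprintf("row index %d out of bounds [1, %d]",
                 row_index, n_rows(volume)), call. = FALSE)
  line_profile(volume$voxels[slice_index, row_index, ],
               slice_index, row_index, volume$side)
}

#' Bone-threshold preprocessing of a profile
#'
#' Returns a copy in which values below `bone_threshold` are floored to 0
#' while values at or above it are kept, segmenting the bone before
#' matching. Running the matcher on preprocessed copies suppresses
#' soft-tissue noise; fusion always uses the original intensities. A
#' threshold of `-Inf` disables the operation (identity copy).
#'
#' @param profile a [line_profile()].
#' @param bone_threshold HU cutoff; `-Inf` to disable.
#' @return A new [line_profile()]; the input is untouched.
#' @export
preprocess_profile <- function(profile, bone_threshold = 150) {
  if (!inherits(profile, "line_profile"))
    stop("'profile' must be a line_profile", call. = FALSE)
  v <- profile$values
  if (is.finite(bone_threshold)) v[v < bone_threshold] <- 0
  line_profile(v, profile$slice, profile$row, profile$side)
}
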