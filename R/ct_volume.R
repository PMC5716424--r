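#' CT volume container
#'
#' A `ct_volume` holds a dense 3D grid of CT intensities in Hounsfield units
#' together with its voxel spacing and a side label. The array is indexed
#' `voxels[s, a, x]`:
#'
#' * `s` — superior-inferior slice index (increasing superior to inferior),
#' * `a` — anterior-posterior row index (increasing anterior to posterior,
#'   i.e. downwards in the displayed axial image),
#' * `x` — right-left column index, increasing from the left edge of the
#'   displayed field toward the right edge.
#'
#' The left-sided acquisition (the scan in which the patient's left side is
#' complete and uncompressed) occupies the low-`x` columns of the stitched
#' field; its right-facing edge is the truncated, possibly deformed one. The
#' right-sided acquisition occupies the high-`x` columns with its left-facing
#' edge truncated. All intensities are stored raw; no windowing is applied.
#'
#' @param voxels numeric 3D array indexed `[slice, row, column]`, in HU.
#' @param spacing numeric length-3, voxel size in mm along (SI, AP, RL).
#' @param side one of `"left"`, `"right"`, `"full"`.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), side = "full") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array", call. = FALSE)
  if (any(dim(voxels) < 1L))
    stop("all three volume extents must be >= 1", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive numbers (mm)", call. = FALSE)
  side <- match.arg(side, c("left", "right", "full"))
  storage.mode(voxels) <- "double"
  structure(
    list(voxels = voxels, spacing = as.double(spacing), side = side),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d slices x %d rows x %d cols, spacing %.3g x %.3g x %.3g mm, side=%s\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$side))
  cat(sprintf("  HU range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

n_slices <- function(v) dim(v$voxels)[1]
n_rows   <- function(v) dim(v$voxels)[2]
n_cols   <- function(v) dim(v$voxels)[3]

is_ct_volume <- function(x) inherits(x, "ct_volume")

stopifnot_volume <- function(x, arg = "volume") {
  if (!is_ct_volume(x)) stop(sprintf("'%s' must be a ct_volume", arg), call. = FALSE)
  invisible(x)
}

## round-half-up, used for the cropped column count
round_half_up <- function(x) floor(x + 0.5)

#' Crop a volume to one lateral side
#'
#' Keeps a lateral fraction of the columns: `side = "left"` keeps the first
#' (low-`x`) columns, emulating the left-sided partial acquisition,
#' `side = "right"` keeps the last columns. The kept count is
#' `round(keep_fraction * n_cols)` (half-up), never below 2. Intensities are
#' never reordered or rescaled.
#'
#' @param volume a [ct_volume()].
#' @param keep_fraction fraction of columns to keep, in (0, 1].
#' @param side `"left"` or `"right"`.
#' @return A `ct_volume` with the requested columns and updated side label.
#' @export
crop_volume <- function(volume, keep_fraction, side) {
  stopifnot_volume(volume)
  side <- match.arg(side, c("left", "right"))
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1L ||
      keep_fraction <= 0 || keep_fraction > 1)
    stop("'keep_fraction' must be a single number in (0, 1]", call. = FALSE)
  nc <- n_cols(volume)
  k <- round_half_up(keep_fraction * nc)
  if (k < 2)
    stop(sprintf("crop would keep %d column(s); at least 2 are required", k),
         call. = FALSE)
  k <- min(k, nc)
  cols <- if (side == "left") seq_len(k) else seq.int(nc - k + 1L, nc)
  ct_volume(volume$voxels[, , cols, drop = FALSE], volume$spacing, side = side)
}

## drop 'margin' columns from a volume's truncated (facing) edge:
## the right edge of a left-sided volume, the left edge of a right-sided one.
trim_facing_margin <- function(volume, margin, facing) {
  if (margin == 0L) return(volume)
  nc <- n_cols(volume)
  if (margin < 0L || margin >= nc - 1L)
    stop("'margin' must leave at least 2 columns", call. = FALSE)
  cols <- if (facing == "right") seq_len(nc - margin)
          else seq.int(margin + 1L, nc)
  ct_volume(volume$voxels[, , cols, drop = FALSE], volume$spacing, volume$side)
}
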