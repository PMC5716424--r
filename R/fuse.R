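#' Fusion configuration
#'
#' How the overlap region of the merged volume is filled, how many columns
#' are subtracted from each scan's truncated edge before merging (the same
#' margin the matcher used — margins are subtracted once), and the fill
#' value for rows exposed by AP alignment.
#'
#' @param mode `"left_centered"`, `"right_centered"`, or `"average"`:
#'   overlap intensities from the left scan only, the right scan only, or
#'   their arithmetic mean.
#' @param margin columns subtracted from each facing edge (>= 0).
#' @param fill_value HU for exposed rows (default air).
#' @return A `fusion_config` object.
#' @export
fusion_config <- function(mode = c("average", "left_centered", "right_centered"),
                          margin = 0L, fill_value = -1000) {
  mode <- match.arg(mode)
  if (margin < 0) stop("'margin' must be >= 0", call. = FALSE)
  structure(list(mode = mode, margin = as.integer(margin),
                 fill_value = as.double(fill_value)),
            class = "fusion_config")
}

#' Align the two scans along the slice axis
#'
#' Removes the unpaired slices implied by `delta_si` (a structure on left
#' slice `y` sits on right slice `y - delta_si`) and trims both volumes to a
#' common slice count, so that slice `i` of one corresponds anatomically to
#' slice `i` of the other. At most `|delta_si|` slices are dropped from the
#' leading end of one volume, plus whatever trailing slices have no partner.
#'
#' @param left_vol,right_vol the two partial [ct_volume()]s.
#' @param delta_si SI offset in slices.
#' @return A list with the two aligned volumes, `left` and `right`.
#' @export
align_si <- function(left_vol, right_vol, delta_si) {
  stopifnot_volume(left_vol, "left_vol"); stopifnot_volume(right_vol, "right_vol")
  d <- as.integer(delta_si)
  lv <- left_vol$voxels; rv <- right_vol$voxels
  if (d > 0L) {
    if (d >= dim(lv)[1]) stop("SI shift consumes all slices", call. = FALSE)
    lv <- lv[-seq_len(d), , , drop = FALSE]
  } else if (d < 0L) {
    if (-d >= dim(rv)[1]) stop("SI shift consumes all slices", call. = FALSE)
    rv <- rv[-seq_len(-d), , , drop = FALSE]
  }
  ns <- min(dim(lv)[1], dim(rv)[1])
  list(
    left  = ct_volume(lv[seq_len(ns), , , drop = FALSE],
                      left_vol$spacing, left_vol$side),
    right = ct_volume(rv[seq_len(ns), , , drop = FALSE],
                      right_vol$spacing, right_vol$side)
  )
}

#' Align the right scan along the anterior-posterior axis
#'
#' Displaces every slice's rows by `delta_ap` (positive toward posterior,
#' compensating a left scan that sits `delta_ap` rows lower than the right
#' one); exposed rows are set to `fill_value`. Extents are unchanged.
#'
#' @param right_vol a [ct_volume()].
#' @param delta_ap AP offset in rows; `|delta_ap| < n_rows`.
#' @param fill_value HU for exposed rows.
#' @return The shifted [ct_volume()].
#' @export
align_ap <- function(right_vol, delta_ap, fill_value = -1000) {
  stopifnot_volume(right_vol, "right_vol")
  d <- as.integer(delta_ap)
  if (d == 0L) return(right_vol)
  ct_volume(shift_rows(right_vol$voxels, d, fill_value),
            right_vol$spacing, right_vol$side)
}

#' Subtraction-and-merge fusion of the two partial scans
#'
#' Aligns the scans in SI and AP, subtracts `config$margin` columns from
#' each truncated (facing) edge — discarding the possibly deformed bands —
#' and merges: columns outside the overlap copy their sole source, columns
#' inside follow `config$mode`. Every output voxel is either a copy of
#' exactly one source voxel or, in average mode inside the overlap, the
#' mean of exactly two (rounded half-to-even when both sources are
#' integer-valued, the native CT representation). The output width is
#' `w_L' + w_R' - delta_rl'` with primes denoting post-subtraction widths
#' and overlap.
#'
#' @param left_vol,right_vol the two partial [ct_volume()]s.
#' @param offsets an [offset_estimate()], e.g. from [estimate_offsets()];
#'   `delta_rl` is on the as-given volume scale and must exceed
#'   `2 * margin`.
#' @param config a [fusion_config()].
#' @return A [ct_volume()] with side `"full"`.
#' @export
fuse <- function(left_vol, right_vol, offsets, config = fusion_config()) {
  stopifnot_volume(left_vol, "left_vol"); stopifnot_volume(right_vol, "right_vol")
  if (!inherits(config, "fusion_config"))
    stop("'config' must be a fusion_config", call. = FALSE)
  if (n_rows(left_vol) != n_rows(right_vol))
    stop("mismatched row counts between the two scans", call. = FALSE)
  al <- align_si(left_vol, right_vol, offsets$delta_si)
  r <- align_ap(al$right, offsets$delta_ap, config$fill_value)
  l <- trim_facing_margin(al$left, config$margin, "right")
  r <- trim_facing_margin(r, config$margin, "left")
  dx <- offsets$delta_rl - 2L * config$margin
  wl <- n_cols(l); wr <- n_cols(r)
  if (dx < 1L)
    stop("no overlap remains after margin subtraction", call. = FALSE)
  if (dx > wl || dx > wr)
    stop("overlap exceeds a scan's width after margin subtraction",
         call. = FALSE)
  wout <- wl + wr - dx
  out <- array(config$fill_value, dim = c(n_slices(l), n_rows(l), wout))
  if (wl > dx) out[, , seq_len(wl - dx)] <- l$voxels[, , seq_len(wl - dx)]
  if (wr > dx) out[, , seq.int(wl + 1L, wout)] <- r$voxels[, , seq.int(dx + 1L, wr)]
  ol <- l$voxels[, , seq.int(wl - dx + 1L, wl), drop = FALSE]
  or <- r$voxels[, , seq_len(dx), drop = FALSE]
  out[, , seq.int(wl - dx + 1L, wl)] <- switch(config$mode,
    left_centered  = ol,
    right_centered = or,
    average = {
      avg <- (ol + or) / 2
      if (is_integer_valued(ol) && is_integer_valued(or)) round(avg) else avg
    })
  ct_volume(out, l$spacing, side = "full")
}

is_integer_valued <- function(v) all(v == round(v))
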