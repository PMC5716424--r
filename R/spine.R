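#' Spine-anchoring rectangle
#'
#' The anchor for line-profile extraction: the reference SI slice and the
#' (row, col) center of a rectangle placed over the spine, together with the
#' rectangle half-extents.
#'
#' @param slice reference SI slice index (1-based).
#' @param row,col rectangle center (AP row, RL column), 1-based.
#' @param half_width,half_height rectangle half-extents in voxels (columns,
#'   rows respectively).
#' @return A `spine_rect` object.
#' @export
spine_rect <- function(slice, row, col, half_width = 8L, half_height = 8L) {
  structure(list(slice = as.integer(slice), row = as.integer(row),
                 col = as.integer(col),
                 half_width = as.integer(half_width),
                 half_height = as.integer(half_height)),
            class = "spine_rect")
}

#' @export
print.spine_rect <- function(x, ...) {
  cat(sprintf("<spine_rect> slice %d, center (row %d, col %d), rect %dx%d\n",
              x$slice, x$row, x$col,
              2L * x$half_height + 1L, 2L * x$half_width + 1L))
  invisible(x)
}

#' Locate the spine in a partial CT volume
#'
#' Exhaustively scores every admissible rectangle center on the reference
#' slice and returns the one maximizing the bone score: the sum of
#' `intensity - bone_threshold` over rectangle voxels at or above the
#' threshold. Thresholding first suppresses soft-tissue bias, so the score
#' responds to bone only. The search is restricted by the anatomical prior
#' that the spine sits in the posterior (lower) part of the axial image:
#' for a right-sided scan (which occupies the right of the stitched field,
#' spine near its left edge) the lower-left quadrant, for a left-sided scan
#' the lower-right quadrant, and the whole lower half for a full volume.
#' Ties are broken toward the smallest row, then the smallest column. The
#' implementation uses a summed-area table and is exactly equivalent to the
#' brute-force scan.
#'
#' @param volume a [ct_volume()].
#' @param bone_threshold HU cutoff separating bone from soft tissue.
#' @param rect_size `(half_width, half_height)` of the rectangle in voxels.
#' @param search_region `"lower_left"`, `"lower_right"`, `"lower_half"`, or
#'   `NULL` to choose from the volume's side label as above.
#' @param reference_slice 1-based SI slice, or `"middle"`.
#' @param manual_center optional `(row, col)` override; skips the search
#'   (rectangle size and position can be customized per patient).
#' @return A [spine_rect()].
#' @export
locate_spine <- function(volume, bone_threshold = 150,
                         rect_size = c(8L, 8L), search_region = NULL,
                         reference_slice = "middle", manual_center = NULL) {
  stopifnot_volume(volume)
  hw <- as.integer(rect_size[1]); hh <- as.integer(rect_size[2])
  nr <- n_rows(volume); nc <- n_cols(volume)
  ref <- if (identical(reference_slice, "middle"))
    (n_slices(volume) + 1L) %/% 2L else as.integer(reference_slice)
  if (ref < 1L || ref > n_slices(volume))
    stop("reference slice out of bounds", call. = FALSE)
  if (!is.null(manual_center))
    return(spine_rect(ref, manual_center[1], manual_center[2], hw, hh))
  if (is.null(search_region))
    search_region <- switch(volume$side,
                            left = "lower_right", right = "lower_left",
                            full = "lower_half")
  search_region <- match.arg(search_region,
                             c("lower_left", "lower_right", "lower_half"))
  ## admissible centers keep the rectangle fully inside the image
  rows_ok <- seq.int(hh + 1L, nr - hh)
  cols_ok <- seq.int(hw + 1L, nc - hw)
  rows_ok <- rows_ok[rows_ok > nr %/% 2L]              # posterior half
  cols_ok <- switch(search_region,
                    lower_left  = cols_ok[cols_ok <= nc %/% 2L],
                    lower_right = cols_ok[cols_ok >  nc %/% 2L],
                    lower_half  = cols_ok)
  if (!length(rows_ok) || !length(cols_ok))
    stop("search region admits no rectangle center; supply 'manual_center'",
         call. = FALSE)
  sl <- volume$voxels[ref, , ]
  region_rows <- seq.int(min(rows_ok) - hh, max(rows_ok) + hh)
  region_cols <- seq.int(min(cols_ok) - hw, max(cols_ok) + hw)
  if (!any(sl[region_rows, region_cols] >= bone_threshold))
    stop(paste0("no voxel at or above the bone threshold in the search ",
                "region; supply 'manual_center' for this patient"),
         call. = FALSE)
  score_img <- pmax(sl - bone_threshold, 0)
  ## summed-area table with a zero border for O(1) rectangle sums
  sat <- matrix(0, nr + 1L, nc + 1L)
  sat[-1L, -1L] <- t(apply(apply(score_img, 2, cumsum), 1, cumsum))
  r1 <- rows_ok - hh; r2 <- rows_ok + hh
  c1 <- cols_ok - hw; c2 <- cols_ok + hw
  scores <- sat[r2 + 1L, c2 + 1L, drop = FALSE] -
            sat[r1,      c2 + 1L, drop = FALSE] -
            sat[r2 + 1L, c1,      drop = FALSE] +
            sat[r1,      c1,      drop = FALSE]
  best <- which(scores == max(scores), arr.ind = TRUE)
  ## ties: smallest row, then smallest column (row-major which() order after
  ## sorting by (row, col))
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  spine_rect(ref, rows_ok[best[1]], cols_ok[best[2]], hw, hh)
}
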