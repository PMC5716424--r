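#' Match curve: RMSE as a function of candidate overlap
#'
#' Holds, for every candidate overlap width `delta` (in columns), the
#' root-mean-square error between the facing segments of the two profiles,
#' plus the minimizing overlap `delta_star` and its `rmse_min`. When the
#' matcher was run with a deformation margin, `delta` refers to the
#' margin-trimmed profiles.
#'
#' @param delta integer vector of candidate overlaps.
#' @param rmse nonnegative RMSE per candidate.
#' @param method `"varied"` or `"fixed"`.
#' @return A `match_curve` object.
#' @export
match_curve <- function(delta, rmse, method) {
  if (length(delta) != length(rmse) || !length(delta))
    stop("'delta' and 'rmse' must be nonempty and equal length", call. = FALSE)
  ## ties resolved toward the largest overlap: on featureless (e.g. fully
  ## floored) segments several overlaps score identically and the widest
  ## consistent one is the conservative choice
  ix <- which(rmse == min(rmse))
  ix <- ix[which.max(delta[ix])]
  structure(list(delta = as.integer(delta), rmse = as.double(rmse),
                 delta_star = as.integer(delta[ix]),
                 rmse_min = rmse[ix], method = method),
            class = "match_curve")
}

#' @export
print.match_curve <- function(x, ...) {
  cat(sprintf("<match_curve> %s matching, %d candidates, best overlap %d (RMSE %.4g)\n",
              x$method, length(x$delta), x$delta_star, x$rmse_min))
  invisible(x)
}

#' Registration result
#'
#' The estimated rigid translation between the two partial scans:
#' `delta_si` (slices), `delta_ap` (rows), `delta_rl` (the overlap width in
#' columns, on the scale of the volumes as given, i.e. any matching margin
#' already added back), and the minimized mean-square intensity difference
#' over the full 3D overlap region (for reporting).
#'
#' @param delta_si,delta_ap,delta_rl integer offsets.
#' @param objective nonnegative mean-square HU difference, or `NA`.
#' @param rmse_min the profile-level RMSE at the optimum (optional).
#' @return An `offset_estimate` object.
#' @export
offset_estimate <- function(delta_si, delta_ap, delta_rl,
                            objective = NA_real_, rmse_min = NA_real_) {
  structure(list(delta_si = as.integer(delta_si),
                 delta_ap = as.integer(delta_ap),
                 delta_rl = as.integer(delta_rl),
                 objective = as.double(objective),
                 rmse_min = as.double(rmse_min)),
            class = "offset_estimate")
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat(sprintf(
    "<offset_estimate> delta_si=%d slices, delta_ap=%d rows, delta_rl=%d cols (objective %.4g)\n",
    x$delta_si, x$delta_ap, x$delta_rl, x$objective))
  invisible(x)
}

profile_values <- function(p, what) {
  if (inherits(p, "line_profile")) p$values
  else if (is.numeric(p)) as.double(p)
  else stop(sprintf("'%s' must be a line_profile or numeric vector", what),
            call. = FALSE)
}

## drop `margin` columns from the facing ends: the right end of the
## left-sided profile, the left end of the right-sided profile (the
## subtraction step of subtraction-and-merge, applied once, before matching)
trim_profile_pair <- function(lv, rv, margin) {
  if (margin > 0L) {
    if (margin >= length(lv) - 1L || margin >= length(rv) - 1L)
      stop("margin leaves fewer than 2 profile samples", call. = FALSE)
    lv <- lv[seq_len(length(lv) - margin)]
    rv <- rv[-seq_len(margin)]
  }
  list(lv = lv, rv = rv)
}

#' Varied-length subsequence matching
#'
#' Scans every candidate overlap width `delta` from `delta_min` up to the
#' shorter profile length, and scores each by the RMSE between the last
#' `delta` samples of the left profile and the first `delta` samples of the
#' right profile:
#' `rmse(delta) = sqrt(mean((left[len_L - delta + i] - right[i])^2))`,
#' `i = 1..delta`. The true overlap minimizes the curve; ties go to the
#' largest overlap. If `margin > 0`, that many columns are first removed
#' from each profile's facing end (deformed-edge subtraction) and the
#' returned overlaps refer to the trimmed profiles.
#'
#' @param left,right [line_profile()]s (or plain numeric vectors) from the
#'   left- and right-sided scans.
#' @param delta_min smallest overlap considered (very small overlaps are
#'   noise-dominated).
#' @param margin columns to subtract from each facing end before matching.
#' @return A [match_curve()].
#' @export
match_varied <- function(left, right, delta_min = 8L, margin = 0L) {
  lv <- profile_values(left, "left"); rv <- profile_values(right, "right")
  if (delta_min < 2L) stop("'delta_min' must be at least 2", call. = FALSE)
  tr <- trim_profile_pair(lv, rv, as.integer(margin))
  lv <- tr$lv; rv <- tr$rv
  nl <- length(lv)
  dmax <- min(nl, length(rv))
  if (dmax < delta_min)
    stop(sprintf("profiles leave only %d samples after the margin; delta_min is %d",
                 dmax, delta_min), call. = FALSE)
  delta <- seq.int(delta_min, dmax)
  rmse <- vapply(delta, function(d) {
    diff <- lv[seq.int(nl - d + 1L, nl)] - rv[seq_len(d)]
    sqrt(sum(diff * diff) / d)
  }, numeric(1))
  match_curve(delta, rmse, "varied")
}

#' Fixed-length subsequence matching
#'
#' Takes a fixed query window of `query_len` samples from the left profile,
#' centered on the spine column (the overlap is assumed to contain the spine
#' width), slides it along the right profile, and scores each shift by RMSE.
#' Each shift is converted to the equivalent overlap width so that fixed-
#' and varied-length matching report on the same scale: a query starting at
#' left index `q` aligned at right shift `t` (0-based) implies an overlap of
#' `len_L - q + 1 + t` columns. Ties go to the largest equivalent overlap.
#'
#' @param left,right [line_profile()]s (or numeric vectors).
#' @param query_center 1-based column on the left profile (before any margin
#'   trimming) at the query window center, normally the spine column.
#' @param query_len window length in columns; must fit in both profiles.
#' @param margin columns subtracted from each facing end first.
#' @return A [match_curve()]; `delta` are equivalent overlaps on the
#'   margin-trimmed profiles.
#' @export
match_fixed <- function(left, right, query_center, query_len = 32L,
                        margin = 0L) {
  lv <- profile_values(left, "left"); rv <- profile_values(right, "right")
  tr <- trim_profile_pair(lv, rv, as.integer(margin))
  lv <- tr$lv; rv <- tr$rv
  nl <- length(lv); nr <- length(rv)
  query_len <- as.integer(query_len)
  qs <- as.integer(query_center) - query_len %/% 2L
  if (qs < 1L || qs + query_len - 1L > nl)
    stop(sprintf(
      "query window [%d, %d] falls outside the left profile (length %d)",
      qs, qs + query_len - 1L, nl), call. = FALSE)
  if (query_len > nr)
    stop("query window is longer than the right profile", call. = FALSE)
  q <- lv[seq.int(qs, qs + query_len - 1L)]
  shifts <- 0:(nr - query_len)
  rmse <- vapply(shifts, function(t) {
    diff <- q - rv[seq.int(t + 1L, t + query_len)]
    sqrt(sum(diff * diff) / query_len)
  }, numeric(1))
  match_curve(nl - qs + 1L + shifts, rmse, "fixed")
}

#' Full-ROI registration objective
#'
#' The mean-square CT-number difference over the 3D overlap region implied
#' by an offset estimate: after SI/AP alignment, the last `delta_rl` columns
#' of the left scan against the first `delta_rl` columns of the right scan,
#' over all common slices and rows.
#'
#' @param left_vol,right_vol the two partial [ct_volume()]s.
#' @param offsets an [offset_estimate()].
#' @param fill_value HU used for rows exposed by the AP alignment.
#' @return A single nonnegative number.
#' @export
roi_objective <- function(left_vol, right_vol, offsets, fill_value = -1000) {
  stopifnot_volume(left_vol, "left_vol"); stopifnot_volume(right_vol, "right_vol")
  al <- align_si(left_vol, right_vol, offsets$delta_si)
  r <- align_ap(al$right, offsets$delta_ap, fill_value)
  l <- al$left
  o <- offsets$delta_rl
  if (o < 1L || o > n_cols(l) || o > n_cols(r))
    stop("offsets define an empty or out-of-range overlap", call. = FALSE)
  a <- l$voxels[, , seq.int(n_cols(l) - o + 1L, n_cols(l)), drop = FALSE]
  b <- r$voxels[, , seq_len(o), drop = FALSE]
  mean((a - b)^2)
}

#' Estimate the rigid offsets between two partial scans
#'
#' For every candidate SI/AP displacement in the configured search windows,
#' extracts the left profile through the spine center and the right profile
#' at the displaced position, optionally bone-preprocesses both, runs the
#' configured matcher, and returns the displacement whose minimal profile
#' RMSE is globally smallest. Exact RMSE ties between candidates resolve toward the
#' largest overlap (on bone-preprocessed profiles, short windows containing
#' no bone on either side score exactly zero, and the widest consistent
#' overlap is the informative one), then toward the smallest
#' `(|delta_si|, |delta_ap|)` displacement — the marker setup makes true
#' shifts very small. The reported `delta_rl` is on the scale of the volumes
#' as given (`matcher optimum + 2 * margin`), and the full-ROI mean-square
#' objective is recomputed at the optimum for reporting.
#'
#' @param left_vol,right_vol the two partial [ct_volume()]s; they must share
#'   spacing and row/column extents (slice counts may differ by up to the SI
#'   window).
#' @param spine_left,spine_right [spine_rect()]s located in each scan; the
#'   left anchor defines the profile position, the right one is checked for
#'   consistency.
#' @param config a [stitch_config()] (or list overriding parts of it).
#' @return An [offset_estimate()].
#' @export
estimate_offsets <- function(left_vol, right_vol, spine_left, spine_right,
                             config = stitch_config()) {
  stopifnot_volume(left_vol, "left_vol"); stopifnot_volume(right_vol, "right_vol")
  cfg <- stitch_config_fill(config)
  if (!isTRUE(all.equal(left_vol$spacing, right_vol$spacing)))
    stop("the two scans have different voxel spacing; acquire with identical imaging parameters",
         call. = FALSE)
  if (n_rows(left_vol) != n_rows(right_vol) ||
      n_cols(left_vol) != n_cols(right_vol))
    stop("the two scans must share row and column extents", call. = FALSE)
  if (abs(n_slices(left_vol) - n_slices(right_vol)) > cfg$si_window)
    stop("slice counts differ by more than the SI search window", call. = FALSE)
  yc <- spine_left$slice; zc <- spine_left$row; xc <- spine_left$col
  if (!is.null(spine_right) &&
      abs(spine_right$row - spine_left$row) > cfg$ap_window + 4L)
    warning("spine rows detected in the two scans differ by more than the AP window; check the inputs")
  thr <- if (isTRUE(cfg$preprocess)) cfg$bone_threshold_hu else -Inf
  lp <- preprocess_profile(extract_profile(left_vol, yc, zc), thr)
  ## fixed matcher: clamp the query window into the margin-trimmed profile
  qc <- xc
  if (cfg$matcher == "fixed") {
    nl <- n_cols(left_vol) - cfg$margin
    half <- cfg$query_len %/% 2L
    qc <- min(max(qc, half + 1L), nl - (cfg$query_len - half) + 1L)
  }
  cand <- expand.grid(dy = -cfg$si_window:cfg$si_window,
                      dz = -cfg$ap_window:cfg$ap_window)
  cand <- cand[order(abs(cand$dy), abs(cand$dz), cand$dy, cand$dz), ]
  best <- NULL
  for (k in seq_len(nrow(cand))) {
    dy <- cand$dy[k]; dz <- cand$dz[k]
    ys <- yc - dy; zs <- zc - dz
    if (ys < 1L || ys > n_slices(right_vol) ||
        zs < 1L || zs > n_rows(right_vol)) next
    rp <- preprocess_profile(extract_profile(right_vol, ys, zs), thr)
    curve <- if (cfg$matcher == "varied")
      match_varied(lp, rp, delta_min = cfg$delta_min, margin = cfg$margin)
    else
      match_fixed(lp, rp, query_center = qc, query_len = cfg$query_len,
                  margin = cfg$margin)
    better <- is.null(best) || curve$rmse_min < best$rmse ||
      (curve$rmse_min == best$rmse && curve$delta_star > best$delta)
    if (better) {
      best <- list(dy = dy, dz = dz, rmse = curve$rmse_min,
                   delta = curve$delta_star)
    }
  }
  if (is.null(best) || !is.finite(best$rmse))
    stop("no finite RMSE over the search window; check the spine anchors",
         call. = FALSE)
  est <- offset_estimate(delta_si = best$dy, delta_ap = best$dz,
                         delta_rl = best$delta + 2L * cfg$margin,
                         rmse_min = best$rmse)
  est$objective <- roi_objective(left_vol, right_vol, est,
                                 fill_value = cfg$fill_value)
  est
}
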