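#' Specification of a synthetic CT phantom
#'
#' Describes a full axial CT-like volume: air background, an elliptical
#' soft-tissue body cross-section, and a bright rectangular bony insert in
#' the posterior midline standing in for the spine. A smooth random HU
#' texture is superimposed on the whole body (soft tissue and bone) so that
#' every slice and every row carries a distinct intensity fingerprint, and
#' the spine insert jitters laterally by a small per-slice amount — both are
#' what makes slice- and row-level alignment identifiable. All intensities
#' are rounded to integer HU, as a scanner would emit.
#'
#' @param n_slices,n_rows,n_cols volume extents (SI, AP, RL); minimum (4, 32, 32).
#' @param body_center (row, col) center of the body ellipse; default mid-image.
#' @param body_semi (row, col) semi-axes of the body ellipse in voxels;
#'   default nearly fills the field laterally, as an oversized patient would.
#' @param tissue_hu,bone_hu,air_hu intensities of the three materials.
#' @param spine_center (row, col) center of the bony insert; default posterior
#'   midline, halfway between body center and posterior body edge.
#' @param spine_half (row-half-height, col-half-width) of the insert.
#' @param jitter per-slice maximum lateral displacement of the insert (voxels).
#' @param texture standard deviation (HU) of the smooth body texture.
#' @param spacing voxel spacing in mm (SI, AP, RL).
#' @param seed integer seed; the same spec always yields the same phantom.
#' @return A `phantom_spec` object for [generate_phantom()].
#' @export
phantom_spec <- function(n_slices = 20, n_rows = 128, n_cols = 192,
                         body_center = NULL, body_semi = NULL,
                         tissue_hu = 40, bone_hu = 700, air_hu = -1000,
                         spine_center = NULL, spine_half = c(10, 8),
                         jitter = 1, texture = 10,
                         spacing = c(2.5, 1, 1), seed = 1L) {
  ext <- as.integer(c(n_slices, n_rows, n_cols))
  if (any(ext < c(4L, 32L, 32L)))
    stop("phantom extents must be at least (4, 32, 32)", call. = FALSE)
  if (is.null(body_center)) body_center <- c(n_rows / 2, (n_cols + 1) / 2)
  if (is.null(body_semi))   body_semi   <- c(0.40 * n_rows, 0.46 * n_cols)
  if (is.null(spine_center))
    spine_center <- c(body_center[1] + 0.5 * body_semi[1], body_center[2])
  if (!(air_hu < tissue_hu && tissue_hu < bone_hu))
    stop("intensities must satisfy air < tissue < bone", call. = FALSE)
  if (spine_center[1] <= body_center[1])
    stop("spine insert must lie in the posterior half of the body",
         call. = FALSE)
  ## the insert, at its maximal jitter, must stay inside the body ellipse
  corners_r <- spine_center[1] + c(-1, 1) * spine_half[1]
  corners_c <- spine_center[2] + c(-1, 1) * (spine_half[2] + jitter)
  for (r in corners_r) for (cc in corners_c) {
    if (((r - body_center[1]) / body_semi[1])^2 +
        ((cc - body_center[2]) / body_semi[2])^2 > 1)
      stop("spine insert (including jitter) extends outside the body ellipse",
           call. = FALSE)
  }
  structure(list(
    n_slices = ext[1], n_rows = ext[2], n_cols = ext[3],
    body_center = as.double(body_center), body_semi = as.double(body_semi),
    tissue_hu = tissue_hu, bone_hu = bone_hu, air_hu = air_hu,
    spine_center = as.double(spine_center), spine_half = as.double(spine_half),
    jitter = as.integer(jitter), texture = as.double(texture),
    spacing = as.double(spacing), seed = as.integer(seed)
  ), class = "phantom_spec")
}

## bilinear upsampling of a coarse random grid: smooth 2D field, n x m
smooth_field <- function(n, m, step = 8L) {
  gn <- ceiling((n - 1) / step) + 1L
  gm <- ceiling((m - 1) / step) + 1L
  g <- matrix(stats::rnorm(gn * gm), gn, gm)
  interp_mat <- function(len, glen) {
    pos <- seq(0, glen - 1, length.out = len)
    lo <- pmin(floor(pos), glen - 2); w <- pos - lo
    mat <- matrix(0, len, glen)
    mat[cbind(seq_len(len), lo + 1)] <- 1 - w
    mat[cbind(seq_len(len), lo + 2)] <- w
    mat
  }
  interp_mat(n, gn) %*% g %*% t(interp_mat(m, gm))
}

#' Generate a synthetic CT phantom volume
#'
#' Deterministic for a fixed spec (seed included). See [phantom_spec()] for
#' what the phantom contains.
#'
#' @param spec a [phantom_spec()].
#' @return A [ct_volume()] with side `"full"`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("'spec' must be a phantom_spec", call. = FALSE)
  withr::with_seed(spec$seed, {
    ns <- spec$n_slices; nr <- spec$n_rows; nc <- spec$n_cols
    rows <- seq_len(nr); cols <- seq_len(nc)
    body <- outer(((rows - spec$body_center[1]) / spec$body_semi[1])^2,
                  ((cols - spec$body_center[2]) / spec$body_semi[2])^2,
                  "+") <= 1
    base <- matrix(spec$air_hu, nr, nc)
    base[body] <- spec$tissue_hu
    jit <- if (spec$jitter > 0)
      sample.int(2L * spec$jitter + 1L, ns, replace = TRUE) - spec$jitter - 1L
    else integer(ns)
    sp_rows <- which(abs(rows - spec$spine_center[1]) <= spec$spine_half[1])
    vox <- array(0, dim = c(ns, nr, nc))
    for (s in seq_len(ns)) {
      sl <- base
      cx <- spec$spine_center[2] + jit[s]
      sp_cols <- which(abs(cols - cx) <= spec$spine_half[2])
      sl[sp_rows, sp_cols] <- spec$bone_hu
      if (spec$texture > 0) {
        f <- smooth_field(nr, nc)
        f <- f / stats::sd(f) * spec$texture
        sl[body] <- sl[body] + f[body]
      }
      vox[s, , ] <- sl
    }
    ct_volume(round(vox), spacing = spec$spacing, side = "full")
  })
}

#' Specification of a left/right split of a full volume
#'
#' Describes how a full phantom is divided into two partial acquisitions
#' with known ground truth: a lateral overlap of `overlap_cols` columns,
#' optional AP and SI misalignment of the right-sided scan, optional lateral
#' compression of each scan's truncated edge, and independent additive
#' Gaussian noise per scan (two physical scans have independent noise, which
#' is what makes average fusion meaningful).
#'
#' Sign conventions match the estimator's output: `ap_shift` (= true
#' delta_ap) means the left scan's content sits `ap_shift` rows lower
#' (more posterior) than the right scan's; `si_shift` (= true delta_si)
#' means a structure on left slice `y` appears on right slice `y - si_shift`.
#'
#' @param overlap_cols true lateral overlap in columns (>= 2).
#' @param ap_shift,si_shift true AP (rows) / SI (slices) offsets.
#' @param deform_margin width in columns of the compressed band at each
#'   scan's truncated edge.
#' @param deform_strength fraction in `[0, 1)` of lateral compression
#'   within the band; 0 disables deformation.
#' @param noise_sigma HU standard deviation of per-scan additive noise.
#' @param air_hu fill value for rows exposed by the AP shift.
#' @param seed integer seed for the noise streams.
#' @return A `split_spec` for [split_phantom()].
#' @export
split_spec <- function(overlap_cols, ap_shift = 0L, si_shift = 0L,
                       deform_margin = 0L, deform_strength = 0,
                       noise_sigma = 0, air_hu = -1000, seed = 1L) {
  if (overlap_cols < 2)
    stop("'overlap_cols' must be at least 2", call. = FALSE)
  if (deform_strength < 0 || deform_strength >= 1)
    stop("'deform_strength' must be in [0, 1)", call. = FALSE)
  if (deform_margin < 0) stop("'deform_margin' must be >= 0", call. = FALSE)
  structure(list(
    overlap_cols = as.integer(overlap_cols),
    ap_shift = as.integer(ap_shift), si_shift = as.integer(si_shift),
    deform_margin = as.integer(deform_margin),
    deform_strength = as.double(deform_strength),
    noise_sigma = as.double(noise_sigma), air_hu = as.double(air_hu),
    seed = as.integer(seed)
  ), class = "split_spec")
}

## laterally compress the band of `m` columns at one edge of the volume:
## nearest-neighbour resampling that squeezes the innermost (1-s)*m columns
## of the band across the whole band, so edge columns no longer match truth.
deform_edge <- function(vox, m, strength, edge) {
  if (m == 0L || strength == 0) return(vox)
  nc <- dim(vox)[3]
  p <- 0:(m - 1)                       # 0 = innermost band column
  src_p <- floor(p * (1 - strength))
  if (edge == "right") {               # band = last m columns
    idx <- nc - m + 1 + p
    src <- nc - m + 1 + src_p
  } else {                             # band = first m columns
    idx <- m - p
    src <- m - src_p
  }
  vox[, , idx] <- vox[, , src, drop = FALSE]
  vox
}

#' Split a full volume into two partial acquisitions with known truth
#'
#' The left-sided scan keeps the first `w_L` columns, the right-sided scan
#' the last `w_R`, with `w_L + w_R - n_cols = overlap_cols` (widths as equal
#' as possible). SI misalignment is realized by dropping edge slices (a scan
#' that starts one slice lower simply never acquires the first slice), AP
#' misalignment by displacing the right scan's rows with air fill, then each
#' scan's truncated edge band is compressed and independent noise is added.
#'
#' @param volume a full [ct_volume()].
#' @param split a [split_spec()].
#' @return A list with elements `left`, `right` (both [ct_volume()]) and
#'   `truth` (an [offset_estimate()] holding the exact offsets).
#' @export
split_phantom <- function(volume, split) {
  stopifnot_volume(volume)
  if (!inherits(split, "split_spec"))
    stop("'split' must be a split_spec", call. = FALSE)
  nc <- n_cols(volume); ns <- n_slices(volume)
  o <- split$overlap_cols
  if (o > nc) stop("'overlap_cols' exceeds the volume width", call. = FALSE)
  if (o < 2L * split$deform_margin + 2L)
    stop(sprintf(
      "overlap of %d columns leaves no clean region after two %d-column deformed bands",
      o, split$deform_margin), call. = FALSE)
  if (abs(split$si_shift) >= ns)
    stop("'si_shift' consumes all slices", call. = FALSE)
  w_l <- as.integer(ceiling((nc + o) / 2))
  w_r <- nc + o - w_l
  lv <- volume$voxels[, , seq_len(w_l), drop = FALSE]
  rv <- volume$voxels[, , seq.int(nc - w_r + 1L, nc), drop = FALSE]
  ## SI: structure on left slice y must appear on right slice y - si_shift
  d <- split$si_shift
  if (d > 0L) rv <- rv[-seq_len(d), , , drop = FALSE]
  if (d < 0L) lv <- lv[-seq_len(-d), , , drop = FALSE]
  ## AP: left content sits ap_shift rows lower than right, so displace the
  ## right scan's content by -ap_shift rows (air fill)
  if (split$ap_shift != 0L)
    rv <- shift_rows(rv, -split$ap_shift, split$air_hu)
  lv <- deform_edge(lv, split$deform_margin, split$deform_strength, "right")
  rv <- deform_edge(rv, split$deform_margin, split$deform_strength, "left")
  if (split$noise_sigma > 0) {
    withr::with_seed(split$seed, {
      lv <- round(lv + stats::rnorm(length(lv), 0, split$noise_sigma))
      rv <- round(rv + stats::rnorm(length(rv), 0, split$noise_sigma))
    })
  }
  list(
    left  = ct_volume(lv, volume$spacing, side = "left"),
    right = ct_volume(rv, volume$spacing, side = "right"),
    truth = offset_estimate(delta_si = split$si_shift,
                            delta_ap = split$ap_shift,
                            delta_rl = o, objective = NA_real_)
  )
}

## displace all rows of a [s, a, x] array by `delta` (positive = toward
## larger a, i.e. posterior), filling exposed rows
shift_rows <- function(vox, delta, fill) {
  if (delta == 0L) return(vox)
  nr <- dim(vox)[2]
  if (abs(delta) >= nr) stop("row shift exceeds the number of rows",
                             call. = FALSE)
  out <- array(fill, dim = dim(vox))
  if (delta > 0L) {
    out[, seq.int(delta + 1L, nr), ] <- vox[, seq_len(nr - delta), ,
                                            drop = FALSE]
  } else {
    out[, seq_len(nr + delta), ] <- vox[, seq.int(1L - delta, nr), ,
                                        drop = FALSE]
  }
  out
}
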