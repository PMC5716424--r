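# Independent brute-force recomputations used as oracles. Deliberately
# written as plain loops, sharing no code with the package internals.

oracle_match_varied <- function(lv, rv, delta_min) {
  nl <- length(lv)
  dmax <- min(nl, length(rv))
  delta <- delta_min:dmax
  rmse <- numeric(length(delta))
  for (k in seq_along(delta)) {
    d <- delta[k]
    s <- 0
    for (i in 0:(d - 1)) s <- s + (lv[nl - d + 1 + i] - rv[1 + i])^2
    rmse[k] <- sqrt(s / d)
  }
  ix <- which(rmse == min(rmse))
  ix <- ix[which.max(delta[ix])]
  list(delta = delta, rmse = rmse, delta_star = delta[ix], rmse_min = rmse[ix])
}

oracle_match_fixed <- function(lv, rv, query_center, query_len) {
  nl <- length(lv)
  qs <- query_center - query_len %/% 2
  q <- lv[qs:(qs + query_len - 1)]
  shifts <- 0:(length(rv) - query_len)
  rmse <- numeric(length(shifts))
  for (k in seq_along(shifts)) {
    t <- shifts[k]
    s <- 0
    for (i in 1:query_len) s <- s + (q[i] - rv[t + i])^2
    rmse[k] <- sqrt(s / query_len)
  }
  delta <- nl - qs + 1 + shifts
  ix <- which(rmse == min(rmse))
  ix <- ix[which.max(delta[ix])]
  list(delta = delta, rmse = rmse, delta_star = delta[ix], rmse_min = rmse[ix])
}

# mean-square intensity difference over the overlap ROI, by triple loop
oracle_roi <- function(lvox, rvox, overlap) {
  ns <- dim(lvox)[1]; nr <- dim(lvox)[2]
  wl <- dim(lvox)[3]
  s <- 0; n <- 0
  for (si in 1:ns) for (ai in 1:nr) for (k in 1:overlap) {
    d <- lvox[si, ai, wl - overlap + k] - rvox[si, ai, k]
    s <- s + d^2
    n <- n + 1
  }
  s / n
}

# exhaustive rectangle-score search on one slice; ties -> smallest row,
# then smallest column
oracle_spine_search <- function(slice_mat, threshold, hw, hh, rows, cols) {
  best <- NULL
  for (r in rows) for (x in cols) {
    rect <- slice_mat[(r - hh):(r + hh), (x - hw):(x + hw)]
    sc <- sum(pmax(rect - threshold, 0))
    if (is.null(best) || sc > best$score) best <- list(row = r, col = x, score = sc)
  }
  best
}

# synthetic profile with air flanks, soft-tissue body and a bony plateau --
# the generic shape the matcher sees
random_profile_values <- function(n, rng_bone = TRUE) {
  v <- round(rnorm(n, 40, 15))
  flank <- max(1, round(n * 0.1))
  v[seq_len(flank)] <- -1000
  v[seq.int(n - flank + 1, n)] <- -1000
  if (rng_bone) {
    w <- sample(3:max(4, n %/% 4), 1)
    at <- sample(seq.int(flank + 1, n - flank - w), 1)
    v[at:(at + w - 1)] <- round(rnorm(w, 700, 20))
  }
  v
}
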