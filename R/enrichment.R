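#' Signal profile around reference points (boundaries)
#'
#' Aggregates a binned signal track around anchor positions: each anchor
#' contributes the bins in `[position - flank, position + flank)`, and the
#' profile is the position-wise mean across anchors — the usual way of
#' asking whether, say, CTCF is enriched at TAD boundaries. Anchors whose
#' window extends past a chromosome end are dropped; with `skip_zeros`,
#' all-zero windows are excluded too and counted as skipped.
#'
#' @param track A `signal_track`.
#' @param boundaries Data.frame with a `position` column (bp, on the bin
#'   grid), e.g. from [assign_boundary_levels()], or a numeric vector.
#' @param flank_bp Flank on each side (bp, multiple of the resolution).
#' @param skip_zeros Exclude all-zero windows.
#' @return A `profile_result`: list with `position` (bp offsets of bin
#'   starts relative to the anchor), `mean_signal`, `n_regions`,
#'   `n_skipped`.
#' @export
reference_point_profile <- function(track, boundaries, flank_bp = 5e5,
                                    skip_zeros = FALSE) {
  stopifnot(inherits(track, "signal_track"))
  if (is.data.frame(boundaries)) boundaries <- boundaries$position
  res <- track$resolution
  if (flank_bp %% res != 0)
    stop("parameter error: flank_bp must be a multiple of the resolution")
  F <- as.integer(flank_bp / res)
  nb <- length(track$values)
  rows <- list(); n_skipped <- 0L
  for (p in boundaries) {
    b0 <- p / res - F          # 0-based first bin of the window
    b1 <- p / res + F - 1
    if (b0 < 0 || b1 >= nb) { n_skipped <- n_skipped + 1L; next }
    v <- track$values[(b0 + 1):(b1 + 1)]
    if (skip_zeros && all(v == 0)) { n_skipped <- n_skipped + 1L; next }
    rows[[length(rows) + 1L]] <- v
  }
  if (length(rows)) {
    mat <- do.call(rbind, rows)
    mean_signal <- colMeans(mat)
  } else {
    mean_signal <- rep(NA_real_, 2L * F)
  }
  structure(list(position = seq(-flank_bp, flank_bp - res, by = res),
                 mean_signal = mean_signal,
                 n_regions = length(rows), n_skipped = n_skipped),
            class = "profile_result")
}

# Length-weighted resampling of `v` (source bins) onto `n_out` equal target
# positions: target t covers source fraction [t*m/n_out, (t+1)*m/n_out).
.resample_weighted <- function(v, n_out) {
  m <- length(v)
  if (m == n_out) return(v)
  out <- numeric(n_out)
  for (t in seq_len(n_out)) {
    lo <- (t - 1) * m / n_out
    hi <- t * m / n_out
    b0 <- floor(lo); b1 <- ceiling(hi) - 1
    acc <- 0
    for (b in b0:b1) {
      ov <- min(hi, b + 1) - max(lo, b)
      if (ov > 0) acc <- acc + v[b + 1] * ov
    }
    out[t] <- acc / (hi - lo)
  }
  out
}

#' Scaled-region signal profile across TAD bodies
#'
#' Each region's body is linearly rescaled to a common length
#' (`body_bp`, default 30 kb) by length-weighted averaging of source bins
#' onto the target positions; flanking bins are taken unscaled. The
#' profile is the position-wise mean across regions. Regions shorter than
#' one bin, or extending (with flanks) past the chromosome, are skipped
#' and counted; with `skip_zeros` (the default, matching the usual
#' scale-regions setting) all-zero regions are skipped too.
#'
#' @param track A `signal_track`.
#' @param regions Data.frame with `start`, `end` columns (bp, on the bin
#'   grid), e.g. a hierarchy's records.
#' @param body_bp Common body length after scaling (bp, multiple of the
#'   resolution).
#' @param flank_bp Unscaled flank on each side (bp, multiple of the
#'   resolution; 0 for none).
#' @param skip_zeros Exclude all-zero regions.
#' @return A `profile_result`; `position` is the profile index in bp-like
#'   units: flank offsets are real offsets and body positions are the
#'   scaled coordinate.
#' @export
scale_regions_profile <- function(track, regions, body_bp = 30000,
                                  flank_bp = 0, skip_zeros = TRUE) {
  stopifnot(inherits(track, "signal_track"))
  res <- track$resolution
  if (body_bp %% res != 0 || flank_bp %% res != 0)
    stop("parameter error: body_bp and flank_bp must be multiples of the resolution")
  n_body <- as.integer(body_bp / res)
  F <- as.integer(flank_bp / res)
  nb <- length(track$values)
  rows <- list(); n_skipped <- 0L
  for (k in seq_len(nrow(regions))) {
    s <- regions$start[k]; e <- regions$end[k]
    if (e - s < res) { n_skipped <- n_skipped + 1L; next }
    b0 <- s / res; b1 <- e / res - 1          # 0-based body bins
    if (b0 - F < 0 || b1 + F >= nb) { n_skipped <- n_skipped + 1L; next }
    body <- track$values[(b0 + 1):(b1 + 1)]
    left <- if (F > 0) track$values[(b0 - F + 1):b0] else numeric()
    right <- if (F > 0) track$values[(b1 + 2):(b1 + 1 + F)] else numeric()
    v <- c(left, .resample_weighted(body, n_body), right)
    if (skip_zeros && all(v == 0)) { n_skipped <- n_skipped + 1L; next }
    rows[[length(rows) + 1L]] <- v
  }
  npos <- 2L * F + n_body
  if (length(rows)) {
    mean_signal <- colMeans(do.call(rbind, rows))
  } else {
    mean_signal <- rep(NA_real_, npos)
  }
  structure(list(position = c(if (F > 0) seq(-flank_bp, -res, by = res),
                              seq(0, body_bp - res, by = res),
                              if (F > 0) seq(body_bp, body_bp + flank_bp - res,
                                             by = res)),
                 mean_signal = mean_signal,
                 n_regions = length(rows), n_skipped = n_skipped),
            class = "profile_result")
}
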