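#' Parameters for the synthetic nested-TAD generator
#'
#' Controls the ground-truth hierarchy layout and the block-enriched
#' contact-map model: expected counts decay with genomic distance as
#' `A * (|i - j| + 1)^-alpha` and are multiplied by `beta` for every
#' domain jointly containing the two bins, so nesting compounds the
#' enrichment multiplicatively; observed counts are Poisson.
#'
#' @param chrom_length Chromosome length (bp).
#' @param resolution Bin size (bp); must divide `chrom_length`.
#' @param max_depth Maximum nesting depth (>= 1).
#' @param split_probability Per-domain probability of splitting into
#'   children, per level (recycled to `max_depth - 1`).
#' @param children_range Inclusive range of child counts per split.
#' @param gap_fraction Expected fraction of the chromosome left uncovered
#'   between top-level domains.
#' @param min_tad_bp,max_tad_bp Top-level domain size range (log-uniform).
#' @param alpha Distance-decay exponent.
#' @param beta Per-level contact enrichment factor (> 1 for detectable
#'   structure).
#' @param A Background contact intensity at distance 0.
#' @return A `sim_params` list.
#' @export
sim_params <- function(chrom_length = 24e6, resolution = 1e4,
                       max_depth = 3, split_probability = 0.7,
                       children_range = c(2, 3), gap_fraction = 0.05,
                       min_tad_bp = 3e4, max_tad_bp = 2e6,
                       alpha = 1.0, beta = 1.6, A = 30) {
  if (chrom_length %% resolution != 0)
    stop("parameter error: resolution does not divide chrom_length")
  if (max_depth < 1) stop("parameter error: max_depth must be >= 1")
  if (any(split_probability < 0 | split_probability > 1))
    stop("parameter error: split_probability must lie in [0, 1]")
  structure(list(chrom_length = chrom_length, resolution = resolution,
                 max_depth = as.integer(max_depth),
                 split_probability = split_probability,
                 children_range = as.integer(children_range),
                 gap_fraction = gap_fraction,
                 min_tad_bp = min_tad_bp, max_tad_bp = max_tad_bp,
                 alpha = alpha, beta = beta, A = A),
            class = "sim_params")
}

#' Simulate a ground-truth nested TAD hierarchy
#'
#' Tiles the chromosome with level-1 domains of log-uniform size (between
#' `min_tad_bp` and `max_tad_bp`, snapped to the bin grid), optionally
#' separated by gaps, then recursively splits each domain into
#' non-overlapping children (each strictly inside its parent) with the
#' per-level split probability, down to `max_depth`. Generator levels are
#' recorded and agree with [assign_tad_levels()] by construction.
#'
#' @param p A [sim_params()].
#' @param seed Integer seed.
#' @return A validated `tad_hierarchy` with levels.
#' @export
simulate_hierarchy <- function(p = sim_params(), seed = NULL) {
  stopifnot(inherits(p, "sim_params"))
  .with_seed(seed, {
    res <- p$resolution
    nb <- p$chrom_length / res
    min_bins <- max(1, round(p$min_tad_bp / res))
    max_bins <- max(min_bins, round(p$max_tad_bp / res))
    starts <- numeric(); ends <- numeric(); levels <- integer()
    emit <- function(s, e, l) {
      starts[length(starts) + 1L] <<- s
      ends[length(ends) + 1L] <<- e
      levels[length(levels) + 1L] <<- l
    }
    split_prob_at <- function(depth) {
      sp <- p$split_probability
      sp[min(depth, length(sp))]
    }
    split_domain <- function(b0, b1, level) {   # bins [b0, b1), 0-based
      emit(b0 * res, b1 * res, level)
      if (level >= p$max_depth) return(invisible())
      w <- b1 - b0
      if (w < 4L) return(invisible())
      if (stats::runif(1) > split_prob_at(level)) return(invisible())
      kmax <- min(p$children_range[2L], w - 1L)
      kmin <- min(max(2L, p$children_range[1L]), kmax)
      if (kmax < 2L) return(invisible())
      k <- if (kmin == kmax) kmin else sample(kmin:kmax, 1L)
      cuts <- sort(sample((b0 + 1L):(b1 - 1L), k - 1L))
      edges <- c(b0, cuts, b1)
      for (c_ in seq_len(k)) split_domain(edges[c_], edges[c_ + 1L],
                                          level + 1L)
    }
    pos <- 0L
    while (pos < nb) {
      if (nb - pos < min_bins) break    # trailing stub left uncovered
      if (p$gap_fraction > 0 && stats::runif(1) < p$gap_fraction) {
        pos <- pos + sample.int(max(1L, min_bins), 1L)
        next
      }
      w <- round(exp(stats::runif(1, log(min_bins), log(max_bins))))
      w <- max(min_bins, min(w, nb - pos))
      if (nb - (pos + w) < min_bins) w <- nb - pos   # absorb the remainder
      split_domain(pos, pos + w, 1L)
      pos <- pos + w
    }
    h <- tad_hierarchy(starts, ends, levels, resolution = res,
                       chrom_length = p$chrom_length)
    validate_hierarchy(h)
  })
}

# Number of domains jointly containing bins i and j, as a dense matrix.
.containment_depth <- function(h) {
  nb <- n_bins(h)
  depth <- matrix(0L, nb, nb)
  r <- h$records
  for (k in seq_len(nrow(r))) {
    b0 <- r$start[k] / h$resolution + 1
    b1 <- r$end[k] / h$resolution
    depth[b0:b1, b0:b1] <- depth[b0:b1, b0:b1] + 1L
  }
  depth
}

#' Simulate a block-enriched Hi-C contact matrix for a hierarchy
#'
#' Expected count `mu(i, j) = A * (|i - j| + 1)^-alpha * beta^depth(i, j)`
#' with `depth(i, j)` the number of domains containing both bins; observed
#' counts are independent Poisson draws on the upper triangle,
#' symmetrized. The result is integer-valued and nonnegative, suitable for
#' downsampling and mixing experiments.
#'
#' @param h A `tad_hierarchy` (its levels define the block structure).
#' @param p A [sim_params()] supplying `A`, `alpha`, `beta`.
#' @param seed Integer seed.
#' @return A `contact_matrix`.
#' @export
simulate_contact_matrix <- function(h, p = sim_params(), seed = NULL) {
  h <- .check_validated(h)
  nb <- n_bins(h)
  dist <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  mu <- p$A * (dist + 1)^(-p$alpha) * p$beta^.containment_depth(h)
  .with_seed(seed, {
    ut <- upper.tri(mu, diag = TRUE)
    draws <- stats::rpois(sum(ut), mu[ut])
    x <- matrix(0, nb, nb)
    x[ut] <- draws
    x <- x + t(x)
    diag(x) <- diag(x) / 2
    contact_matrix(x, resolution = h$resolution, chrom = h$chrom,
                   chrom_length = h$chrom_length)
  })
}

#' Perturb a hierarchy by boundary shifts and record dropout
#'
#' Shifts each record's start and end independently by a uniform integer
#' in `[-shift_bins, +shift_bins]` bins (clamped so that start stays
#' nonnegative, start < end, and end stays within the chromosome), then
#' drops each record independently with probability `drop_prob`, dedups,
#' and re-assigns levels. Used to probe how gracefully similarity metrics
#' degrade with boundary error.
#'
#' @param h A validated `tad_hierarchy`.
#' @param shift_bins Maximum boundary shift (bins).
#' @param drop_prob Per-record dropout probability.
#' @param seed Integer seed.
#' @return The perturbed `tad_hierarchy` with fresh levels.
#' @export
perturb_hierarchy <- function(h, shift_bins = 0, drop_prob = 0,
                              seed = NULL) {
  h <- .check_validated(h)
  r <- h$records
  if (nrow(r) == 0L) return(h)
  .with_seed(seed, {
    res <- h$resolution
    n <- nrow(r)
    if (shift_bins > 0) {
      d1 <- sample(-shift_bins:shift_bins, n, replace = TRUE) * res
      d2 <- sample(-shift_bins:shift_bins, n, replace = TRUE) * res
      s <- pmin(pmax(r$start + d1, 0), h$chrom_length - res)
      e <- pmin(pmax(r$end + d2, s + res), h$chrom_length)
      r$start <- s; r$end <- e
    }
    if (drop_prob > 0) {
      keep <- stats::runif(n) >= drop_prob
      r <- r[keep, , drop = FALSE]
    }
    h$records <- data.frame(start = r$start, end = r$end,
                            level = rep(NA_integer_, nrow(r)))
    h$validated <- FALSE
    assign_tad_levels(validate_hierarchy(h))
  })
}
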