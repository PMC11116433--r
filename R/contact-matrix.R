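#' Symmetric intra-chromosomal contact matrix
#'
#' Binned pairwise contact counts on one chromosome. Counts are stored as a
#' dense symmetric matrix; the total is the sum over unordered bin pairs
#' (diagonal counted once). Raw matrices are integer-valued; balanced
#' matrices may carry real values.
#'
#' @param counts Square symmetric nonnegative numeric matrix.
#' @param resolution Bin size (bp).
#' @param chrom Chromosome label.
#' @param chrom_length Chromosome length (bp); defaults to
#'   `nrow(counts) * resolution`.
#' @return A `contact_matrix` S3 object.
#' @export
contact_matrix <- function(counts, resolution, chrom = "chr1",
                           chrom_length = nrow(counts) * resolution) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("shape error: counts must be square")
  if (any(counts < 0)) stop("value error: negative counts")
  if (max(abs(counts - t(counts))) > 1e-9)
    stop("symmetry error: counts asymmetric beyond 1e-9")
  structure(list(chrom = as.character(chrom),
                 resolution = as.numeric(resolution),
                 chrom_length = as.numeric(chrom_length),
                 n_bins = nrow(counts),
                 counts = counts),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins @ %g bp, total %g\n",
              x$chrom, x$n_bins, x$resolution, contact_total(x)))
  invisible(x)
}

#' Total contacts over unordered bin pairs
#'
#' Sums each off-diagonal pair once and the diagonal once.
#' @param m A `contact_matrix`.
#' @return Scalar total.
#' @export
contact_total <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  sum(m$counts[upper.tri(m$counts, diag = TRUE)])
}

# Run `code` under a seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' ICE balancing of a contact matrix
#'
#' Iterative correction: repeatedly divides `c(i, j)` by `s_i * s_j`, where
#' `s_i` is bin i's marginal divided by the mean unmasked marginal, until
#' the maximum relative deviation of unmasked marginals from their mean
#' falls below `tol` (or `max_iter` is reached, with a warning). Bins whose
#' marginal is zero are masked and excluded throughout; the balanced matrix
#' is rescaled at the end so its total equals the input total.
#'
#' @param m A `contact_matrix`.
#' @param tol Convergence tolerance on the relative marginal deviation.
#' @param max_iter Iteration cap.
#' @param mask_zero_bins Mask zero-marginal bins (default). An additional
#'   `mask_frac` masks that fraction of lowest-marginal bins first.
#' @param mask_frac Optional fraction in `[0, 1)` of lowest-coverage bins to
#'   mask before balancing.
#' @return A list with `matrix` (balanced `contact_matrix`), `bias`
#'   (multiplicative per-bin bias, `NA` on masked bins), `mask` (logical,
#'   `TRUE` = masked), `converged`, `n_iter`.
#' @export
ice_normalize <- function(m, tol = 1e-5, max_iter = 100,
                          mask_zero_bins = TRUE, mask_frac = 0) {
  stopifnot(inherits(m, "contact_matrix"))
  x <- m$counts
  nb <- nrow(x)
  marg <- rowSums(x)
  mask <- if (mask_zero_bins) marg == 0 else rep(FALSE, nb)
  if (mask_frac > 0) {
    k <- floor(mask_frac * nb)
    if (k > 0) mask[order(marg)[seq_len(k)]] <- TRUE
  }
  if (all(mask)) stop("degenerate-input error: all bins masked")
  x[mask, ] <- 0; x[, mask] <- 0
  total_in <- sum(x[upper.tri(x, diag = TRUE)])
  bias <- rep(1, nb)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    marg <- rowSums(x)
    mu <- mean(marg[!mask])
    dev <- max(abs(marg[!mask] / mu - 1))
    if (dev < tol) { converged <- TRUE; break }
    s <- marg / mu
    s[mask | s == 0] <- 1
    x <- x / outer(s, s)
    bias <- bias * s
  }
  if (!converged) {
    marg <- rowSums(x)
    mu <- mean(marg[!mask])
    if (max(abs(marg[!mask] / mu - 1)) < tol) converged <- TRUE
    else warning(sprintf("ICE did not converge in %d iterations", max_iter))
  }
  total_out <- sum(x[upper.tri(x, diag = TRUE)])
  if (total_out > 0) x <- x * (total_in / total_out)
  bias[mask] <- NA_real_
  out <- m
  out$counts <- x
  list(matrix = out, bias = bias, mask = mask, converged = converged,
       n_iter = iter)
}

#' Downsample a contact matrix to an exact total
#'
#' Draws exactly `target_total` contacts without replacement from the
#' multiset of individual contacts (a multivariate hypergeometric over
#' matrix entries, realized by sequential conditional hypergeometric
#' draws), emulating the downsampling of a real read multiset. The output
#' total equals `target_total` exactly and the result is reproducible for
#' a fixed seed. `method = "multinomial"` gives the with-replacement
#' variant instead.
#'
#' @param m Integer-valued `contact_matrix`.
#' @param target_total Requested total over unordered pairs,
#'   `0 <= target_total <= contact_total(m)` (multinomial mode allows any
#'   nonnegative total).
#' @param seed Integer seed.
#' @param method `"hypergeometric"` (default, without replacement) or
#'   `"multinomial"`.
#' @return The downsampled `contact_matrix`.
#' @export
downsample_contacts <- function(m, target_total, seed = NULL,
                                method = c("hypergeometric", "multinomial")) {
  stopifnot(inherits(m, "contact_matrix"))
  method <- match.arg(method)
  x <- m$counts
  if (max(abs(x - round(x))) > 1e-9)
    stop("type error: counts must be integer-valued for downsampling")
  x <- round(x)
  ut <- upper.tri(x, diag = TRUE)
  counts <- x[ut]
  total <- sum(counts)
  target_total <- round(target_total)
  if (target_total < 0) stop("parameter error: negative target_total")
  if (method == "hypergeometric" && target_total > total)
    stop("parameter error: target_total exceeds the matrix total")
  if (target_total == total && method == "hypergeometric") return(m)
  out <- m
  new <- numeric(length(counts))
  if (target_total > 0) {
    if (method == "hypergeometric") {
      new <- .with_seed(seed, {
        drawn <- numeric(length(counts))
        remaining_pool <- total
        remaining_draw <- target_total
        for (k in seq_along(counts)) {
          if (remaining_draw == 0) break
          ck <- counts[k]
          if (ck == 0) next
          d <- stats::rhyper(1, m = ck, n = remaining_pool - ck,
                             k = remaining_draw)
          drawn[k] <- d
          remaining_pool <- remaining_pool - ck
          remaining_draw <- remaining_draw - d
        }
        drawn
      })
    } else {
      new <- .with_seed(seed, {
        p <- counts / total
        as.numeric(stats::rmultinom(1, size = target_total, prob = p))
      })
    }
  }
  y <- matrix(0, nrow(x), ncol(x))
  y[ut] <- new
  y <- y + t(y)
  diag(y) <- diag(y) / 2
  out$counts <- y
  out
}

#' Mix contact matrices at given ratios
#'
#' Emulates pseudo-bulk mixtures of cell populations: every input is first
#' downsampled to a common total (`equalized_total`, by default the
#' smallest input total), then input i is downsampled to
#' `round(ratio_i * equalized_total)` (round-half-to-even) and the results
#' are summed entrywise. The canonical ratio grid for two populations is
#' given by [mixing_ratio_grid()]. With all mass on one component the
#' mixture reproduces a pure downsample of that component bit-exactly for
#' the same seed.
#'
#' @param ms List of integer-valued `contact_matrix` objects, same shape.
#' @param ratios Nonnegative weights summing to 1.
#' @param equalized_total Common total before ratio-downsampling.
#' @param seed Integer seed; input i uses sub-seeds derived as
#'   `seed + i - 1` (stage 1) and `seed + i - 1 + length(ms)` (stage 2).
#' @return The mixed `contact_matrix` with total
#'   `sum(round(ratios * equalized_total))`.
#' @export
mix_matrices <- function(ms, ratios,
                         equalized_total = min(vapply(ms, contact_total,
                                                      numeric(1))),
                         seed = NULL) {
  stopifnot(length(ms) >= 1L, all(vapply(ms, inherits, logical(1),
                                         "contact_matrix")))
  nb <- ms[[1L]]$n_bins
  if (any(vapply(ms, function(m) m$n_bins, integer(1)) != nb))
    stop("shape error: matrices differ in bin count")
  if (length(ratios) != length(ms))
    stop("parameter error: one ratio per matrix required")
  if (any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9)
    stop("parameter error: ratios must be nonnegative and sum to 1")
  acc <- matrix(0, nb, nb)
  for (i in seq_along(ms)) {
    s1 <- if (is.null(seed)) NULL else seed + i - 1L
    s2 <- if (is.null(seed)) NULL else seed + i - 1L + length(ms)
    eq <- downsample_contacts(ms[[i]], equalized_total, seed = s1)
    target <- round(ratios[i] * equalized_total)
    if (target == 0) next
    part <- downsample_contacts(eq, target, seed = s2)
    acc <- acc + part$counts
  }
  out <- ms[[1L]]
  out$counts <- acc
  out
}

#' The canonical two-population mixing ratio grid
#'
#' The pure samples plus 9:1 through 1:9 in steps of one tenth.
#' @return A two-column matrix of ratios, rows summing to 1.
#' @export
mixing_ratio_grid <- function() {
  a <- seq(10, 0) / 10
  cbind(a, 1 - a, deparse.level = 0)
}

#' Pseudo-bulk aggregation of single-cell contact matrices
#'
#' Selects cells from each group (sampling without replacement within the
#' group) and sums their matrices entrywise. Group selection counts come
#' either from `n_per_group` directly or from `ratios` of `n_total` cells,
#' apportioned by largest remainder so they sum to `n_total` exactly.
#'
#' @param cells List of `contact_matrix` objects, one per cell.
#' @param groups Factor/vector assigning each cell to a group.
#' @param n_per_group Named or positionally matched cell counts per group.
#' @param ratios Group mixing ratios (alternative to `n_per_group`).
#' @param n_total Total number of cells to select when using `ratios`.
#' @param seed Integer seed for the within-group sampling.
#' @return A list with `matrix` (the summed `contact_matrix`) and
#'   `selected` (indices of the chosen cells).
#' @export
pseudo_bulk <- function(cells, groups = rep(1L, length(cells)),
                        n_per_group = NULL, ratios = NULL,
                        n_total = length(cells), seed = NULL) {
  stopifnot(length(cells) >= 1L, length(groups) == length(cells))
  groups <- as.factor(groups)
  glev <- levels(groups)
  if (is.null(n_per_group)) {
    if (is.null(ratios)) stop("parameter error: give n_per_group or ratios")
    if (length(ratios) != length(glev))
      stop("parameter error: one ratio per group required")
    ratios <- ratios / sum(ratios)
    raw <- ratios * n_total
    n_per_group <- floor(raw)
    short <- n_total - sum(n_per_group)
    if (short > 0) {
      bump <- order(raw - floor(raw), decreasing = TRUE)[seq_len(short)]
      n_per_group[bump] <- n_per_group[bump] + 1L
    }
  }
  if (length(n_per_group) != length(glev))
    stop("parameter error: one count per group required")
  avail <- table(groups)
  if (any(n_per_group > as.integer(avail)))
    stop("parameter error: requested more cells than available in a group")
  selected <- .with_seed(seed, {
    unlist(lapply(seq_along(glev), function(g) {
      idx <- which(groups == glev[g])
      k <- n_per_group[g]
      if (k == 0L) integer() else idx[sample.int(length(idx), k)]
    }))
  })
  acc <- matrix(0, cells[[1L]]$n_bins, cells[[1L]]$n_bins)
  for (i in selected) acc <- acc + cells[[i]]$counts
  out <- cells[[1L]]
  out$counts <- acc
  list(matrix = out, selected = sort(selected))
}
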