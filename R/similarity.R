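#' Pixel multiplier for level rasters
#'
#' Each raster pixel is the nesting level of the innermost domain covering
#' the pixel, multiplied by this constant.
#' @export
LEVEL_RASTER_MULTIPLIER <- 20

#' Default Hier_SSIM sliding-window size in bp
#' @export
HIER_SSIM_WINDOW_BP <- 8e6

#' Rasterize a TAD hierarchy into a level map
#'
#' Builds the square "TAD level map" the hierarchy-similarity metric is
#' computed on: pixel (i, j) carries `20 * max{level(T) : T contains bins i
#' and j}`, i.e. 20 times the level of the innermost domain covering both
#' bins, and 0 where no domain covers the pair. The raster is symmetric by
#' construction and every value is a nonnegative multiple of 20.
#'
#' @param h A `tad_hierarchy` with levels assigned.
#' @param n_bins Raster side; defaults to the hierarchy's bin count and
#'   must equal `ceiling(chrom_length / resolution)` when supplied.
#' @param multiplier Pixel multiplier (default [LEVEL_RASTER_MULTIPLIER]).
#' @return A `level_raster`: list with `pixels` (matrix), `resolution`,
#'   `multiplier`.
#' @export
rasterize_hierarchy <- function(h, n_bins = NULL,
                                multiplier = LEVEL_RASTER_MULTIPLIER) {
  h <- .check_validated(h)
  nb <- as.integer(ceiling(h$chrom_length / h$resolution))
  if (is.null(n_bins)) n_bins <- nb
  if (n_bins != nb)
    stop(sprintf("shape error: n_bins %d inconsistent with chrom_length/resolution (%d)",
                 n_bins, nb))
  r <- h$records
  if (nrow(r) && anyNA(r$level)) {
    h <- assign_tad_levels(h)
    r <- h$records
  }
  px <- matrix(0, n_bins, n_bins)
  if (nrow(r)) {
    ord <- order(r$level)          # ascending: inner (higher) levels win
    for (k in ord) {
      b0 <- r$start[k] / h$resolution + 1
      b1 <- r$end[k] / h$resolution
      px[b0:b1, b0:b1] <- multiplier * r$level[k]
    }
  }
  structure(list(pixels = px, resolution = h$resolution,
                 multiplier = multiplier),
            class = "level_raster")
}

#' SSIM parameter set
#'
#' Stabilization constants `C1 = (K1 * L)^2`, `C2 = (K2 * L)^2` and the
#' local uniform patch side used by the windowed structural-similarity
#' statistic.
#'
#' @param L Data range of the compared images (must be positive unless the
#'   inputs are identical).
#' @param K1,K2 Stabilization fractions.
#' @param patch_side Odd local patch side (uniform weights).
#' @return An `ssim_params` list with `K1`, `K2`, `patch_side`, `L`, `C1`,
#'   `C2`.
#' @export
ssim_params <- function(L, K1 = 0.01, K2 = 0.03, patch_side = 7) {
  if (patch_side %% 2 != 1 || patch_side < 1)
    stop("parameter error: patch_side must be odd and positive")
  structure(list(K1 = K1, K2 = K2, patch_side = as.integer(patch_side),
                 L = L, C1 = (K1 * L)^2, C2 = (K2 * L)^2),
            class = "ssim_params")
}

# Valid-mode mean over every w x w patch (compiled running-sum box filter).
.uniform_filter_valid <- function(x, w) .box_mean_valid(x, w)

#' Mean local structural similarity of two square matrices
#'
#' The structural-similarity statistic averaged over every fully interior
#' local patch (uniform weights, default side 7), using sample (unbiased)
#' variance and covariance per patch:
#' `((2*mu_x*mu_y + C1) * (2*cov_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2))`.
#' Identical inputs return exactly 1 regardless of the data range.
#'
#' @param x,y Square numeric matrices of the same shape, side at least the
#'   patch side.
#' @param params An [ssim_params()] (carries the data range `L`).
#' @return A scalar in `[-1, 1]`.
#' @export
ssim_window <- function(x, y, params) {
  stopifnot(inherits(params, "ssim_params"))
  if (!all(dim(x) == dim(y))) stop("shape error: x and y differ in shape")
  if (nrow(x) < params$patch_side)
    stop("shape error: matrix side smaller than the SSIM patch")
  if (identical(dim(x), dim(y)) && all(x == y)) return(1)
  if (!is.finite(params$L) || params$L <= 0)
    stop("parameter error: data range L must be positive for non-identical inputs")
  w <- params$patch_side
  npix <- w * w
  cov_norm <- npix / (npix - 1)          # sample statistics
  ux <- .uniform_filter_valid(x, w)
  uy <- .uniform_filter_valid(y, w)
  uxx <- .uniform_filter_valid(x * x, w)
  uyy <- .uniform_filter_valid(y * y, w)
  uxy <- .uniform_filter_valid(x * y, w)
  vx <- cov_norm * (uxx - ux * ux)
  vy <- cov_norm * (uyy - uy * uy)
  vxy <- cov_norm * (uxy - ux * uy)
  C1 <- params$C1; C2 <- params$C2
  s <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux * ux + uy * uy + C1) * (vx + vy + C2))
  mean(s)
}

#' Hier_SSIM: hierarchy similarity of two level rasters
#'
#' Slides a window of `window_bp` (8 Mb by default) along the diagonal of
#' the two level maps, computes the structural similarity of each pair of
#' diagonal blocks, and returns the average — the Hier_SSIM metric for
#' comparing hierarchical TAD calls. Windows start at bins 0, `step_bins`,
#' `2 * step_bins`, ...; a trailing block shorter than the window is
#' dropped. The SSIM data range defaults to 20 times the maximum level
#' observed across both rasters (20 when both rasters are empty); a fixed
#' `L` can be supplied for reproducibility across panels.
#'
#' @param a,b `level_raster` objects of the same size and resolution.
#' @param window_bp Diagonal window size in bp; must be a multiple of the
#'   resolution.
#' @param step_bins Stride between window starts; defaults to one full
#'   window (non-overlapping blocks).
#' @param L Optional fixed SSIM data range.
#' @param params_fun Function of `L` returning the [ssim_params()] to use.
#' @return Scalar Hier_SSIM.
#' @export
hier_ssim <- function(a, b, window_bp = HIER_SSIM_WINDOW_BP,
                      step_bins = NULL, L = NULL, params_fun = ssim_params) {
  stopifnot(inherits(a, "level_raster"), inherits(b, "level_raster"))
  if (!all(dim(a$pixels) == dim(b$pixels)))
    stop("shape error: rasters differ in size")
  if (a$resolution != b$resolution)
    stop("resolution error: rasters differ in resolution")
  if (window_bp %% a$resolution != 0)
    stop("parameter error: resolution does not divide window_bp")
  W <- as.integer(window_bp / a$resolution)
  nb <- nrow(a$pixels)
  if (nb < W)
    stop(sprintf("insufficient-extent error: %d bins < window of %d bins", nb, W))
  if (is.null(step_bins)) step_bins <- W
  if (is.null(L)) {
    L <- max(a$pixels, b$pixels)
    if (L == 0) L <- a$multiplier
  }
  p <- params_fun(L)
  starts <- seq(0L, nb - W, by = step_bins)
  vals <- vapply(starts, function(s0) {
    idx <- (s0 + 1L):(s0 + W)
    ssim_window(a$pixels[idx, idx], b$pixels[idx, idx], p)
  }, numeric(1))
  mean(vals)
}

#' Coding-tree overlap ratio of two hierarchies
#'
#' Treats each hierarchy's distinct `(start, end)` intervals (all levels)
#' as the nodes of its coding tree and scores the intersection of the two
#' node sets: nodes match when both endpoints agree within
#' `match_tolerance_bins` bins, matched greedily one-to-one by smallest
#' endpoint distance, and `OR = 2 * matches / (|A| + |B|)` (a Dice
#' coefficient on matched nodes). Two empty hierarchies have OR 1.
#'
#' @param a,b `tad_hierarchy` objects at the same resolution.
#' @param match_tolerance_bins Maximum per-endpoint discrepancy in bins.
#' @return Scalar in `[0, 1]`.
#' @export
overlap_ratio <- function(a, b, match_tolerance_bins = 0) {
  a <- .check_validated(a); b <- .check_validated(b)
  if (a$resolution != b$resolution)
    stop("resolution error: hierarchies differ in resolution")
  res <- a$resolution
  na_ <- unique(a$records[c("start", "end")])
  nb_ <- unique(b$records[c("start", "end")])
  if (nrow(na_) == 0L && nrow(nb_) == 0L) return(1)
  if (nrow(na_) == 0L || nrow(nb_) == 0L) return(0)
  ds <- abs(outer(na_$start, nb_$start, "-")) / res
  de <- abs(outer(na_$end, nb_$end, "-")) / res
  d <- pmax(ds, de)
  eligible <- which(d <= match_tolerance_bins, arr.ind = TRUE)
  matches <- 0L
  if (nrow(eligible)) {
    ord <- order(d[eligible], eligible[, 1L], eligible[, 2L])
    used_a <- logical(nrow(na_)); used_b <- logical(nrow(nb_))
    for (k in ord) {
      i <- eligible[k, 1L]; j <- eligible[k, 2L]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        matches <- matches + 1L
      }
    }
  }
  2 * matches / (nrow(na_) + nrow(nb_))
}

#' Caller-by-caller similarity matrix
#'
#' @param values Symmetric numeric matrix of pairwise similarities with
#'   unit diagonal.
#' @param labels Row/column labels.
#' @return A `similarity_matrix`.
#' @export
similarity_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("shape error: must be square")
  if (max(abs(values - t(values))) > 1e-9)
    stop("symmetry error: similarity matrix asymmetric")
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels),
            class = "similarity_matrix")
}

#' Average-linkage (UPGMA) clustering of a similarity matrix
#'
#' Agglomerates on the distance `d = 1 - similarity` with unweighted
#' average linkage: the distance between two clusters is the mean of all
#' cross-pair distances from the original matrix. Ties are broken by the
#' lexicographically smallest pair of member labels, making the merge order
#' deterministic. The result converts to a standard [stats::hclust] tree.
#'
#' @param s A `similarity_matrix`, or a symmetric distance matrix when
#'   `is_distance = TRUE`.
#' @param is_distance Interpret `s` directly as distances.
#' @return A list with `merge`, `height`, `labels`, `order` in
#'   [stats::hclust] layout, plus class `hclust` for plotting/cutting.
#' @export
average_linkage_cluster <- function(s, is_distance = FALSE) {
  if (inherits(s, "similarity_matrix")) {
    d <- 1 - s$values
    labels <- s$labels
  } else {
    d <- as.matrix(s)
    if (max(abs(d - t(d))) > 1e-9)
      stop("symmetry error: input matrix asymmetric")
    if (!is_distance) d <- 1 - d
    labels <- rownames(d)
    if (is.null(labels)) labels <- paste0("S", seq_len(nrow(d)))
  }
  n <- nrow(d)
  diag(d) <- 0
  if (n < 2L) stop("parameter error: need at least two items to cluster")
  # active clusters: list of member index vectors; id: hclust convention
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      dist_ij <- mean(d[members[[i]], members[[j]]])
      key <- c(dist_ij, min(members[[i]][1L], members[[j]][1L]),
               max(members[[i]][1L], members[[j]][1L]))
      if (is.null(best) || dist_ij < best$key[1L] - 1e-12 ||
          (abs(dist_ij - best$key[1L]) <= 1e-12 &&
           (key[2L] < best$key[2L] ||
            (key[2L] == best$key[2L] && key[3L] < best$key[3L])))) {
        best <- list(i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    pair <- c(ids[i], ids[j])
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]
    height[step] <- best$key[1L]
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    ids[i] <- step
    members[[j]] <- NULL
    ids <- ids[-j]
  }
  hc <- list(merge = merge, height = height,
             order = .dendrogram_order(merge, n), labels = labels,
             method = "average", call = match.call(),
             dist.method = "1 - similarity")
  class(hc) <- "hclust"
  hc
}

.dendrogram_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(n - 1L)
}

#' Render an hclust tree as nested Newick-like text
#'
#' @param hc An `hclust` object (e.g. from [average_linkage_cluster()]).
#' @param digits Height digits.
#' @return A single Newick string with merge heights as internal labels.
#' @export
cluster_newick <- function(hc, digits = 6) {
  fmt <- function(node) {
    if (node < 0) return(hc$labels[-node])
    h <- signif(hc$height[node], digits)
    sprintf("(%s,%s):%g", fmt(hc$merge[node, 1L]), fmt(hc$merge[node, 2L]), h)
  }
  paste0(fmt(nrow(hc$merge)), ";")
}
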