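# Independent oracles and fixture generators used across the suite.

# Longest strict-containment-chain levels by memoized recursion over the
# pairwise containment relation (no sorting; independent of the package's
# width-descending dynamic program).
oracle_levels <- function(start, end) {
  n <- length(start)
  if (n == 0L) return(integer())
  # contains[i, j]: interval j strictly contains interval i
  contains <- outer(start, start, function(a, b) b <= a) &
    outer(end, end, function(a, b) a <= b) &
    !(outer(start, start, "==") & outer(end, end, "=="))
  memo <- rep(NA_integer_, n)
  depth <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    memo[i] <<- 0L                      # cycle guard (cannot occur)
    cs <- which(contains[i, ])
    v <- if (length(cs)) 1L + max(vapply(cs, depth, integer(1))) else 1L
    memo[i] <<- v
    v
  }
  vapply(seq_len(n), depth, integer(1))
}

# Random (generally non-nested) interval set on the resolution grid,
# deduplicated, as a validated hierarchy.
random_interval_hierarchy <- function(n, resolution = 1e4,
                                      chrom_length = 2e6) {
  nb <- chrom_length / resolution
  s <- sample.int(nb, n, replace = TRUE) - 1L
  w <- sample.int(nb, n, replace = TRUE)
  e <- pmin(s + w, nb)
  keep <- e > s
  validate_hierarchy(tad_hierarchy(s[keep] * resolution, e[keep] * resolution,
                                   resolution = resolution,
                                   chrom_length = chrom_length))
}

# Average-linkage clustering via Lance-Williams recurrence (different update
# route than the package's naive cross-pair recomputation).
oracle_upgma <- function(d) {
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  labels <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(active) > 1L) {
    k <- length(active)
    best <- c(Inf, 0L, 0L)
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      if (d[active[a], active[b]] < best[1L] - 1e-12) {
        best <- c(d[active[a], active[b]], a, b)
      }
    }
    ia <- active[best[2L]]; ib <- active[best[3L]]
    heights <- c(heights, best[1L])
    # Lance-Williams UPGMA update onto slot ia
    for (other in setdiff(active, c(ia, ib))) {
      d[ia, other] <- d[other, ia] <-
        (sizes[ia] * d[ia, other] + sizes[ib] * d[ib, other]) /
        (sizes[ia] + sizes[ib])
    }
    sizes[ia] <- sizes[ia] + sizes[ib]
    labels[[ia]] <- sort(c(labels[[ia]], labels[[ib]]))
    active <- setdiff(active, ib)
    partitions[[length(partitions) + 1L]] <- labels[[ia]]
  }
  list(heights = heights, partitions = partitions)
}

# Cluster member sets at every merge of an hclust-layout tree.
hclust_partitions <- function(hc) {
  n <- nrow(hc$merge) + 1L
  sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    mem <- function(node) if (node < 0) -node else sets[[node]]
    sets[[s]] <- sort(c(mem(hc$merge[s, 1L]), mem(hc$merge[s, 2L])))
  }
  sets
}

# A small, fixed, properly nested hierarchy used in several files.
nested_demo_hierarchy <- function() {
  validate_hierarchy(tad_hierarchy(
    starts = c(0, 0, 50000, 10000),
    ends = c(100000, 50000, 100000, 40000),
    resolution = 10000, chrom_length = 200000))
}

# Small deterministic Poisson contact matrix.
random_contact_matrix <- function(nb = 30, lambda = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(0, nb, nb)
  ut <- upper.tri(x, diag = TRUE)
  x[ut] <- rpois(sum(ut), lambda)
  x <- x + t(x)
  diag(x) <- diag(x) / 2
  contact_matrix(x, resolution = 1e4)
}
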