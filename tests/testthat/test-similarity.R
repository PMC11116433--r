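test_that("level rasters carry 20x the innermost covering level", {
  # domain of 3 bins (level 1) containing a 2-bin child (level 2)
  h <- assign_tad_levels(validate_hierarchy(tad_hierarchy(
    c(0, 0), c(30000, 20000), resolution = 10000, chrom_length = 4e4)))
  ras <- rasterize_hierarchy(h)
  expect_equal(ras$pixels[1, 2], 40)   # both bins inside the child
  expect_equal(ras$pixels[1, 3], 20)   # only the parent covers the pair
  expect_equal(ras$pixels[4, 4], 0)    # outside every domain
  expect_true(isSymmetric(ras$pixels))
  expect_true(all(ras$pixels %% 20 == 0))

  empty <- validate_hierarchy(tad_hierarchy(resolution = 1e4,
                                            chrom_length = 4e4))
  expect_true(all(rasterize_hierarchy(empty)$pixels == 0))

  expect_error(rasterize_hierarchy(h, n_bins = 10), "shape error")
})

test_that("raster pixels equal an innermost-common-domain enumeration", {
  set.seed(21)
  for (rep in 1:5) {
    h <- assign_tad_levels(random_interval_hierarchy(15, chrom_length = 3e5))
    ras <- rasterize_hierarchy(h)
    r <- h$records
    nb <- n_bins(h)
    for (i in sample.int(nb, 6)) for (j in sample.int(nb, 6)) {
      covering <- r$start / 1e4 <= min(i, j) - 1 & max(i, j) <= r$end / 1e4
      want <- if (any(covering)) 20 * max(r$level[covering]) else 0
      expect_equal(ras$pixels[i, j], want)
    }
  }
})

test_that("windowed SSIM matches closed forms and the reference image library", {
  p <- ssim_params(L = 20)
  x0 <- matrix(0, 10, 10)
  y20 <- matrix(20, 10, 10)
  # constant windows: all variances vanish, statistic is 0.04/400.04
  expect_equal(ssim_window(x0, y20, p), 0.04 / 400.04, tolerance = 1e-14)

  set.seed(33)
  a <- matrix(sample(0:3, 144, TRUE) * 20, 12, 12)
  expect_identical(ssim_window(a, a, ssim_params(L = 60)), 1)
  b <- matrix(sample(0:3, 144, TRUE) * 20, 12, 12)
  expect_equal(ssim_window(a, b, ssim_params(L = 60)),
               ssim_window(b, a, ssim_params(L = 60)))

  # frozen from scikit-image structural_similarity (win_size = 7,
  # gaussian_weights = FALSE, data_range = 80) on this exact seeded pair
  set.seed(42)
  x <- matrix(sample(0:4, 400, TRUE) * 20, 20, 20)
  y <- matrix(sample(0:4, 400, TRUE) * 20, 20, 20)
  expect_equal(ssim_window(x, y, ssim_params(L = 80)),
               0.028399070197372, tolerance = 1e-13)

  expect_error(ssim_window(x, y[1:10, 1:10], ssim_params(L = 80)),
               "shape error")
  expect_error(ssim_window(x, y, ssim_params(L = 0)), "parameter error")
})

test_that("Hier_SSIM averages diagonal windows and honors the window grid", {
  p <- sim_params(chrom_length = 2.4e7, resolution = 1e4)
  h <- simulate_hierarchy(p, seed = 5)
  ra <- rasterize_hierarchy(h)
  expect_identical(hier_ssim(ra, ra), 1)

  # 2400 bins at 10 kb with an 8 Mb window -> exactly 3 full windows
  W <- HIER_SSIM_WINDOW_BP / 1e4
  expect_equal(length(seq(0, nrow(ra$pixels) - W, by = W)), 3L)

  hb <- perturb_hierarchy(h, shift_bins = 3, seed = 6)
  rb <- rasterize_hierarchy(assign_tad_levels(hb))
  v <- hier_ssim(ra, rb)
  expect_equal(hier_ssim(rb, ra), v)
  expect_true(v < 1 && v > -1)

  # manual average over the three diagonal blocks
  L <- max(ra$pixels, rb$pixels)
  manual <- mean(vapply(0:2, function(k) {
    idx <- (k * W + 1):((k + 1) * W)
    ssim_window(ra$pixels[idx, idx], rb$pixels[idx, idx], ssim_params(L))
  }, numeric(1)))
  expect_equal(v, manual)

  # content beyond the last full window is ignored
  p2 <- sim_params(chrom_length = 2.5e7, resolution = 1e4)
  h2 <- simulate_hierarchy(p2, seed = 5)
  ra2 <- rasterize_hierarchy(h2)
  rb2 <- ra2
  tail_idx <- (3 * W + 1):nrow(rb2$pixels)
  rb2$pixels[tail_idx, tail_idx] <- 0
  expect_identical(hier_ssim(ra2, rb2, L = max(ra2$pixels)), 1)

  # two empty rasters are identical, hence similarity 1
  e <- rasterize_hierarchy(validate_hierarchy(
    tad_hierarchy(resolution = 1e4, chrom_length = 2.4e7)))
  expect_identical(hier_ssim(e, e), 1)

  small <- rasterize_hierarchy(validate_hierarchy(
    tad_hierarchy(resolution = 1e4, chrom_length = 4e6)))
  expect_error(hier_ssim(small, small), "insufficient-extent")
  expect_error(hier_ssim(ra, rb, window_bp = 8e6 + 1), "parameter error")
})

test_that("overlap ratio is a Dice score on matched coding-tree nodes", {
  res <- 1e4
  mk <- function(s, e) validate_hierarchy(
    tad_hierarchy(s * res, e * res, resolution = res, chrom_length = 2e5))
  A <- mk(c(0, 0, 5), c(10, 5, 10))
  B <- mk(c(0, 0, 4), c(10, 5, 10))
  expect_equal(overlap_ratio(A, B), 2 * 2 / (3 + 3))
  expect_equal(overlap_ratio(A, A), 1)
  expect_equal(overlap_ratio(A, B), overlap_ratio(B, A))

  C <- mk(c(11, 14), c(14, 17))
  expect_equal(overlap_ratio(A, C), 0)

  # tolerance monotonicity: more slack can only add matches
  set.seed(9)
  for (rep in 1:10) {
    X <- random_interval_hierarchy(20)
    Y <- random_interval_hierarchy(20)
    ors <- vapply(c(0, 1, 2, 5), function(tol)
      overlap_ratio(X, Y, match_tolerance_bins = tol), numeric(1))
    expect_true(all(diff(ors) >= 0))
    expect_true(all(ors >= 0 & ors <= 1))
  }

  empty <- mk(numeric(), numeric())
  expect_equal(overlap_ratio(empty, empty), 1)
  expect_equal(overlap_ratio(A, empty), 0)
})

test_that("average-linkage clustering reproduces hand and library results", {
  # hand-computed UPGMA: d(A,B)=.1, d(A,C)=.4, d(B,C)=.5
  d <- matrix(c(0, .1, .4, .1, 0, .5, .4, .5, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  hc <- average_linkage_cluster(d, is_distance = TRUE)
  expect_equal(hc$height, c(0.1, 0.45))
  expect_equal(hclust_partitions(hc), list(c(1L, 2L), c(1L, 2L, 3L)))

  two <- matrix(c(0, .3, .3, 0), 2, 2)
  hc2 <- average_linkage_cluster(two, is_distance = TRUE)
  expect_equal(hc2$height, 0.3)

  ties <- matrix(0.2, 4, 4); diag(ties) <- 0
  hct <- average_linkage_cluster(ties, is_distance = TRUE)
  expect_equal(hct$height, rep(0.2, 3))
  # smallest-label tie break merges {1,2} first
  expect_equal(hclust_partitions(hct)[[1]], c(1L, 2L))

  # similarity input converts via d = 1 - s
  s <- similarity_matrix(1 - d)
  expect_equal(average_linkage_cluster(s)$height, c(0.1, 0.45))

  # equivalence with Lance-Williams recurrence and stats::hclust
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    d0 <- matrix(0, n, n)
    d0[upper.tri(d0)] <- runif(n * (n - 1) / 2)
    d0 <- d0 + t(d0)
    got <- average_linkage_cluster(d0, is_distance = TRUE)
    want <- oracle_upgma(d0)
    expect_equal(got$height, want$heights)
    expect_equal(hclust_partitions(got), want$partitions)
    ref <- hclust(as.dist(d0), method = "average")
    expect_equal(sort(got$height), sort(ref$height))
  }

  asym <- matrix(c(0, .1, .3, 0), 2, 2)
  expect_error(average_linkage_cluster(asym, is_distance = TRUE),
               "symmetry error")
})

test_that("dendrograms render as nested newick text", {
  d <- matrix(c(0, .1, .4, .1, 0, .5, .4, .5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  hc <- average_linkage_cluster(d, is_distance = TRUE)
  nwk <- cluster_newick(hc)
  expect_match(nwk, "^\\(.*\\):0\\.45;$")
  expect_match(nwk, "\\(x,y\\):0\\.1|\\(y,x\\):0\\.1")
})
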