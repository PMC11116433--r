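test_that("validation dedups, sorts, and rejects malformed records", {
  h <- tad_hierarchy(c(0, 0), c(100000, 100000),
                     resolution = 10000, chrom_length = 200000)
  expect_equal(nrow(validate_hierarchy(h)$records), 1L)

  expect_error(validate_hierarchy(
    tad_hierarchy(10050, 100000, resolution = 10000, chrom_length = 2e5)),
    "grid error")
  expect_error(validate_hierarchy(
    tad_hierarchy(50000, 50000, resolution = 10000, chrom_length = 2e5)),
    "interval error")
  expect_error(validate_hierarchy(
    tad_hierarchy(0, 300000, resolution = 10000, chrom_length = 2e5)),
    "bounds error")

  empty <- validate_hierarchy(
    tad_hierarchy(resolution = 10000, chrom_length = 2e5))
  expect_equal(nrow(empty$records), 0L)

  # deterministic (start asc, length desc) ordering
  h2 <- validate_hierarchy(tad_hierarchy(
    c(50000, 0, 0), c(100000, 50000, 100000),
    resolution = 10000, chrom_length = 2e5))
  expect_equal(h2$records$start, c(0, 0, 50000))
  expect_equal(h2$records$end, c(100000, 50000, 100000))
})

test_that("level assignment follows the longest strict-containment chain", {
  h <- assign_tad_levels(nested_demo_hierarchy())
  got <- h$records[order(h$records$start, h$records$end), ]
  expect_equal(got$level[got$start == 0 & got$end == 100000], 1L)
  expect_equal(got$level[got$start == 0 & got$end == 50000], 2L)
  expect_equal(got$level[got$start == 50000], 2L)
  expect_equal(got$level[got$start == 10000], 3L)

  single <- assign_tad_levels(validate_hierarchy(
    tad_hierarchy(0, 50000, resolution = 10000, chrom_length = 2e5)))
  expect_equal(single$records$level, 1L)

  # partial overlap is not containment
  partial <- assign_tad_levels(validate_hierarchy(tad_hierarchy(
    c(0, 40000), c(60000, 100000), resolution = 10000, chrom_length = 2e5)))
  expect_equal(partial$records$level, c(1L, 1L))
})

test_that("level assignment equals the brute-force oracle on random sets", {
  set.seed(101)
  for (rep in 1:50) {
    h <- random_interval_hierarchy(sample(1:120, 1))
    fast <- assign_tad_levels(h)
    expect_identical(fast$records$level,
                     oracle_levels(fast$records$start, fast$records$end))
  }
})

test_that("in a perfectly nested set level is 1 + number of containers", {
  set.seed(7)
  # nested chain with random siblings
  starts <- c(0, 10000, 20000, 30000)
  ends <- c(200000, 190000, 180000, 170000)
  h <- assign_tad_levels(validate_hierarchy(
    tad_hierarchy(starts, ends, resolution = 10000, chrom_length = 2e5)))
  r <- h$records
  n_containers <- vapply(seq_len(nrow(r)), function(i)
    sum(r$start <= r$start[i] & r$end >= r$end[i]) - 1L, integer(1))
  expect_equal(r$level, n_containers + 1L)
})

test_that("boundary levels tally start/end multiplicity per position", {
  h <- nested_demo_hierarchy()
  b <- assign_boundary_levels(h)
  expect_equal(b$level[b$position == 0], 2L)
  expect_equal(b$level[b$position == 100000], 2L)
  expect_equal(b$level[b$position %in% c(10000, 40000, 50000)],
               rep(1L, 3))
  expect_true(all(b$level >= 1L))

  one <- assign_boundary_levels(validate_hierarchy(
    tad_hierarchy(0, 50000, resolution = 10000, chrom_length = 2e5)))
  expect_equal(one$level, c(1L, 1L))

  expect_equal(nrow(assign_boundary_levels(validate_hierarchy(
    tad_hierarchy(resolution = 1e4, chrom_length = 2e5)))), 0L)

  # number of starts summed over positions equals the number of records
  set.seed(11)
  for (rep in 1:10) {
    h <- random_interval_hierarchy(40)
    b <- assign_boundary_levels(h)
    n_starts <- vapply(b$position, function(p)
      sum(h$records$start == p), integer(1))
    expect_equal(sum(n_starts), nrow(h$records))
  }
})

test_that("size filter uses inclusive bounds and re-assigns levels", {
  h <- validate_hierarchy(tad_hierarchy(
    c(0, 0, 0, 0), c(20000, 30000, 2e6, 2.01e6),
    resolution = 10000, chrom_length = 3e6))
  f <- filter_by_size(h)
  expect_setequal(f$records$end - f$records$start, c(30000, 2e6))

  expect_equal(filter_by_size(h, 0, Inf)$records[c("start", "end")],
               h$records[c("start", "end")])
  expect_error(filter_by_size(h, 100, 50), "parameter error")

  # surviving child is promoted to level 1 when its parent is removed
  nested <- validate_hierarchy(tad_hierarchy(
    c(0, 10000), c(2.5e6, 110000), resolution = 10000, chrom_length = 3e6))
  f2 <- filter_by_size(nested)
  expect_equal(nrow(f2$records), 1L)
  expect_equal(f2$records$level, 1L)
  expect_identical(f2$records$level,
                   oracle_levels(f2$records$start, f2$records$end))

  # idempotence
  expect_equal(filter_by_size(filter_by_size(h))$records,
               filter_by_size(h)$records)
})

test_that("genomic coverage is the union fraction of the chromosome", {
  h <- validate_hierarchy(tad_hierarchy(
    c(0, 200000), c(300000, 500000), resolution = 100000,
    chrom_length = 1e6))
  expect_equal(genomic_coverage(h), 0.5)

  expect_equal(genomic_coverage(validate_hierarchy(
    tad_hierarchy(resolution = 1e4, chrom_length = 1e6))), 0)

  nested <- nested_demo_hierarchy()
  expect_equal(genomic_coverage(nested), 0.5)

  # invariant to adding a record inside the union; exact for one record
  h1 <- validate_hierarchy(tad_hierarchy(0, 120000, resolution = 1e4,
                                         chrom_length = 4e5))
  expect_equal(genomic_coverage(h1), 120000 / 4e5)
  h2 <- validate_hierarchy(tad_hierarchy(c(0, 30000), c(120000, 70000),
                                         resolution = 1e4,
                                         chrom_length = 4e5))
  expect_equal(genomic_coverage(h2), genomic_coverage(h1))

  # multi-sample aggregation is the mean of per-sample coverages
  expect_equal(genomic_coverage(list(h1, nested)),
               mean(c(genomic_coverage(h1), genomic_coverage(nested))))

  bad <- tad_hierarchy(resolution = 1e4, chrom_length = 0)
  expect_error(genomic_coverage(bad), "parameter error")
})

test_that("level distribution counts and percentages are consistent", {
  h <- assign_tad_levels(nested_demo_hierarchy())
  ld <- level_distribution(h)
  expect_equal(ld$n_tads, c(1L, 2L, 1L))
  expect_equal(ld$pct_tads, c(25, 50, 25))
  expect_equal(sum(ld$pct_tads), 100, tolerance = 1e-9)
  expect_equal(sum(ld$pct_boundaries), 100, tolerance = 1e-9)

  flat <- assign_tad_levels(validate_hierarchy(tad_hierarchy(
    c(0, 100000), c(50000, 150000), resolution = 10000,
    chrom_length = 2e5)))
  ldf <- level_distribution(flat)
  expect_equal(ldf$pct_tads, 100)

  empty <- validate_hierarchy(tad_hierarchy(resolution = 1e4,
                                            chrom_length = 2e5))
  expect_equal(nrow(level_distribution(empty)), 0L)
})
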