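#' Hierarchical TAD call container
#'
#' A `tad_hierarchy` holds a set of (possibly nested) topologically
#' associating domain (TAD) intervals on one chromosome at a fixed bin
#' resolution. Coordinates are 0-based, half-open base pairs, snapped to the
#' resolution grid, so `bin = coordinate / resolution` is exact.
#'
#' Levels follow the outside-in convention: level 1 for domains that do not
#' belong to any larger domain, increasing by 1 for each nested layer.
#'
#' @param starts,ends Integer-valued bp coordinates (0-based, half-open).
#' @param levels Optional positive integer nesting levels; `NA` when unset.
#' @param chrom Chromosome identifier.
#' @param resolution Bin size in bp.
#' @param chrom_length Chromosome length in bp.
#' @return An object of class `tad_hierarchy` with elements `chrom`,
#'   `resolution`, `chrom_length` and `records` (a data.frame with columns
#'   `start`, `end`, `level`).
#' @examples
#' h <- tad_hierarchy(c(0, 0, 50000, 10000), c(100000, 50000, 100000, 40000),
#'                    resolution = 10000, chrom_length = 200000)
#' h <- assign_tad_levels(validate_hierarchy(h))
#' h$records
#' @export
tad_hierarchy <- function(starts = numeric(), ends = numeric(), levels = NULL,
                          chrom = "chr1", resolution, chrom_length) {
  if (missing(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive bin size in bp")
  if (missing(chrom_length) || length(chrom_length) != 1L)
    stop("`chrom_length` must be given (bp)")
  if (length(starts) != length(ends))
    stop("`starts` and `ends` must have equal length")
  if (is.null(levels)) levels <- rep(NA_integer_, length(starts))
  if (length(levels) != length(starts))
    stop("`levels` must match `starts` in length")
  structure(
    list(chrom = as.character(chrom),
         resolution = as.numeric(resolution),
         chrom_length = as.numeric(chrom_length),
         records = data.frame(start = as.numeric(starts),
                              end = as.numeric(ends),
                              level = as.integer(levels)),
         validated = FALSE),
    class = "tad_hierarchy")
}

#' @export
print.tad_hierarchy <- function(x, ...) {
  cat(sprintf("tad_hierarchy: %s, %d records, resolution %g bp, length %g bp\n",
              x$chrom, nrow(x$records), x$resolution, x$chrom_length))
  lv <- x$records$level
  if (nrow(x$records) && !anyNA(lv))
    cat(sprintf("  levels: %s\n",
                paste(sprintf("%d:%d", as.integer(names(table(lv))),
                              as.integer(table(lv))), collapse = " ")))
  invisible(x)
}

#' Number of bins spanned by a hierarchy's chromosome
#' @param h A `tad_hierarchy`.
#' @return Integer bin count `ceiling(chrom_length / resolution)`.
#' @export
n_bins <- function(h) as.integer(ceiling(h$chrom_length / h$resolution))

#' Validate and canonicalize a TAD hierarchy
#'
#' Checks every record against the container's invariants, removes duplicate
#' `(start, end)` pairs, and sorts records by (start ascending, length
#' descending) so that downstream operations are deterministic.
#'
#' @param h A `tad_hierarchy`.
#' @return The canonical hierarchy, marked validated.
#' @export
validate_hierarchy <- function(h) {
  stopifnot(inherits(h, "tad_hierarchy"))
  r <- h$records
  if (nrow(r)) {
    bad <- r$end <= r$start
    if (any(bad))
      stop(sprintf("interval error: end <= start for %d record(s), first at row %d",
                   sum(bad), which(bad)[1L]))
    if (any(r$start < 0))
      stop("bounds error: negative start coordinate")
    off <- (r$start %% h$resolution != 0) | (r$end %% h$resolution != 0)
    if (any(off))
      stop(sprintf("grid error: coordinate not a multiple of resolution %g (first at row %d)",
                   h$resolution, which(off)[1L]))
    if (any(r$end > h$chrom_length))
      stop("bounds error: record exceeds chrom_length")
    r <- r[!duplicated(r[c("start", "end")]), , drop = FALSE]
    r <- r[order(r$start, -(r$end - r$start)), , drop = FALSE]
    rownames(r) <- NULL
  }
  h$records <- r
  h$validated <- TRUE
  h
}

.check_validated <- function(h) {
  stopifnot(inherits(h, "tad_hierarchy"))
  if (!isTRUE(h$validated)) h <- validate_hierarchy(h)
  h
}

#' Assign nesting levels to TAD records
#'
#' Level of a domain T is 1 plus the length of the longest chain of records
#' strictly containing T (strict containment: contained in and not equal).
#' Outermost domains therefore get level 1, and the level increases by one
#' per nested layer. Partial (non-nested) overlaps never contribute, so
#' outputs of callers that emit overlapping, non-nested domains still get
#' well-defined levels. On a properly nested set this reduces to 1 + the
#' number of strict containers.
#'
#' @param h A validated `tad_hierarchy` (validated automatically otherwise).
#' @return The hierarchy with `records$level` filled in.
#' @export
assign_tad_levels <- function(h) {
  h <- .check_validated(h)
  r <- h$records
  n <- nrow(r)
  if (n == 0L) return(h)
  w <- r$end - r$start
  ord <- order(-w, r$start)        # width-descending: containers come first
  lev <- integer(n)
  s <- r$start; e <- r$end
  for (k in seq_len(n)) {
    i <- ord[k]
    if (k == 1L) { lev[i] <- 1L; next }
    prev <- ord[seq_len(k - 1L)]
    inside <- s[prev] <= s[i] & e[i] <= e[prev] &
      !(s[prev] == s[i] & e[prev] == e[i])
    lev[i] <- if (any(inside)) max(lev[prev[inside]]) + 1L else 1L
  }
  h$records$level <- lev
  h
}

#' Boundary positions and their levels
#'
#' Each distinct coordinate appearing as a record start or end is a boundary.
#' Its level is the maximum of the number of domains starting there and the
#' number ending there (the single-direction maximum rule), so a boundary
#' shared by several nested domains on one side gets a correspondingly
#' higher level.
#'
#' @param h A validated `tad_hierarchy`.
#' @return A data.frame with columns `position` (bp) and `level`, sorted by
#'   position.
#' @export
assign_boundary_levels <- function(h) {
  h <- .check_validated(h)
  r <- h$records
  if (nrow(r) == 0L)
    return(data.frame(position = numeric(), level = integer()))
  pos <- sort(unique(c(r$start, r$end)))
  ns <- tabulate(match(r$start, pos), nbins = length(pos))
  ne <- tabulate(match(r$end, pos), nbins = length(pos))
  data.frame(position = pos, level = pmax(ns, ne))
}

#' Filter TAD records by segment length
#'
#' Retains records whose length lies in `[min_len, max_len]` (inclusive
#' bounds); the defaults remove segments shorter than 30 kb or longer than
#' 2 Mb, the size range generally considered for TADs and subTADs. Levels
#' are re-assigned on the survivors, since removing an outer domain promotes
#' its children.
#'
#' @param h A validated `tad_hierarchy`.
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return The filtered hierarchy with fresh levels.
#' @export
filter_by_size <- function(h, min_len = 30000, max_len = 2e6) {
  if (min_len > max_len) stop("parameter error: min_len > max_len")
  h <- .check_validated(h)
  len <- h$records$end - h$records$start
  h$records <- h$records[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(h$records) <- NULL
  assign_tad_levels(h)
}

#' Fraction of the chromosome covered by TADs
#'
#' The union of all record intervals divided by the chromosome length;
#' equivalently 1 minus the complement fraction. For a list of hierarchies
#' (e.g. one per sample) the arithmetic mean of per-sample coverages is
#' returned.
#'
#' @param h A `tad_hierarchy` or a list of them.
#' @return Coverage fraction in `[0, 1]`.
#' @export
genomic_coverage <- function(h) {
  if (is.list(h) && !inherits(h, "tad_hierarchy"))
    return(mean(vapply(h, genomic_coverage, numeric(1))))
  h <- .check_validated(h)
  if (is.na(h$chrom_length) || h$chrom_length <= 0)
    stop("parameter error: chrom_length unset or not positive")
  r <- h$records
  if (nrow(r) == 0L) return(0)
  ir <- IRanges::IRanges(start = as.integer(r$start) + 1L,
                         end = as.integer(r$end))
  sum(IRanges::width(IRanges::reduce(ir))) / h$chrom_length
}

#' Per-level counts and percentages of TADs and boundaries
#'
#' @param h A `tad_hierarchy` with levels assigned.
#' @param b Optionally, a boundary data.frame from
#'   [assign_boundary_levels()]; computed from `h` when omitted.
#' @return A data.frame with one row per level: `level`, `n_tads`,
#'   `pct_tads`, `n_boundaries`, `pct_boundaries`. Percentages are on the
#'   0-100 scale and sum to 100 within each populated column.
#' @export
level_distribution <- function(h, b = NULL) {
  h <- .check_validated(h)
  if (nrow(h$records) && anyNA(h$records$level)) h <- assign_tad_levels(h)
  if (is.null(b)) b <- assign_boundary_levels(h)
  tl <- h$records$level
  levels <- sort(unique(c(tl, b$level)))
  if (length(levels) == 0L)
    return(data.frame(level = integer(), n_tads = integer(),
                      pct_tads = numeric(), n_boundaries = integer(),
                      pct_boundaries = numeric()))
  nt <- vapply(levels, function(l) sum(tl == l), integer(1))
  nb <- vapply(levels, function(l) sum(b$level == l), integer(1))
  data.frame(level = levels,
             n_tads = nt,
             pct_tads = if (sum(nt)) 100 * nt / sum(nt) else rep(0, length(nt)),
             n_boundaries = nb,
             pct_boundaries = if (sum(nb)) 100 * nb / sum(nb)
                              else rep(0, length(nb)))
}
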