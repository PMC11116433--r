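#' Describe the dialect of a TAD call file
#'
#' Caller outputs differ in whether coordinates are base pairs or bin
#' indices, whether bins count from 0 or 1, whether a level column is
#' present, and whether levels are encoded as one file per level.
#'
#' @param unit `"bp"` or `"bin"`. Bin-unit end coordinates are inclusive bin
#'   indices and are converted to half-open bp internally.
#' @param bin_base First bin index, 0 or 1 (ignored for bp input).
#' @param has_level Whether a third/level column is present.
#' @param per_level_files Whether levels come from file rank (one file per
#'   level) instead of a column.
#' @return A `call_dialect` list.
#' @export
call_dialect <- function(unit = c("bp", "bin"), bin_base = 0,
                         has_level = TRUE, per_level_files = FALSE) {
  unit <- match.arg(unit)
  if (!bin_base %in% c(0, 1)) stop("bin_base must be 0 or 1")
  if (per_level_files) has_level <- FALSE
  structure(list(unit = unit, bin_base = bin_base, has_level = has_level,
                 per_level_files = per_level_files), class = "call_dialect")
}

.read_numeric_table <- function(path, min_cols, drop_leading_chrom = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) return(NULL)
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (drop_leading_chrom) {
    # tolerate a leading chromosome-name column (the canonical 4-column form)
    fields <- lapply(fields, function(f)
      if (length(f) > min_cols && is.na(suppressWarnings(as.numeric(f[1L]))))
        f[-1L] else f)
  }
  ncol <- lengths(fields)
  if (any(ncol < min_cols))
    stop(sprintf("parse error: line %d has %d field(s), expected >= %d",
                 which(ncol < min_cols)[1L], min(ncol), min_cols))
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- vapply(vals, anyNA, logical(1))
  if (any(bad))
    stop(sprintf("parse error: non-numeric field at line %d", which(bad)[1L]))
  do.call(rbind, lapply(vals, function(v) v[seq_len(min_cols)]))
}

#' Read TAD calls in a generic 2/3-column dialect
#'
#' Harmonizes heterogeneous caller outputs into the canonical container:
#' whitespace/tab-separated columns start, end (and optionally level),
#' either in bp or in bin units. Bin units are converted by
#' `start_bp = (start_bin - bin_base) * resolution` and
#' `end_bp = (end_bin - bin_base + 1) * resolution` (inclusive end bins).
#' For per-level dialects, pass one path per level; the file's rank is its
#' level. Missing levels are left unset; run [assign_tad_levels()].
#'
#' @param paths One path, or several for per-level dialects.
#' @param dialect A [call_dialect()].
#' @param resolution,chrom_length Bin size and chromosome length in bp.
#' @param chrom Chromosome label for the result.
#' @return A validated `tad_hierarchy`.
#' @export
read_tad_calls <- function(paths, dialect = call_dialect(), resolution,
                           chrom_length, chrom = "chr1") {
  stopifnot(inherits(dialect, "call_dialect"))
  if (dialect$per_level_files) {
    parts <- lapply(seq_along(paths), function(i) {
      m <- .read_numeric_table(paths[i], 2L)
      if (is.null(m)) return(NULL)
      cbind(m, i)
    })
    m <- do.call(rbind, parts)
  } else {
    m <- .read_numeric_table(paths[1L], if (dialect$has_level) 3L else 2L,
                             drop_leading_chrom = TRUE)
    if (!is.null(m) && !dialect$has_level) m <- cbind(m, NA_real_)
  }
  if (is.null(m))
    return(validate_hierarchy(tad_hierarchy(
      resolution = resolution, chrom_length = chrom_length, chrom = chrom)))
  start <- m[, 1L]; end <- m[, 2L]; level <- m[, 3L]
  if (any(start < 0) || any(end < 0))
    stop("bounds error: negative coordinate in input")
  if (dialect$unit == "bin") {
    start <- (start - dialect$bin_base) * resolution
    end <- (end - dialect$bin_base + 1) * resolution
  }
  validate_hierarchy(tad_hierarchy(start, end, as.integer(level),
                                   chrom = chrom, resolution = resolution,
                                   chrom_length = chrom_length))
}

#' Write TAD calls in the canonical 4-column format
#'
#' Tab-separated columns chrom, start, end, level; records sorted by
#' (start, -length). Round-trips exactly through [read_tad_calls()] with
#' the default bp dialect.
#'
#' @param h A validated `tad_hierarchy` with levels.
#' @param path Output file path.
#' @export
write_tad_calls <- function(h, path) {
  h <- .check_validated(h)
  r <- h$records
  lines <- sprintf("%s\t%s\t%s\t%s", h$chrom,
                   format(r$start, scientific = FALSE, trim = TRUE),
                   format(r$end, scientific = FALSE, trim = TRUE),
                   ifelse(is.na(r$level), "NA", as.character(r$level)))
  writeLines(lines, path)
  invisible(path)
}

#' Write boundaries as BED3
#'
#' Each boundary occupies one bin: `[position, position + resolution)`,
#' with the boundary level in the score column.
#'
#' @param b Boundary data.frame from [assign_boundary_levels()].
#' @param h The hierarchy the boundaries came from (for chrom/resolution).
#' @param path Output file path.
#' @export
write_boundaries_bed <- function(b, h, path) {
  lines <- sprintf("%s\t%s\t%s\t.\t%d", h$chrom,
                   format(b$position, scientific = FALSE, trim = TRUE),
                   format(b$position + h$resolution, scientific = FALSE,
                          trim = TRUE),
                   b$level)
  writeLines(lines, path)
  invisible(path)
}

#' Read a sparse intra-chromosomal contact matrix
#'
#' Three whitespace-separated columns i, j, count. In the `bin_pairs`
#' dialect i and j are 0-based bin indices; in the `coordinate_pairs`
#' ("Rao format") dialect they are genomic coordinates, mapped to bins by
#' `floor(c / resolution)`. Duplicate entries are summed and `(i, j)` /
#' `(j, i)` pairs are folded to a symmetric matrix.
#'
#' @param path Input file.
#' @param dialect `"bin_pairs"` or `"coordinate_pairs"`.
#' @param resolution,chrom_length Bin size and chromosome length (bp).
#' @param chrom Chromosome label.
#' @return A `contact_matrix`.
#' @export
read_sparse_contacts <- function(path,
                                 dialect = c("bin_pairs", "coordinate_pairs"),
                                 resolution, chrom_length, chrom = "chr1") {
  dialect <- match.arg(dialect)
  nb <- as.integer(ceiling(chrom_length / resolution))
  m <- .read_numeric_table(path, 3L)
  cm <- matrix(0, nb, nb)
  if (!is.null(m)) {
    if (any(m[, 3L] < 0)) stop("value error: negative contact count")
    i <- m[, 1L]; j <- m[, 2L]
    if (dialect == "coordinate_pairs") {
      if (any(i >= chrom_length | j >= chrom_length) || any(i < 0 | j < 0))
        stop("bounds error: coordinate outside chromosome")
      i <- floor(i / resolution); j <- floor(j / resolution)
    } else if (any(i >= nb | j >= nb) || any(i < 0 | j < 0)) {
      stop("bounds error: bin index outside chromosome")
    }
    lo <- pmin(i, j); hi <- pmax(i, j)
    agg <- rowsum(m[, 3L], group = lo * nb + hi)
    key <- as.numeric(rownames(agg))
    li <- key %/% nb; hj <- key %% nb
    cm[cbind(li + 1, hj + 1)] <- agg[, 1L]
    cm[cbind(hj + 1, li + 1)] <- agg[, 1L]
  }
  contact_matrix(cm, resolution = resolution, chrom = chrom,
                 chrom_length = chrom_length)
}

#' Read a whitespace-separated dense contact matrix
#'
#' @param path Input file (square numeric matrix, symmetric to 1e-9).
#' @param resolution Bin size (bp).
#' @param chrom Chromosome label.
#' @return A `contact_matrix`.
#' @export
read_dense_contacts <- function(path, resolution, chrom = "chr1") {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m))
    stop(sprintf("shape error: dense matrix is %d x %d, expected square",
                 nrow(m), ncol(m)))
  if (max(abs(m - t(m))) > 1e-9)
    stop("symmetry error: dense matrix asymmetric beyond 1e-9")
  contact_matrix((m + t(m)) / 2, resolution = resolution, chrom = chrom)
}

#' Write a contact matrix as sparse upper-triangle text
#'
#' Emits one `i j count` line (0-based bin indices, i <= j) per nonzero
#' entry. Round-trips exactly through [read_sparse_contacts()].
#'
#' @param m A `contact_matrix`.
#' @param path Output file path.
#' @export
write_sparse_contacts <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  x <- m$counts
  idx <- which(upper.tri(x, diag = TRUE) & x != 0, arr.ind = TRUE)
  lines <- sprintf("%d\t%d\t%s", idx[, 1L] - 1L, idx[, 2L] - 1L,
                   format(x[idx], scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Write a contact matrix as a whitespace dense matrix
#' @param m A `contact_matrix`.
#' @param path Output file path.
#' @export
write_dense_contacts <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  utils::write.table(m$counts, path, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path)
}

#' Read a bedGraph signal track onto the bin grid
#'
#' Per-bin values are the length-weighted mean of the overlapping bedGraph
#' intervals, treating uncovered bases as 0; bins with no covering interval
#' get 0. Overlapping input intervals on the same bases are rejected as
#' ambiguous.
#'
#' @param path 4-column bedGraph (chrom, start, end, value).
#' @param resolution,chrom_length Bin size and chromosome length (bp).
#' @param chrom Only intervals on this chromosome are used; `NULL` takes
#'   the first chromosome seen.
#' @return A `signal_track`: list with `chrom`, `resolution`, `values`
#'   (one per bin).
#' @export
read_signal_bedgraph <- function(path, resolution, chrom_length,
                                 chrom = NULL) {
  nb <- as.integer(ceiling(chrom_length / resolution))
  tab <- tryCatch(
    utils::read.table(path, header = FALSE,
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric")),
    error = function(e) NULL)
  vals <- numeric(nb)
  if (!is.null(tab) && nrow(tab)) {
    if (is.null(chrom)) chrom <- tab$chrom[1L]
    tab <- tab[tab$chrom == chrom, , drop = FALSE]
    tab <- tab[order(tab$start), , drop = FALSE]
    if (nrow(tab) > 1L && any(tab$start[-1L] < tab$end[-nrow(tab)]))
      stop("ambiguity error: overlapping bedGraph intervals")
    for (k in seq_len(nrow(tab))) {
      s <- tab$start[k]; e <- min(tab$end[k], chrom_length)
      if (e <= s) next
      b0 <- floor(s / resolution); b1 <- floor((e - 1) / resolution)
      for (b in b0:b1) {
        ov <- min(e, (b + 1) * resolution) - max(s, b * resolution)
        vals[b + 1L] <- vals[b + 1L] + tab$value[k] * ov / resolution
      }
    }
  }
  structure(list(chrom = if (is.null(chrom)) "chr1" else chrom,
                 resolution = as.numeric(resolution),
                 chrom_length = as.numeric(chrom_length),
                 values = vals),
            class = "signal_track")
}

#' Construct a signal track directly from per-bin values
#' @param values One numeric value per bin.
#' @param resolution Bin size (bp).
#' @param chrom Chromosome label.
#' @param chrom_length Chromosome length; defaults to a whole number of bins.
#' @return A `signal_track`.
#' @export
signal_track <- function(values, resolution, chrom = "chr1",
                         chrom_length = length(values) * resolution) {
  structure(list(chrom = chrom, resolution = as.numeric(resolution),
                 chrom_length = as.numeric(chrom_length),
                 values = as.numeric(values)),
            class = "signal_track")
}
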