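# Genomic intervals and their file formats.  All coordinates are 0-based
# half-open (BED convention) in every tibble; conversion to the 1-based
# closed convention happens only at the GRanges boundary.

as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_tibble <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

validate_intervals <- function(x, genome = NULL, what = "interval set") {
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    rlang::abort(paste0(what, " is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    rlang::abort(paste0(what, ": intervals must satisfy 0 <= start < end"))
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(x$chrom), genome$chrom)
    if (length(unknown) > 0) {
      rlang::abort(paste0(what, ": unknown chromosome(s): ",
                          paste(unknown, collapse = ", ")))
    }
    len <- setNames(genome$length, genome$chrom)
    if (any(x$end > len[x$chrom])) {
      rlang::abort(paste0(what, ": interval extends beyond chromosome length"))
    }
  }
  dplyr::arrange(as_tibble(x), .data$chrom, .data$start, .data$end)
}

#' Read genomic intervals from a BED file
#'
#' Reads BED3+ (0-based half-open) via rtracklayer, validates the
#' records, and returns them sorted per chromosome.  Overlapping
#' intervals are preserved (no merging); see [merge_intervals()].
#'
#' @param path BED file path.
#' @param genome Optional chromosome-length tibble (`chrom`, `length`);
#'   when supplied, unknown chromosomes or out-of-bounds intervals are
#'   errors.
#' @return A tibble with `chrom`, `start`, `end` (and `name` when the
#'   file has one).
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  x <- granges_to_tibble(gr)
  if (!is.null(gr$name) && !all(is.na(gr$name))) x$name <- gr$name
  validate_intervals(x, genome, what = paste0("BED file ", path))
}

#' Write genomic intervals to a BED file
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x, what = "interval set")
  gr <- as_granges(x)
  if (!is.null(x[["name"]])) gr$name <- x[["name"]]
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a 4-column bedGraph as a value track
#'
#' @param path bedGraph file path.
#' @return A tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  x <- granges_to_tibble(gr)
  x$value <- as.numeric(gr$score)
  validate_intervals(x, what = paste0("bedGraph file ", path))
}

#' Write a binned track as bedGraph
#'
#' @param track Track tibble with `chrom`, `start`, `end` and a value
#'   column (`value` or `count`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  value <- if (!is.null(track[["value"]])) track[["value"]] else track[["count"]]
  if (is.null(value)) rlang::abort("track needs a `value` or `count` column")
  gr <- as_granges(track)
  gr$score <- as.numeric(value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Merge overlapping or adjacent intervals
#'
#' @param x Interval tibble.
#' @return A tibble of disjoint intervals (union of the input).
#' @export
merge_intervals <- function(x) {
  x <- validate_intervals(x, what = "interval set")
  granges_to_tibble(GenomicRanges::reduce(as_granges(x)))
}

#' Complement of an interval set within a genome
#'
#' @param x Interval tibble.
#' @param genome Chromosome-length tibble (`chrom`, `length`).
#' @return Intervals covering every base of `genome` not covered by `x`.
#' @export
complement_intervals <- function(x, genome) {
  x <- validate_intervals(x, genome, what = "interval set")
  whole <- tibble(chrom = genome$chrom, start = 0L, end = genome$length)
  hits <- GenomicRanges::setdiff(as_granges(whole),
                                 GenomicRanges::reduce(as_granges(x)))
  validate_intervals(granges_to_tibble(hits), genome, what = "complement")
}

#' Read chromosome lengths
#'
#' Reads a two-column, headerless chrom-sizes TSV (`chrom`, `length`).
#'
#' @param path File path.
#' @return A tibble with `chrom` and `length`.
#' @export
read_genome <- function(path) {
  g <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "ci", progress = FALSE)
  if (any(is.na(g$length)) || any(g$length < 1)) {
    rlang::abort("chromosome lengths must be positive integers")
  }
  g
}

#' @rdname read_genome
#' @param genome Chromosome-length tibble.
#' @export
write_genome <- function(genome, path) {
  readr::write_tsv(genome[c("chrom", "length")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
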