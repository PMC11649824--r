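#' Construct a table of single-nucleotide site records
#'
#' Sites (crosslink positions, called peaks, m6A positions, editing
#' positions) share one representation: a data frame with columns
#' `chrom`, `pos` (0-based single nucleotide), `strand` (`+`/`-`),
#' `score` (non-negative) and `sample_id`.
#'
#' @param chrom character chromosome names
#' @param pos integer 0-based positions
#' @param strand `+` or `-`
#' @param score non-negative numeric scores (crosslink counts, peak scores,
#'   model probabilities, ...)
#' @param sample_id sample/replicate label, `""` if not applicable
#' @return a `data.frame` of class `site_records`
#' @export
site_records <- function(chrom = character(), pos = integer(),
                         strand = character(), score = numeric(),
                         sample_id = "") {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  score <- rep_len(as.numeric(score), n)
  sample_id <- rep_len(as.character(sample_id), n)
  .stop_if(any(pos < 0), "site positions must be >= 0")
  .stop_if(any(!strand %in% c("+", "-")), "strand must be '+' or '-'")
  .stop_if(any(score < 0), "scores must be >= 0")
  df <- data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
                   score = score, sample_id = sample_id,
                   stringsAsFactors = FALSE)
  class(df) <- c("site_records", "data.frame")
  df
}

.as_site_records <- function(df) {
  class(df) <- c("site_records", "data.frame")
  rownames(df) <- NULL
  df
}

#' Sort sites deterministically by (chrom, pos, strand, sample)
#' @param sites a `site_records` data frame
#' @return the sorted sites
#' @export
sort_sites <- function(sites) {
  .as_site_records(sites[order(sites$chrom, sites$pos, sites$strand,
                               sites$sample_id), , drop = FALSE])
}

#' Read single-nucleotide sites from a 6-column BED file
#'
#' Strict BED6 reader for site-like records. Each record must span exactly
#' one nucleotide (`end == start + 1`) unless `kind = "interval"`.
#'
#' @param path path to a BED6 file
#' @param kind `"site"` (default; enforces single-nucleotide records) or
#'   `"interval"` (returns an interval data frame)
#' @return a `site_records` data frame (`kind = "site"`), or a data frame
#'   with `chrom,start,end,name,score,strand` (`kind = "interval"`)
#' @export
read_sites <- function(path, kind = c("site", "interval")) {
  kind <- match.arg(kind)
  .stop_if(!file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(if (kind == "site") site_records() else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 name = character(), score = numeric(), strand = character(),
                 stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  .stop_if(length(bad) > 0L,
           sprintf("malformed BED line %d in %s: expected >= 6 tab-separated fields, got %d",
                   bad[1L], path, nf[bad[1L]]))
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  score <- suppressWarnings(as.numeric(m[, 5L]))
  badnum <- which(is.na(start) | is.na(end) | is.na(score))
  .stop_if(length(badnum) > 0L,
           sprintf("malformed BED line %d in %s: non-numeric start/end/score",
                   badnum[1L], path))
  .stop_if(any(m[, 6L] != "+" & m[, 6L] != "-"),
           sprintf("malformed BED line %d in %s: strand must be '+' or '-'",
                   which(m[, 6L] != "+" & m[, 6L] != "-")[1L], path))
  if (kind == "interval") {
    .stop_if(any(start >= end), "interval records require start < end")
    return(data.frame(chrom = m[, 1L], start = start, end = end,
                      name = m[, 4L], score = score, strand = m[, 6L],
                      stringsAsFactors = FALSE))
  }
  notsingle <- which(end != start + 1L)
  .stop_if(length(notsingle) > 0L,
           sprintf("BED line %d in %s: single-nucleotide record required (end = start + 1)",
                   notsingle[1L], path))
  site_records(chrom = m[, 1L], pos = start, strand = m[, 6L],
               score = score, sample_id = m[, 4L])
}

#' Write sites to BED6 with deterministic ordering
#'
#' Records are sorted by (chrom, pos, strand, sample) and written as
#' single-nucleotide BED6 lines (`end = pos + 1`; the `name` column holds
#' the sample id, `.` if empty).
#'
#' @param sites a `site_records` data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sites <- function(sites, path) {
  s <- sort_sites(sites)
  nm <- ifelse(nzchar(s$sample_id), s$sample_id, ".")
  out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", s$chrom, s$pos, s$pos + 1L,
                 nm, formatC(s$score, format = "g", digits = 15), s$strand)
  writeLines(out, path)
  invisible(path)
}

#' Write genomic intervals to BED6
#' @param intervals data frame with `chrom,start,end,name,score,strand`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_intervals <- function(intervals, path) {
  .stop_if(any(intervals$start >= intervals$end), "intervals require start < end")
  o <- order(intervals$chrom, intervals$start, intervals$strand)
  s <- intervals[o, , drop = FALSE]
  out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", s$chrom, as.integer(s$start),
                 as.integer(s$end), as.character(s$name),
                 formatC(s$score, format = "g", digits = 15), s$strand)
  writeLines(out, path)
  invisible(path)
}

# site_records -> GRanges (1-based internally to GRanges, width 1)
.sites_gr <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L),
    strand = sites$strand)
}
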