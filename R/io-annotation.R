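#' Transcript annotation table
#'
#' A transcript model is stored as rows of one table: columns `gene_id`,
#' `chrom`, `strand`, `feature` (`utr5`, `cds`, `utr3`), `start`, `end`
#' (0-based half-open genomic) and `representative` (logical). Within one
#' gene the feature intervals must be disjoint.
#'
#' @param df data frame with the columns above
#' @return validated annotation of class `transcript_annotation`
#' @export
transcript_annotation <- function(df) {
  need <- c("gene_id", "chrom", "strand", "feature", "start", "end")
  .stop_if(!all(need %in% names(df)), "annotation needs columns: ",
           paste(need, collapse = ", "))
  if (is.null(df$representative)) df$representative <- TRUE
  .stop_if(any(!df$feature %in% c("utr5", "cds", "utr3")),
           "feature must be one of utr5/cds/utr3")
  .stop_if(any(df$start >= df$end), "feature intervals require start < end")
  .stop_if(any(!df$strand %in% c("+", "-")), "strand must be '+' or '-'")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  # intervals within one gene must be pairwise disjoint
  for (g in unique(df$gene_id)) {
    sub <- df[df$gene_id == g, , drop = FALSE]
    o <- order(sub$start)
    s <- sub$start[o]; e <- sub$end[o]
    if (length(s) > 1L && any(s[-1L] < e[-length(e)]))
      stop("overlapping feature intervals in gene ", g, call. = FALSE)
  }
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("transcript_annotation", "data.frame")
  df
}

#' Read transcript annotation from GFF3 or the simplified TSV dialect
#'
#' GFF3 input must tag features as `five_prime_UTR`, `CDS` and
#' `three_prime_UTR`; 1-based closed coordinates are converted to 0-based
#' half-open. The TSV dialect has explicit columns
#' `gene_id, chrom, strand, feature, start, end, representative`
#' already in 0-based half-open coordinates.
#'
#' @param path input file
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`
#' @param representative_only keep only representative models (default TRUE)
#' @return a [transcript_annotation()] table
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "tsv"),
                            representative_only = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (is.null(df$representative)) df$representative <- TRUE
    df$representative <- as.logical(df$representative)
  } else {
    gr <- rtracklayer::import(path)
    keep <- as.character(gr$type) %in%
      c("five_prime_UTR", "CDS", "three_prime_UTR")
    gr <- gr[keep]
    feat <- c(five_prime_UTR = "utr5", CDS = "cds",
              three_prime_UTR = "utr3")[as.character(gr$type)]
    gid <- if (!is.null(gr$Parent) && any(lengths(gr$Parent) > 0)) {
      vapply(gr$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
             character(1))
    } else if (!is.null(gr$ID)) as.character(gr$ID) else
      stop("GFF3 features carry neither Parent nor ID attributes")
    # strip a transcript suffix like ".1" to a gene id
    gid <- sub("\\.\\d+$", "", gid)
    df <- data.frame(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      feature = unname(feat),
      start = GenomicRanges::start(gr) - 1L,  # 1-based closed -> 0-based half-open
      end = GenomicRanges::end(gr),
      representative = TRUE,
      stringsAsFactors = FALSE)
  }
  if (representative_only) df <- df[df$representative, , drop = FALSE]
  transcript_annotation(df)
}

#' Write annotation as the simplified TSV dialect
#' @param annotation a [transcript_annotation()] table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotation_tsv <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write annotation as GFF3
#' @param annotation a [transcript_annotation()] table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotation_gff3 <- function(annotation, path) {
  type <- c(utr5 = "five_prime_UTR", cds = "CDS",
            utr3 = "three_prime_UTR")[annotation$feature]
  lines <- sprintf("%s\tcoreader\t%s\t%d\t%d\t.\t%s\t.\tID=%s.f%d;Parent=%s.1",
                   annotation$chrom, type, annotation$start + 1L,
                   annotation$end, annotation$strand, annotation$gene_id,
                   seq_len(nrow(annotation)), annotation$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# GRanges of feature intervals, metadata gene_id/feature/feature row index
.annotation_gr <- function(annotation) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$gene_id <- annotation$gene_id
  S4Vectors::mcols(gr)$feature <- annotation$feature
  gr
}

# one GRanges per gene spanning all its features
.gene_gr <- function(annotation) {
  sp <- split(seq_len(nrow(annotation)), annotation$gene_id)
  gid <- names(sp)
  st <- vapply(sp, function(i) min(annotation$start[i]), integer(1))
  en <- vapply(sp, function(i) max(annotation$end[i]), integer(1))
  ch <- vapply(sp, function(i) annotation$chrom[i[1]], character(1))
  sd <- vapply(sp, function(i) annotation$strand[i[1]], character(1))
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(st + 1L, en), strand = sd)
  S4Vectors::mcols(gr)$gene_id <- gid
  gr
}

#' Locate sites within annotated transcript features
#'
#' Maps each site to a containing (gene, feature) and the transcript-
#' oriented offset within that feature (0-based from the feature's 5'
#' end; minus-strand genes are flipped). Sites overlapping no feature get
#' `NA` annotations. When a site falls in features of several genes the
#' first gene in annotation order is used (see
#' [annotate_positions_to_genes()] for expression-prioritized assignment).
#'
#' @param sites a `site_records` data frame
#' @param annotation a [transcript_annotation()] table
#' @return `sites` with added columns `gene_id`, `feature`,
#'   `feature_offset`, `feature_length`, `frac`
#' @export
locate_sites <- function(sites, annotation) {
  gr_s <- .sites_gr(sites)
  gr_a <- .annotation_gr(annotation)
  hits <- GenomicRanges::findOverlaps(gr_s, gr_a)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  first <- !duplicated(q)
  q <- q[first]; s <- s[first]
  n <- nrow(sites)
  gene_id <- rep(NA_character_, n); feature <- rep(NA_character_, n)
  off <- rep(NA_integer_, n); flen <- rep(NA_integer_, n)
  gene_id[q] <- annotation$gene_id[s]
  feature[q] <- annotation$feature[s]
  # total feature length and transcript-oriented offset, supporting
  # multi-interval features
  key <- paste(annotation$gene_id, annotation$feature)
  lens <- tapply(annotation$end - annotation$start, key, sum)
  flen[q] <- as.integer(lens[paste(annotation$gene_id[s], annotation$feature[s])])
  for (idx in seq_along(q)) {
    i <- q[idx]; row <- s[idx]
    g <- annotation$gene_id[row]; f <- annotation$feature[row]
    sub <- annotation[annotation$gene_id == g & annotation$feature == f, ,
                      drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    p <- sites$pos[i]
    before <- sum(pmax(0L, pmin(sub$end, p) - sub$start))
    off[i] <- if (annotation$strand[row] == "+") before else
      as.integer(sum(sub$end - sub$start) - before - 1L)
  }
  out <- sites
  out$gene_id <- gene_id
  out$feature <- feature
  out$feature_offset <- off
  out$feature_length <- flen
  out$frac <- ifelse(flen > 0L, off / flen, NA_real_)
  out
}
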