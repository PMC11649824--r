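#' Read a genome FASTA into a sequence store
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet] keyed by chromosome name
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome a [Biostrings::DNAStringSet]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Extract the sequence window around a site
#'
#' Returns the `2*flank + 1` nucleotides centered on a site, in transcript
#' orientation: minus-strand sites return the reverse complement, so the
#' center character is always the site nucleotide read 5'->3' on the
#' site's strand. Windows are taken from genomic (unspliced) sequence.
#'
#' @param genome a [Biostrings::DNAStringSet]
#' @param chrom,pos,strand site coordinates (vectorized; 0-based `pos`)
#' @param flank flank size in bp
#' @param pad if `TRUE` (default) out-of-bounds positions are filled with
#'   `N`; if `FALSE` such windows raise an error
#' @return character vector of sequences of length `2*flank + 1`
#' @export
extract_window <- function(genome, chrom, pos, strand, flank, pad = TRUE) {
  n <- length(pos)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  out <- character(n)
  w <- 2L * flank + 1L
  for (ch in unique(chrom)) {
    .stop_if(!ch %in% names(genome), "chromosome not in genome: ", ch)
    idx <- which(chrom == ch)
    L <- Biostrings::width(genome[ch])
    lo <- pos[idx] - flank          # 0-based inclusive
    hi <- pos[idx] + flank + 1L     # 0-based exclusive
    oob <- lo < 0L | hi > L
    .stop_if(!pad && any(oob), "window out of chromosome bounds at pos ",
             pos[idx][oob][1])
    clo <- pmax(lo, 0L); chi <- pmin(hi, L)
    core <- as.character(Biostrings::subseq(
      rep(genome[ch], length(idx)), start = clo + 1L, end = chi))
    left <- strrep("N", pmax(0L, -lo))
    right <- strrep("N", pmax(0L, hi - L))
    out[idx] <- paste0(left, core, right)
  }
  stopifnot(all(nchar(out) == w))
  minus <- strand == "-"
  if (any(minus))
    out[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[minus])))
  chartr("U", "T", toupper(out))
}

#' One-hot encode a nucleotide sequence
#'
#' Alphabet `A,C,G,T,U,N`; `U` is treated as `T`; `N` rows are all zero.
#'
#' @param seq a single nucleotide string
#' @return a `length x 4` matrix with columns `A,C,G,T`
#' @export
onehot_encode <- function(seq) {
  ch <- strsplit(chartr("U", "T", toupper(seq)), "", fixed = TRUE)[[1]]
  bad <- !ch %in% c("A", "C", "G", "T", "N")
  .stop_if(any(bad), "invalid character in sequence: ", ch[bad][1])
  m <- matrix(0, nrow = length(ch), ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  col <- match(ch, c("A", "C", "G", "T"))
  ok <- !is.na(col)
  m[cbind(which(ok), col[ok])] <- 1
  m
}

# batch one-hot: character vector of equal-length sequences -> array (L, 4, N)
.onehot_batch <- function(seqs) {
  L <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == L))
  ch <- unlist(strsplit(chartr("U", "T", toupper(seqs)), "", fixed = TRUE),
               use.names = FALSE)
  col <- match(ch, c("A", "C", "G", "T"))
  n <- length(seqs)
  x <- array(0, dim = c(L, 4L, n))
  pos <- rep(seq_len(L), times = n)
  samp <- rep(seq_len(n), each = L)
  ok <- !is.na(col)
  x[cbind(pos[ok], col[ok], samp[ok])] <- 1
  x
}

# motif planting: returns modified genome; motif given in transcript
# sense, written reverse-complemented on minus strand. 'at' is the
# 0-based genomic position of the motif start in transcript orientation
# (on minus strand, 'at' is the transcript-5' end, i.e. the genomic END
# of the motif). Later entries win where plants collide.
.plant_motif <- function(genome, chrom, at, strand, motif) {
  motif <- chartr("U", "T", toupper(motif))
  k <- nchar(motif)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  s <- ifelse(strand == "+", at + 1L, at - k + 2L)   # 1-based start
  ins <- ifelse(strand == "+", motif, rc)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    ok <- s[i] >= 1L & s[i] + k - 1L <= Biostrings::width(genome[ch])
    i <- i[ok]
    if (!length(i)) next
    # later plants overwrite earlier: reverse so the stable sort puts the
    # latest first, then greedily keep non-overlapping ranges
    i <- rev(i)
    keep <- rep(TRUE, length(i))
    o <- order(s[i])
    so <- s[i][o]
    kept_end <- -1L
    for (j in seq_along(o)) {
      if (so[j] > kept_end) kept_end <- so[j] + k - 1L
      else keep[o[j]] <- FALSE
    }
    i <- i[keep]
    if (!length(i)) next
    genome[[ch]] <- Biostrings::replaceAt(
      genome[[ch]],
      IRanges::IRanges(start = s[i], width = k),
      as.character(ins[i]))
  }
  genome
}
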