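#' @useDynLib helitronscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats density chisq.test runif setNames
#' @importFrom utils write.table read.table head tail
#' @keywords internal
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a (multi-)FASTA file of DNA sequences
#'
#' Sequences are uppercased and RNA `U` is normalised to `T`. Records are
#' returned as a named character vector (names = FASTA ids up to the first
#' whitespace). Malformed input (empty file, missing `>` header, characters
#' outside `A/C/G/T/N`) raises an error naming the offending line.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase DNA strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path, " (line 1)")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(trimws(first), ">"))
    stop("malformed FASTA: expected '>' header at line 1 of ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in FASTA file: ", path, " (line 1)")
  seqs <- toupper(chartr("Uu", "Tt", as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    # locate the first offending line for the error message
    lines <- readLines(path, warn = FALSE)
    off <- which(!startsWith(lines, ">") & grepl("[^ACGTNUacgtnu]", lines))[1]
    stop("invalid DNA character in record '", ids[bad][1], "'",
         if (!is.na(off)) paste0(" (line ", off, ")") else "")
  }
  if (any(nchar(seqs) == 0)) stop("empty sequence record in ", path)
  stats::setNames(seqs, ids)
}

#' Write DNA records to a FASTA file
#'
#' @param records named character vector of DNA strings.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(!is.null(names(records)), all(nzchar(names(records))))
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' Vectorised; `N` maps to `N`. An involution: `revcomp(revcomp(x)) == x`.
#'
#' @param dna character vector over A/C/G/T/N.
#' @return character vector of the same lengths.
#' @export
revcomp <- function(dna) {
  if (any(grepl("[^ACGTN]", dna))) stop("invalid DNA character in revcomp()")
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna))))
}

#' AT content of a DNA string
#'
#' Fraction (A + T) / (non-N length); `N` is excluded from both numerator and
#' denominator. All-N or empty input is an error.
#'
#' @param dna a single DNA string.
#' @return fraction in \[0, 1\].
#' @export
at_content <- function(dna) {
  stopifnot(length(dna) == 1L, nchar(dna) > 0L)
  s <- Biostrings::DNAString(dna)
  f <- Biostrings::letterFrequency(s, letters = c("A", "T", "N"))
  denom <- nchar(dna) - f[["N"]]
  if (denom == 0) stop("at_content(): sequence is all N")
  unname((f[["A"]] + f[["T"]]) / denom)
}

#' Six-frame translation
#'
#' Standard genetic code, stops as `*`. Frames `F1..F3` translate the input
#' with offsets 0..2; `R1..R3` translate the reverse complement likewise.
#' Trailing partial codons are dropped.
#'
#' @param dna a single DNA string, length >= 3.
#' @return named character vector of 6 peptides (`F1,F2,F3,R1,R2,R3`).
#' @export
six_frame_translate <- function(dna) {
  stopifnot(length(dna) == 1L, nchar(dna) >= 3L)
  tr1 <- function(s, off) {
    n <- nchar(s) - off
    n <- n - (n %% 3L)
    if (n < 3L) return("")
    sub <- substr(s, off + 1L, off + n)
    as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                       if.fuzzy.codon = "X"))
  }
  rc <- revcomp(dna)
  c(F1 = tr1(dna, 0L), F2 = tr1(dna, 1L), F3 = tr1(dna, 2L),
    R1 = tr1(rc, 0L),  R2 = tr1(rc, 1L),  R3 = tr1(rc, 2L))
}

## ---- intervals ------------------------------------------------------------
## Internal coordinates are 0-based half-open [start, end); public GFF3 output
## is converted to 1-based inclusive.

#' Build an interval table
#'
#' @param seq_id,start,end,strand vectors (0-based half-open, strand "+"/"-").
#' @return data.frame with one row per interval.
#' @export
interval <- function(seq_id, start, end, strand = "+") {
  stopifnot(all(start >= 0), all(end > start), all(strand %in% c("+", "-")))
  data.frame(seq_id = as.character(seq_id), start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

#' Convert 0-based half-open intervals to 1-based inclusive (and back)
#'
#' @param df data.frame with `start`/`end` columns.
#' @return data.frame with converted coordinates.
#' @export
to_one_based <- function(df) { df$start <- df$start + 1L; df }

#' @rdname to_one_based
#' @export
to_zero_based <- function(df) { df$start <- df$start - 1L; df }

#' Convert an interval table to GRanges
#' @param df interval data.frame (0-based half-open).
#' @param extra_cols columns to carry over as metadata.
#' @return a [GenomicRanges::GRanges] object.
#' @export
intervals_to_granges <- function(df, extra_cols = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$seq_id,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
  for (cc in extra_cols) S4Vectors::mcols(gr)[[cc]] <- df[[cc]]
  gr
}

#' Write intervals as GFF3
#'
#' @param df interval data.frame (0-based half-open internal coordinates).
#' @param path output file.
#' @param type GFF3 feature type.
#' @param source GFF3 source column.
#' @param extra_cols metadata columns to emit as GFF3 attributes.
#' @export
write_gff3 <- function(df, path, type = "dispersed_repeat",
                       source = "helitronscan", extra_cols = NULL) {
  gr <- intervals_to_granges(df, extra_cols = extra_cols)
  if (!is.null(type) && !"type" %in% extra_cols)
    S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$source <- source
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into an interval table
#'
#' @param path GFF3 file.
#' @return data.frame with 0-based half-open `start`/`end`, plus `type` and any
#'   attribute columns present.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  mc <- as.data.frame(S4Vectors::mcols(gr))
  for (cc in names(mc)) if (!cc %in% names(df)) df[[cc]] <- mc[[cc]]
  df
}

## oriented sequence helpers: "strand-local" coordinates address the plus
## strand for "+" and the reverse complement for "-".

oriented_seq <- function(seq, strand) if (strand == "+") seq else revcomp(seq)

## memoised per-scaffold oriented sequences (revcomp of big scaffolds is
## expensive; compute it once per genome)
oriented_cache <- function(genome) {
  env <- new.env(parent = emptyenv())
  function(sid, strand) {
    if (strand == "+") return(genome[[sid]])
    key <- paste0("rc:", sid)
    if (is.null(env[[key]])) env[[key]] <- revcomp(genome[[sid]])
    env[[key]]
  }
}

## map a strand-local [start, end) interval back to plus-strand coordinates
sl_to_plus <- function(start, end, seq_len, strand) {
  if (length(strand) == 1L) strand <- rep(strand, length(start))
  neg <- strand == "-"
  s <- ifelse(neg, seq_len - end, start)
  e <- ifelse(neg, seq_len - start, end)
  data.frame(start = as.integer(s), end = as.integer(e))
}
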