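## Detection of the Helitron 3' terminal structure: a subterminal hairpin,
## a short spacer, the CTRR motif (R = purine) and -- when required -- the
## host T immediately downstream (the element inserts between host A and T,
## so a genuine 3' terminus is followed by T).

CTRR_MOTIFS <- c("CTAA", "CTAG", "CTGA", "CTGG")

#' Default end-structure scan parameters
#'
#' Hairpin geometry is not dictated by the terminal-structure definition
#' itself; these defaults (stem 6-20 bp with at most 20% mismatches capped at
#' 3, loop 2-10 nt, hairpin-to-CTRR separation 2-20 nt, trailing host T
#' required) follow the structure-based Helitron search tradition and are all
#' overridable.
#'
#' @return named list of scan parameters.
#' @export
end_params <- function() {
  list(stem_min = 6L, stem_max = 20L, loop_min = 2L, loop_max = 10L,
       max_mismatch = 3L, max_mismatch_frac = 0.2,
       sep_min = 2L, sep_max = 20L, require_host_t = TRUE)
}

#' Find CTRR(+T) motif sites on both strands
#'
#' Returns every occurrence of `CTRR` (`R` = A/G) -- by default requiring the
#' trailing host `T`, i.e. the 5-mer `CTRRT` -- on either strand. Coordinates
#' are 0-based half-open on the plus strand and cover the 4-nt CTRR;
#' `sl_start` gives the strand-local start (coordinates on the reverse
#' complement for minus-strand sites).
#'
#' @param seq a single DNA string.
#' @param require_host_t require the T immediately 3' of CTRR.
#' @return data.frame (start, end, strand, sl_start).
#' @export
find_ctrrt_sites <- function(seq, require_host_t = TRUE) {
  n <- nchar(seq)
  pat <- if (require_host_t) "CTRRT" else "CTRR"
  scan1 <- function(s) {
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(s), fixed = FALSE)
    Biostrings::start(m) - 1L
  }
  plus <- scan1(seq)
  minus <- scan1(revcomp(seq))
  res <- rbind(
    if (length(plus)) data.frame(sl_start = plus, strand = "+"),
    if (length(minus)) data.frame(sl_start = minus, strand = "-"))
  if (is.null(res) || nrow(res) == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), sl_start = integer()))
  pp <- sl_to_plus(res$sl_start, res$sl_start + 4L, n, res$strand)
  out <- data.frame(start = pp$start, end = pp$end, strand = res$strand,
                    sl_start = res$sl_start)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Find hairpins (inverted-repeat stems) in a window
#'
#' A hairpin is a loop interval flanked by a stem whose 3' arm is the reverse
#' complement of the 5' arm up to the allowed mismatch budget
#' (`min(max_mismatch, floor(max_mismatch_frac * stem))`). Stems grow outward
#' from the loop and are maximal: the longest budget-respecting extent ending
#' on a matching base pair is reported, one hairpin per qualifying loop.
#'
#' @param seq DNA string scanned in the given coordinate frame.
#' @param win_start,win_end 0-based half-open window (defaults: whole string).
#' @param params list from [end_params()].
#' @return data.frame (arm5_start, arm5_end, loop_start, loop_end, arm3_start,
#'   arm3_end, stem_len, loop_len, mismatches), 0-based half-open.
#' @export
find_hairpins <- function(seq, win_start = 0L, win_end = nchar(seq),
                          params = end_params()) {
  p <- params
  if (win_end - win_start < 2L * p$stem_min + p$loop_min)
    return(empty_hairpins())
  h <- hairpin_scan_cpp(seq, as.integer(win_start), as.integer(win_end),
                        p$stem_min, p$stem_max, p$loop_min, p$loop_max,
                        p$max_mismatch, p$max_mismatch_frac)
  h <- as.data.frame(h)
  if (nrow(h) == 0) return(empty_hairpins())
  data.frame(arm5_start = h$arm5_start,
             arm5_end = h$arm5_start + h$stem_len,
             loop_start = h$loop_start,
             loop_end = h$loop_start + h$loop_len,
             arm3_start = h$loop_start + h$loop_len,
             arm3_end = h$loop_start + h$loop_len + h$stem_len,
             stem_len = h$stem_len, loop_len = h$loop_len,
             mismatches = h$mismatches)
}

empty_hairpins <- function() {
  data.frame(arm5_start = integer(), arm5_end = integer(),
             loop_start = integer(), loop_end = integer(),
             arm3_start = integer(), arm3_end = integer(),
             stem_len = integer(), loop_len = integer(),
             mismatches = integer())
}

#' Genome-wide scan for Helitron 3' end structures
#'
#' Pairs each CTRR(+T) site with an upstream hairpin whose 3' arm ends within
#' `[sep_min, sep_max]` nucleotides of the CTRR start, on both strands. When
#' several hairpins qualify at one CTRR site the longest stem wins, then the
#' fewest mismatches, then the leftmost (deterministic tie-break). Hits are
#' reported in plus-strand coordinates (`start`/`end` span hairpin 5' arm to
#' the last CTRR base) with strand-local sub-structure coordinates
#' (`sl_*`, addressing the reverse complement for minus-strand hits).
#'
#' @param seq a single DNA string (one scaffold).
#' @param seq_id identifier used in the output.
#' @param params list from [end_params()].
#' @return data.frame of end-structure hits, sorted by plus-strand position.
#' @export
find_end_structures <- function(seq, seq_id = "seq", params = end_params()) {
  p <- params
  n <- nchar(seq)
  sites <- find_ctrrt_sites(seq, require_host_t = p$require_host_t)
  picked <- vector("list", nrow(sites))
  seqs <- list("+" = seq, "-" = if (any(sites$strand == "-")) revcomp(seq) else NULL)
  for (i in seq_len(nrow(sites))) {
    st <- sites$strand[i]
    s <- seqs[[st]]
    ctrr <- sites$sl_start[i]
    win_lo <- ctrr - p$sep_max - 2L * p$stem_max - p$loop_max
    win_hi <- ctrr - p$sep_min
    if (win_hi <= 0) next
    # lean inner loop: pass only the window substring to the kernel (the
    # full scaffold would be copied on every call) and keep vectors only
    w0 <- max(0L, win_lo)
    hp <- hairpin_scan_cpp(substr(s, w0 + 1L, win_hi), 0L, win_hi - w0,
                           p$stem_min, p$stem_max, p$loop_min, p$loop_max,
                           p$max_mismatch, p$max_mismatch_frac)
    a5 <- hp[["arm5_start"]] + w0
    if (length(a5) == 0) next
    sl <- hp[["stem_len"]]; ls <- hp[["loop_start"]] + w0
    ll <- hp[["loop_len"]]; mm <- hp[["mismatches"]]
    a3e <- ls + ll + sl
    sep <- ctrr - a3e
    keep <- sep >= p$sep_min & sep <= p$sep_max
    if (!any(keep)) next
    b <- which(keep)[order(-sl[keep], mm[keep], a5[keep])[1L]]
    picked[[i]] <- c(i, a5[b], a5[b] + sl[b], ls[b],
                     ls[b] + ll[b], ls[b] + ll[b], a3e[b],
                     sl[b], ll[b], mm[b])
  }
  picked <- do.call(rbind, picked)
  hits <- NULL
  if (!is.null(picked)) {
    si <- picked[, 1]
    ctrr <- sites$sl_start[si]
    pp <- sl_to_plus(picked[, 2], ctrr + 4L, n, sites$strand[si])
    hits <- data.frame(
      seq_id = seq_id, start = pp$start, end = pp$end,
      strand = sites$strand[si],
      sl_arm5_start = picked[, 2], sl_arm5_end = picked[, 3],
      sl_loop_start = picked[, 4], sl_loop_end = picked[, 5],
      sl_arm3_start = picked[, 6], sl_arm3_end = picked[, 7],
      sl_ctrr_start = ctrr, sl_ctrr_end = ctrr + 4L,
      sl_host_t = if (p$require_host_t) ctrr + 4L else NA_integer_,
      stem_len = picked[, 8], loop_len = picked[, 9],
      mismatches = picked[, 10], stringsAsFactors = FALSE)
  }
  if (is.null(hits))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      sl_arm5_start = integer(), sl_arm5_end = integer(),
                      sl_loop_start = integer(), sl_loop_end = integer(),
                      sl_arm3_start = integer(), sl_arm3_end = integer(),
                      sl_ctrr_start = integer(), sl_ctrr_end = integer(),
                      sl_host_t = integer(), stem_len = integer(),
                      loop_len = integer(), mismatches = integer()))
  rownames(hits) <- NULL
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' Scan a whole genome (multiple scaffolds) for end structures
#'
#' @param genome named character vector of scaffold sequences.
#' @param params list from [end_params()].
#' @return row-bound data.frame of [find_end_structures()] results.
#' @export
scan_genome_ends <- function(genome, params = end_params()) {
  res <- lapply(names(genome), function(id)
    find_end_structures(genome[[id]], seq_id = id, params = params))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
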