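# Independent oracles and small fixture builders used across the suite.

rand_dna <- function(n, at = 0.5) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

comp_base <- c(A = "T", T = "A", C = "G", G = "C", N = "N")

## regex-based CTRR(+T) site oracle, one strand
ctrrt_regex_oracle <- function(seq, host_t = TRUE) {
  pat <- if (host_t) "CT[AG][AG]T" else "CT[AG][AG]"
  m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

## brute-force hairpin enumeration implementing the documented definition:
## for every loop [a, b), grow the stem outward; report the longest extent
## within budget ending on a match, if >= stem_min.
hairpin_bruteforce <- function(seq, win_start = 0, win_end = nchar(seq),
                               stem_min = 6, stem_max = 20,
                               loop_min = 2, loop_max = 10,
                               max_mm = 3, max_mm_frac = 0.2) {
  x <- strsplit(seq, "")[[1]]
  out <- NULL
  for (a in (win_start + stem_min):(win_end - 1)) {
    if (a < 1) next
    for (l in loop_min:loop_max) {
      b <- a + l
      if (b + stem_min > win_end) next
      best_L <- 0; best_mm <- 0; mm <- 0
      Lmax <- min(a - win_start, win_end - b, stem_max)
      for (t in seq_len(Lmax)) {
        match <- comp_base[[x[a - t + 1]]] == x[b + t]
        if (!match) mm <- mm + 1
        budget <- min(max_mm, floor(max_mm_frac * t))
        if (match && mm <= budget) { best_L <- t; best_mm <- mm }
      }
      if (best_L >= stem_min)
        out <- rbind(out, data.frame(arm5_start = a - best_L, stem_len = best_L,
                                     loop_start = a, loop_len = l,
                                     mismatches = best_mm))
    }
  }
  if (is.null(out))
    data.frame(arm5_start = integer(), stem_len = integer(),
               loop_start = integer(), loop_len = integer(),
               mismatches = integer())
  else out
}

## per-site counting K2P oracle
k2p_counting_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  ts_pairs <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)
  key <- paste0(av, bv)
  P <- mean(av != bv & !is.na(ts_pairs[key]))
  Q <- mean(av != bv & is.na(ts_pairs[key]))
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

## codon-table translation oracle (loop over GENETIC_CODE)
translate_oracle <- function(dna) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  paste(unname(gc[codons]), collapse = "")
}

## a synthetic end-structure construct: hairpin(stem/loop) + spacer + CTRR + T
make_end_construct <- function(stem = 6, loop = 4, spacer = 8,
                               ctrr = "CTAG", lead = 20, tail = 20,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arm <- rand_dna(stem)
  paste0(rand_dna(lead), arm, rand_dna(loop), revcomp(arm),
         rand_dna(spacer), ctrr, "T", rand_dna(tail))
}

## deterministic additive distance matrix from a random binary tree; returns
## list(d = matrix, tree-free) built by random split recursion with positive
## branch lengths (path metric is additive by construction)
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 3))
  d <- ape::cophenetic.phylo(tr)
  d[order(rownames(d)), order(colnames(d))]
}
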