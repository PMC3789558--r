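## Gene-fragment capture (translated search), autonomous-element flagging
## (Rep + helicase homology plus a long ORF), EST/cDNA transcript
## classification, cDNA UTR/ORF partition, and the insertion-context
## permutation test.

## Ungapped Karlin-Altschul constants for BLOSUM62 (standard values).
BLOSUM62_LAMBDA <- 0.3176
BLOSUM62_K <- 0.134

#' Default capture/transcript parameters
#'
#' E-value cutoffs follow the conventional shorthand reading: 1e-10 for hits
#' in the same species, 1e-5 for other species, 1e-10 with >= 99% identity
#' for EST/cDNA matches. The 900-nt ORF floor for autonomy reflects the size
#' of Rep/helicase proteins.
#'
#' @return named list of parameters.
#' @export
capture_params <- function() {
  list(e_same = 1e-10, e_other = 1e-5, e_autonomous = 1e-5,
       est_id = 0.99, est_evalue = 1e-10,
       orf_min_nt = 900L, gap_opening = 11, gap_extension = 1)
}

## local protein alignment of a peptide query against a protein, BLOSUM62
protein_local_hit <- function(pep, prot, params = capture_params()) {
  if (nchar(pep) < 3 || nchar(prot) < 3) return(NULL)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(gsub("[*]", "X", pep)),
    Biostrings::AAString(prot),
    type = "local", substitutionMatrix = BLOSUM62,
    gapOpening = params$gap_opening, gapExtension = params$gap_extension)
  sc <- Biostrings::score(al)
  ev <- BLOSUM62_K * nchar(pep) * nchar(prot) * exp(-BLOSUM62_LAMBDA * sc)
  list(score = sc, evalue = ev,
       p_start = Biostrings::start(Biostrings::pattern(al)) - 1L,
       p_end = Biostrings::end(Biostrings::pattern(al)))
}

## map a peptide interval in frame f (F1..F3/R1..R3) to element nt coords
frame_to_nt <- function(frame, p_start, p_end, elen) {
  off <- as.integer(substr(frame, 2, 2)) - 1L
  nt_start <- off + 3L * p_start
  nt_end <- off + 3L * p_end
  if (startsWith(frame, "R")) {
    s <- elen - nt_end; e <- elen - nt_start
    c(s, e)
  } else c(nt_start, nt_end)
}

#' Translated search of an element against a protein set
#'
#' All six reading frames of the element are locally aligned (BLOSUM62)
#' against each protein; hits passing the species-dependent E-value cutoff
#' are kept, hits to TE-flagged proteins are discarded, and overlapping
#' element intervals (>= 1 bp) are merged into captured fragments.
#'
#' @param element DNA string.
#' @param proteins named character vector of protein sequences.
#' @param species_tags character vector (`"same"`/`"other"`), recycled.
#' @param te_flags logical vector marking TE-related proteins, recycled.
#' @param params list from [capture_params()].
#' @return data.frame of captured fragments: element interval (0-based
#'   half-open), protein_id, frame, evalue, source_species_class.
#' @export
translated_search <- function(element, proteins, species_tags = "same",
                              te_flags = FALSE, params = capture_params()) {
  if (length(proteins) == 0) return(empty_fragments())
  species_tags <- rep_len(species_tags, length(proteins))
  te_flags <- rep_len(te_flags, length(proteins))
  peps <- six_frame_translate(element)
  elen <- nchar(element)
  hits <- list()
  for (pi in seq_along(proteins)) {
    if (te_flags[pi]) next
    cutoff <- if (species_tags[pi] == "same") params$e_same else params$e_other
    for (fr in names(peps)) {
      if (nchar(peps[[fr]]) < 10) next
      h <- protein_local_hit(peps[[fr]], proteins[[pi]], params)
      if (is.null(h) || h$evalue > cutoff) next
      nt <- frame_to_nt(fr, h$p_start, h$p_end, elen)
      hits[[length(hits) + 1L]] <- data.frame(
        start = nt[1], end = nt[2], protein_id = names(proteins)[pi],
        frame = fr, evalue = h$evalue,
        source_species_class = species_tags[pi], stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(empty_fragments())
  merge_fragments(hits)
}

empty_fragments <- function() {
  data.frame(start = integer(), end = integer(), protein_id = character(),
             frame = character(), evalue = numeric(),
             source_species_class = character())
}

## merge element intervals overlapping by >= 1 bp; keep the best-E hit's
## annotation for each merged fragment
merge_fragments <- function(hits) {
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  grp <- integer(nrow(hits)); g <- 1L; grp[1] <- 1L
  cur_end <- hits$end[1]
  for (i in seq_len(nrow(hits))[-1]) {
    if (hits$start[i] < cur_end) { grp[i] <- g; cur_end <- max(cur_end, hits$end[i]) }
    else { g <- g + 1L; grp[i] <- g; cur_end <- hits$end[i] }
  }
  rows <- lapply(split(seq_len(nrow(hits)), grp), function(ix) {
    best <- ix[which.min(hits$evalue[ix])]
    data.frame(start = min(hits$start[ix]), end = max(hits$end[ix]),
               protein_id = hits$protein_id[best], frame = hits$frame[best],
               evalue = hits$evalue[best],
               source_species_class = hits$source_species_class[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-capture census over intact elements
#'
#' @param elements named character vector of intact element sequences.
#' @param proteins,species_tags,te_flags as in [translated_search()].
#' @param params list from [capture_params()].
#' @return list: `per_element` (element id, fragment count), `fragments`
#'   (all captured fragments with element ids), `fraction_capturing`,
#'   `total_fragments`, `distinct_genes`.
#' @export
capture_census <- function(elements, proteins, species_tags = "same",
                           te_flags = FALSE, params = capture_params()) {
  frs <- lapply(seq_along(elements), function(i) {
    fr <- translated_search(elements[[i]], proteins, species_tags, te_flags,
                            params)
    if (nrow(fr)) fr$element <- names(elements)[i]
    fr
  })
  frags <- do.call(rbind, frs[vapply(frs, nrow, integer(1)) > 0])
  counts <- vapply(frs, nrow, integer(1))
  per_element <- data.frame(element = names(elements), n_fragments = counts,
                            stringsAsFactors = FALSE)
  list(per_element = per_element,
       fragments = if (is.null(frags)) cbind(empty_fragments(),
                                             element = character(0)) else frags,
       fraction_capturing = mean(counts >= 1),
       total_fragments = sum(counts),
       distinct_genes = if (is.null(frags)) 0L
                        else length(unique(frags$protein_id)))
}

#' Find open reading frames
#'
#' ATG-initiated ORFs (to the next in-frame stop, or the sequence end) of at
#' least `min_nt` nucleotides, on both strands.
#'
#' @param dna DNA string.
#' @param min_nt minimum ORF length in nucleotides (ATG..stop inclusive).
#' @return data.frame: start, end (0-based half-open, plus strand), strand,
#'   frame.
#' @export
find_orfs <- function(dna, min_nt = 900L) {
  n <- nchar(dna)
  peps <- six_frame_translate(dna)
  out <- list()
  for (fr in names(peps)) {
    pep <- peps[[fr]]
    m <- gregexpr("M[^*]*\\*?", pep)[[1]]
    if (m[1] == -1) next
    for (i in seq_along(m)) {
      p_start <- m[i] - 1L
      p_len <- attr(m, "match.length")[i]
      nt_len <- 3L * p_len
      if (nt_len < min_nt) next
      nt <- frame_to_nt(fr, p_start, p_start + p_len, n)
      out[[length(out) + 1L]] <- data.frame(
        start = nt[1], end = nt[2],
        strand = if (startsWith(fr, "R")) "-" else "+", frame = fr,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = character()))
  res
}

#' Flag a family as a putative autonomous Helitron
#'
#' A family is autonomous-candidate when some copy has translated-search hits
#' to BOTH a Rep-class and a helicase-class reference protein (each at
#' `e_autonomous` or better) and an ORF of at least `orf_min_nt` nucleotides
#' spans both hit intervals.
#'
#' @param copies named character vector of copy sequences for the family.
#' @param rep_proteins,helicase_proteins named character vectors of reference
#'   peptides.
#' @param params list from [capture_params()].
#' @return list(autonomous_candidate, copy, orf = interval row or NULL).
#' @export
detect_autonomous <- function(copies, rep_proteins, helicase_proteins,
                              params = capture_params()) {
  p <- params
  p$e_same <- p$e_autonomous; p$e_other <- p$e_autonomous
  for (i in seq_along(copies)) {
    rep_hits <- translated_search(copies[[i]], rep_proteins, "same", FALSE, p)
    if (nrow(rep_hits) == 0) next
    hel_hits <- translated_search(copies[[i]], helicase_proteins, "same",
                                  FALSE, p)
    if (nrow(hel_hits) == 0) next
    orfs <- find_orfs(copies[[i]], min_nt = p$orf_min_nt)
    for (oi in seq_len(nrow(orfs))) {
      spans <- function(h) any(h$start >= orfs$start[oi] &
                               h$end <= orfs$end[oi])
      if (spans(rep_hits) && spans(hel_hits))
        return(list(autonomous_candidate = TRUE,
                    copy = names(copies)[i] %||% i,
                    orf = orfs[oi, , drop = FALSE]))
    }
  }
  list(autonomous_candidate = FALSE, copy = NA, orf = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## nucleotide local identity of a transcript against a target sequence
nt_local_identity <- function(query, target) {
  h <- best_local_hit(query, target)
  if (is.null(h)) return(list(identity = 0, length = 0, score = -Inf,
                              evalue = Inf))
  p <- census_params()
  h$evalue <- p$K * nchar(query) * nchar(target) * exp(-p$lambda * h$score)
  h
}

#' Classify a transcript matching a Helitron
#'
#' Requires a transcript-element match at >= `est_id` identity and
#' `E < est_evalue`. Classes: `parental` when the transcript matches the
#' parental gene better than the element; `helitron_transposase` when the
#' matched element region lies in a flagged transposase ORF;
#' `chimeric` when the transcript's genomic footprint crosses the element
#' boundary; else `helitron_derived`.
#'
#' @param transcript transcript sequence.
#' @param helitron element sequence.
#' @param parental_gene parental gene sequence, or `NULL` (classification
#'   then proceeds among the remaining classes, flagged `parental_untested`).
#' @param transposase_orf optional element-coordinate interval
#'   `c(start, end)` of a flagged transposase ORF.
#' @param footprint optional transcript genomic footprint `c(start, end)`.
#' @param element_interval optional element genomic interval `c(start, end)`.
#' @param params list from [capture_params()].
#' @return list(class, matched_identity, parental_untested).
#' @export
classify_transcript <- function(transcript, helitron, parental_gene = NULL,
                                transposase_orf = NULL, footprint = NULL,
                                element_interval = NULL,
                                params = capture_params()) {
  p <- params
  hel <- nt_local_identity(transcript, helitron)
  if (hel$identity < p$est_id || hel$evalue >= p$est_evalue)
    stop("classify_transcript(): transcript does not match the element at ",
         "the required identity/E-value")
  parental_untested <- is.null(parental_gene)
  if (!parental_untested) {
    par <- nt_local_identity(transcript, parental_gene)
    if (par$identity > hel$identity ||
        (par$identity == hel$identity && par$length > hel$length))
      return(list(class = "parental", matched_identity = par$identity,
                  parental_untested = FALSE))
  }
  if (!is.null(transposase_orf)) {
    if (hel$b_start >= transposase_orf[1] && hel$b_end <= transposase_orf[2])
      return(list(class = "helitron_transposase",
                  matched_identity = hel$identity,
                  parental_untested = parental_untested))
  }
  if (!is.null(footprint) && !is.null(element_interval)) {
    inside <- footprint[1] >= element_interval[1] &&
              footprint[2] <= element_interval[2]
    overlaps <- footprint[2] > element_interval[1] &&
                footprint[1] < element_interval[2]
    if (overlaps && !inside)
      return(list(class = "chimeric", matched_identity = hel$identity,
                  parental_untested = parental_untested))
  }
  list(class = "helitron_derived", matched_identity = hel$identity,
       parental_untested = parental_untested)
}

#' Split a full-length cDNA into 5'-UTR, ORF and 3'-UTR
#'
#' @param cdna cDNA sequence.
#' @param orf_start,orf_end 0-based half-open ORF coordinates; the ORF length
#'   must be divisible by 3.
#' @return list(utr5, orf, utr3) of substrings (UTRs may be empty).
#' @export
split_cdna <- function(cdna, orf_start, orf_end) {
  n <- nchar(cdna)
  if (!(orf_start >= 0 && orf_start < orf_end && orf_end <= n))
    stop("split_cdna(): ORF coordinates out of range")
  if ((orf_end - orf_start) %% 3L != 0L)
    stop("split_cdna(): ORF length not divisible by 3")
  list(utr5 = substr(cdna, 1L, orf_start),
       orf = substr(cdna, orf_start + 1L, orf_end),
       utr3 = substr(cdna, orf_end + 1L, n))
}

#' Which cDNA parts does an element hit overlap?
#'
#' @param hit_start,hit_end 0-based half-open hit interval on the cDNA.
#' @param orf_start,orf_end ORF coordinates as in [split_cdna()].
#' @param cdna_len cDNA length.
#' @return character vector, subset of `c("utr5", "orf", "utr3")`.
#' @export
matched_cdna_parts <- function(hit_start, hit_end, orf_start, orf_end,
                               cdna_len) {
  parts <- character(0)
  if (hit_start < orf_start) parts <- c(parts, "utr5")
  if (hit_end > orf_start && hit_start < orf_end) parts <- c(parts, "orf")
  if (hit_end > orf_end && orf_end < cdna_len) parts <- c(parts, "utr3")
  parts
}

## ---- insertion context ----------------------------------------------------

classify_context <- function(gr_copies, gr_exons, gr_genes, near_bp = 1000L) {
  cls <- rep("beyond_1kb", length(gr_copies))
  dist_gene <- rep(NA_real_, length(gr_copies))
  if (length(gr_genes)) {
    in_gene <- IRanges::overlapsAny(gr_copies, gr_genes, ignore.strand = TRUE)
    in_exon <- if (length(gr_exons))
      IRanges::overlapsAny(gr_copies, gr_exons, ignore.strand = TRUE)
      else rep(FALSE, length(gr_copies))
    d <- GenomicRanges::distanceToNearest(gr_copies, gr_genes,
                                          ignore.strand = TRUE)
    dist_gene[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    near <- !in_gene & !is.na(dist_gene) & dist_gene <= near_bp
    cls[near] <- "within_1kb"
    cls[in_gene] <- "intron"
    cls[in_exon] <- "exon"
  }
  list(class = cls, distance = dist_gene)
}

#' Insertion-context permutation test
#'
#' Classifies each copy as exon / intron / within 1 kb of a gene / beyond
#' 1 kb, then compares the observed class counts with a null in which every
#' copy (length preserved) is placed uniformly at random `n_perm` times.
#' Two-sided empirical p per class:
#' `(1 + # permutations as-or-more-extreme) / (n_perm + 1)` on the shorter
#' tail, doubled and capped at 1.
#'
#' @param copies copy-call data.frame (seq_id, start, end).
#' @param genes data.frame of gene models with `type` (`gene`/`exon`),
#'   `seq_id`, `start`, `end` (0-based half-open), e.g. from [read_gff3()].
#' @param chrom_lengths named vector of scaffold lengths.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param near_bp "near gene" distance threshold.
#' @return list: `observed` (class counts), `p_values`, `classes` (per-copy),
#'   `null_mean`.
#' @export
insertion_context_test <- function(copies, genes, chrom_lengths,
                                   n_perm = 1000L, seed = 1L,
                                   near_bp = 1000L) {
  lvls <- c("exon", "intron", "within_1kb", "beyond_1kb")
  lens <- copies$end - copies$start
  if (any(lens > chrom_lengths[copies$seq_id]))
    stop("insertion_context_test(): copy longer than its chromosome")
  gr_genes <- if (nrow(genes)) intervals_to_granges(
    genes[genes$type == "gene", , drop = FALSE]) else GenomicRanges::GRanges()
  gr_exons <- if (nrow(genes)) intervals_to_granges(
    genes[genes$type == "exon", , drop = FALSE]) else GenomicRanges::GRanges()
  obs_cls <- classify_context(intervals_to_granges(copies), gr_exons,
                              gr_genes, near_bp)$class
  obs <- table(factor(obs_cls, levels = lvls))
  set.seed(seed)
  n <- nrow(copies)
  null_counts <- matrix(0L, nrow = n_perm, ncol = length(lvls),
                        dimnames = list(NULL, lvls))
  # draw all random placements at once; classify with one overlap query
  chroms <- sample(names(chrom_lengths), n * n_perm, replace = TRUE,
                   prob = chrom_lengths / sum(chrom_lengths))
  all_lens <- rep(lens, times = n_perm)
  maxs <- chrom_lengths[chroms] - all_lens
  bad <- maxs < 0
  if (any(bad)) { chroms[bad] <- copies$seq_id[rep(seq_len(n), n_perm)][bad]
                  maxs[bad] <- chrom_lengths[chroms[bad]] - all_lens[bad] }
  starts <- floor(stats::runif(n * n_perm, 0, maxs + 1))
  perm_df <- data.frame(seq_id = chroms, start = starts,
                        end = starts + all_lens)
  cls_all <- classify_context(intervals_to_granges(perm_df), gr_exons,
                              gr_genes, near_bp)$class
  cls_mat <- matrix(factor(cls_all, levels = lvls), nrow = n)
  for (pm in seq_len(n_perm))
    null_counts[pm, ] <- table(factor(cls_mat[, pm], levels = lvls))
  p <- vapply(lvls, function(cl) {
    o <- obs[[cl]]
    ge <- (1 + sum(null_counts[, cl] >= o)) / (n_perm + 1)
    le <- (1 + sum(null_counts[, cl] <= o)) / (n_perm + 1)
    min(1, 2 * min(ge, le))
  }, numeric(1))
  list(observed = obs, p_values = p, classes = obs_cls,
       null_mean = colMeans(null_counts))
}
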