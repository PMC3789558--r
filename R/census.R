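## Family naming/annotation, genome-wide copy census against family
## consensuses, copy-vs-fragment and intactness calling, per-family summary
## statistics, chromosomal distribution, and chimeric-family detection.

#' Default census parameters
#'
#' Copy thresholds follow the family definition used throughout: E < 1e-6,
#' aligned length > 80 bp, identity > 80%. The Karlin-Altschul constants are
#' fixed surrogates for reproducibility (E-values only gate thresholds; any
#' monotone transform of the score behaves identically at a fixed cutoff).
#' `chain_gap` = 15 kb mirrors the long-copy treatment.
#'
#' @return named list of parameters.
#' @export
census_params <- function() {
  list(seed_len = 11L, evalue_max = 1e-6, min_len = 80L, min_id = 0.80,
       lambda = 1.33, K = 0.621, diag_tol = 50L, margin = 100L,
       min_seeds = 2L, match = 1, mismatch = -1, gap = -4,
       chain_gap = 15000L, end_tol = 10L, snap = 3L,
       family_t = 0.80, family_w = 30L, subfamily_t = 0.80)
}

## ---- seeded local search --------------------------------------------------

seed_pairs <- function(query, subject, seed_len) {
  qlen <- nchar(query)
  if (qlen < seed_len) return(data.frame(qpos = integer(), spos = integer()))
  starts <- seq_len(qlen - seed_len + 1L)
  qmers <- substring(query, starts, starts + seed_len - 1L)
  ok <- !grepl("N", qmers, fixed = TRUE)
  if (!any(ok)) return(data.frame(qpos = integer(), spos = integer()))
  pd <- Biostrings::PDict(qmers[ok])
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject))
  counts <- S4Vectors::elementNROWS(m)
  if (sum(counts) == 0) return(data.frame(qpos = integer(), spos = integer()))
  data.frame(qpos = rep(starts[ok], counts),
             spos = unlist(Biostrings::startIndex(m), use.names = FALSE))
}

#' Seeded local search of a family consensus against a genome
#'
#' Exact `seed_len`-mer seeds (via Biostrings PDict matching) are grouped by
#' diagonal; each candidate region is refined by local dynamic-programming
#' alignment (match +1, mismatch -1, gap -2). HSPs are retained when
#' `E < evalue_max`, aligned length `> min_len` and identity `> min_id`,
#' with `E = K * m * n * exp(-lambda * score)`. Both strands are searched;
#' minus-strand HSP query coordinates are reported in consensus orientation.
#'
#' @param consensus family consensus (>= `min_len` bp, <= 20% N).
#' @param genome named character vector of scaffolds.
#' @param params list from [census_params()].
#' @return data.frame of HSPs: seq_id, strand, sstart/send (plus strand,
#'   0-based half-open), qstart/qend (0-based half-open on the consensus),
#'   length (alignment columns), identity, score, evalue.
#' @export
search_genome <- function(consensus, genome, params = census_params()) {
  p <- params
  qlen <- nchar(consensus)
  if (qlen < p$min_len) stop("consensus shorter than ", p$min_len, " bp")
  nfrac <- lengths(regmatches(consensus, gregexpr("N", consensus)))/qlen
  if (nfrac > 0.2) stop("consensus with > 20% N")
  out <- list()
  for (sid in names(genome)) {
    subject <- genome[[sid]]
    ns <- nchar(subject)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") consensus else revcomp(consensus)
      sp <- seed_pairs(q, subject, p$seed_len)
      if (nrow(sp) == 0) next
      d <- sp$spos - sp$qpos
      ord <- order(d, sp$spos)
      d <- d[ord]; spos <- sp$spos[ord]
      grp <- cumsum(c(1L, diff(d) > p$diag_tol))
      for (g in split(seq_along(d), grp)) {
        # split a diagonal group on large subject gaps (tandem copies)
        sg <- spos[g]
        sub_ord <- order(sg)
        sg <- sg[sub_ord]; dg <- d[g][sub_ord]
        part <- cumsum(c(1L, diff(sg) > qlen + 2L * p$margin))
        for (gg in split(seq_along(sg), part)) {
          # isolated chance seeds are not worth a DP refinement; a genuine
          # >80 bp / >80% identity HSP seeds many times over
          if (length(gg) < p$min_seeds) next
          lo <- max(1L, min(dg[gg]) + 1L - p$margin)
          hi <- min(ns, max(dg[gg]) + qlen + p$margin)
          region <- substr(subject, lo, hi)
          al <- align_cpp(q, region, p$match, p$mismatch, p$gap, local = TRUE)
          if (nchar(al$a_aln) == 0) next
          len <- nchar(al$a_aln)
          id <- ungapped_identity(al$a_aln, al$b_aln)
          ev <- p$K * qlen * ns * exp(-p$lambda * al$score)
          if (!(ev < p$evalue_max && len > p$min_len && id > p$min_id)) next
          sstart <- lo - 1L + al$b_start        # 0-based
          send <- lo - 1L + al$b_end
          if (strand == "+") { qs <- al$a_start; qe <- al$a_end }
          else { qs <- qlen - al$a_end; qe <- qlen - al$a_start }
          out[[length(out) + 1L]] <- data.frame(
            seq_id = sid, strand = strand,
            sstart = sstart, send = send, qstart = qs, qend = qe,
            length = len, identity = id, score = al$score, evalue = ev,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hsps <- do.call(rbind, out)
  if (is.null(hsps))
    return(data.frame(seq_id = character(), strand = character(),
                      sstart = integer(), send = integer(),
                      qstart = integer(), qend = integer(),
                      length = integer(), identity = numeric(),
                      score = numeric(), evalue = numeric()))
  # collapse near-duplicate HSPs from adjacent candidate regions
  hsps <- hsps[order(hsps$seq_id, hsps$strand, -hsps$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hsps))
  for (i in seq_len(nrow(hsps))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(hsps)) > i &
               hsps$seq_id == hsps$seq_id[i] & hsps$strand == hsps$strand[i])
    if (!length(j)) next
    ov <- pmin(hsps$send[j], hsps$send[i]) - pmax(hsps$sstart[j], hsps$sstart[i])
    span <- pmin(hsps$send[j] - hsps$sstart[j], hsps$send[i] - hsps$sstart[i])
    keep[j[ov > 0.5 * span]] <- FALSE
  }
  hsps <- hsps[keep, , drop = FALSE]
  hsps <- hsps[order(hsps$seq_id, hsps$sstart), , drop = FALSE]
  rownames(hsps) <- NULL
  hsps
}

## ---- copy / fragment calling ---------------------------------------------

snap_terminus <- function(s, pos, kind, snap) {
  ## s: strand-local scaffold; pos: candidate boundary (0-based);
  ## kind "TC" (element start) or "CTRR" (element end, exclusive)
  for (sh in order(abs(seq(-snap, snap)))) {
    shift <- seq(-snap, snap)[sh]
    p <- pos + shift
    if (kind == "TC") {
      if (p >= 0 && substr(s, p + 1L, p + 2L) == "TC")
        return(list(pos = p, found = TRUE))
    } else {
      if (p >= 4L && p <= nchar(s) &&
          substr(s, p - 3L, p) %in% CTRR_MOTIFS)
        return(list(pos = p, found = TRUE))
    }
  }
  list(pos = pos, found = FALSE)
}

#' Classify chained HSP loci into copies and fragments
#'
#' HSPs on one scaffold/strand are chained when colinear on the consensus
#' with subject gaps at most `chain_gap`. A locus whose alignment reaches
#' both consensus ends (within `end_tol` bp) is one copy; it is intact when
#' the genomic sequence additionally starts `TC` and ends on a `CTRR`
#' (termini snapped within `snap` bp). A locus matching only non-terminal
#' consensus regions with at most one terminus yields one fragment per HSP.
#'
#' @param hsps data.frame from [search_genome()].
#' @param consensus the family consensus searched.
#' @param genome named character vector of scaffolds.
#' @param family family name recorded in the calls.
#' @param params list from [census_params()].
#' @return data.frame of copy calls: interval, family, kind
#'   (`copy`/`fragment`), intact, identity, evalue, has_TC, has_CTRR.
#' @export
call_copies <- function(hsps, consensus, genome, family = "fam",
                        params = census_params()) {
  p <- params
  qlen <- nchar(consensus)
  calls <- list()
  emit <- function(sid, strand, a, b, ident, ev, kind, intact, tc, rr) {
    n <- nchar(genome[[sid]])
    pp <- sl_to_plus(a, b, n, strand)
    data.frame(seq_id = sid, start = pp$start, end = pp$end, strand = strand,
               family = family, kind = kind, intact = intact,
               identity = ident, evalue = ev, has_TC = tc, has_CTRR = rr,
               stringsAsFactors = FALSE)
  }
  for (key in unique(paste(hsps$seq_id, hsps$strand))) {
    sub <- hsps[paste(hsps$seq_id, hsps$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$sstart), , drop = FALSE]
    sid <- sub$seq_id[1]; strand <- sub$strand[1]
    n <- nchar(genome[[sid]])
    s <- oriented_seq(genome[[sid]], strand)
    # chain colinear HSPs
    chain_id <- 1L; chains <- rep(1L, nrow(sub))
    if (nrow(sub) > 1) for (i in 2:nrow(sub)) {
      gap_ok <- sub$sstart[i] - sub$send[i - 1] <= p$chain_gap
      colinear <- if (strand == "+") sub$qstart[i] >= sub$qend[i - 1] - 50L
                  else sub$qend[i] <= sub$qstart[i - 1] + 50L
      if (!(gap_ok && colinear)) chain_id <- chain_id + 1L
      chains[i] <- chain_id
    }
    for (ch in split(seq_len(nrow(sub)), chains)) {
      cc <- sub[ch, , drop = FALSE]
      q_lo <- min(cc$qstart); q_hi <- max(cc$qend)
      end5 <- q_lo <= p$end_tol
      end3 <- qlen - q_hi <= p$end_tol
      ident <- sum(cc$identity * cc$length) / sum(cc$length)
      ev <- min(cc$evalue)
      # strand-local locus interval, projected to full consensus span
      # (local alignments trim mismatching terminal bases; the projection
      # restores the expected element ends before the TC/CTRR snap)
      a_sl <- if (strand == "+") min(cc$sstart) else n - max(cc$send)
      b_sl <- if (strand == "+") max(cc$send) else n - min(cc$sstart)
      a_sl <- max(0L, a_sl - q_lo)
      b_sl <- min(n, b_sl + (qlen - q_hi))
      t5 <- snap_terminus(s, a_sl, "TC", p$snap)
      t3 <- snap_terminus(s, b_sl, "CTRR", p$snap)
      if (end5 && end3) {
        a_sl2 <- if (t5$found) t5$pos else a_sl
        b_sl2 <- if (t3$found) t3$pos else b_sl
        calls[[length(calls) + 1L]] <-
          emit(sid, strand, a_sl2, b_sl2, ident, ev, "copy",
               t5$found && t3$found, t5$found, t3$found)
      } else {
        for (i in seq_len(nrow(cc)))
          calls[[length(calls) + 1L]] <-
            emit(sid, strand,
                 if (strand == "+") cc$sstart[i] else n - cc$send[i],
                 if (strand == "+") cc$send[i] else n - cc$sstart[i],
                 cc$identity[i], cc$evalue[i], "fragment", FALSE,
                 t5$found && i == 1L, t3$found && i == nrow(cc))
      }
    }
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character(), kind = character(),
                      intact = logical(), identity = numeric(),
                      evalue = numeric(), has_TC = logical(),
                      has_CTRR = logical()))
  rownames(out) <- NULL
  out[order(out$seq_id, out$start), , drop = FALSE]
}

## ---- family naming / annotation -------------------------------------------

parse_te_class <- function(ids) {
  cls <- sub(".*class=([^ ]+).*", "\\1", ids)
  cls[!grepl("class=", ids)] <- "Helitron"
  cls
}

#' Annotate a consensus against a known-TE library
#'
#' Best local hit with identity > 0.80 over > 80 aligned bp. A best hit to a
#' non-Helitron TE flags the consensus for discard; a Helitron hit provides
#' the annotation; no qualifying hit yields `"Novel"`.
#'
#' @param consensus DNA string.
#' @param te_library named character vector; record names may carry a
#'   `class=<TE class>` tag (records without a tag count as Helitron).
#' @param min_id,min_len hit thresholds.
#' @return list(annotation, is_non_helitron).
#' @export
annotate_against_library <- function(consensus, te_library,
                                     min_id = 0.80, min_len = 80L) {
  if (is.null(te_library) || length(te_library) == 0)
    return(list(annotation = "Novel", is_non_helitron = FALSE))
  cls <- parse_te_class(names(te_library))
  ids <- sub("\\s.*$", "", names(te_library))
  best <- NULL; best_i <- NA_integer_
  for (i in seq_along(te_library)) {
    h <- best_local_hit(consensus, te_library[[i]])
    if (is.null(h) || h$identity <= min_id || h$length <= min_len) next
    if (is.null(best) || h$score > best$score) { best <- h; best_i <- i }
  }
  if (is.null(best))
    return(list(annotation = "Novel", is_non_helitron = FALSE))
  if (cls[best_i] != "Helitron")
    return(list(annotation = ids[best_i], is_non_helitron = TRUE))
  list(annotation = ids[best_i], is_non_helitron = FALSE)
}

global_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  al <- align_cpp(a, b, match, mismatch, gap, local = FALSE)
  ungapped_identity(al$a_aln, al$b_aln)   # gaps count as mismatches
}

#' Assign an element to a Helitron family (or found a new one)
#'
#' An element joins the first family whose both 30-bp terminal signatures
#' align to the element's termini with identity strictly above `t`
#' (identity = matches / alignment columns, gaps as mismatches). Within the
#' family, the element joins the first subfamily whose exemplar has
#' full-length identity above `subfamily_t`, else founds a new subfamily.
#'
#' @param consensus element consensus (TC...CTRR, >= 60 bp).
#' @param families list of family objects (from [name_families()]); may be
#'   empty.
#' @param t terminal-identity threshold (strict >).
#' @param W terminal signature width.
#' @param subfamily_t full-length subfamily identity threshold.
#' @return list(family = index or NA, subfamily = index or NA).
#' @export
assign_family <- function(consensus, families, t = 0.80, W = 30L,
                          subfamily_t = 0.80) {
  if (nchar(consensus) < 2L * W) stop("element shorter than ", 2L * W, " bp")
  e5 <- substr(consensus, 1L, W)
  e3 <- substr(consensus, nchar(consensus) - W + 1L, nchar(consensus))
  for (fi in seq_along(families)) {
    f <- families[[fi]]
    if (global_identity(e5, f$end5_30) > t &&
        global_identity(e3, f$end3_30) > t) {
      for (si in seq_along(f$subfamilies)) {
        if (global_identity(consensus, f$subfamilies[[si]]$exemplar) >
            subfamily_t)
          return(list(family = fi, subfamily = si))
      }
      return(list(family = fi, subfamily = NA_integer_))
    }
  }
  list(family = NA_integer_, subfamily = NA_integer_)
}

#' Name families from boundary-called consensus elements
#'
#' Elements are first screened against the known-TE library (best non-Helitron
#' hit discards the element); survivors are grouped into families by the
#' terminal-signature rule of [assign_family()] and named `<prefix>-1`,
#' `<prefix>-2`, ... in discovery order, with lettered subfamilies.
#'
#' @param elements `elements` list from [build_families()].
#' @param te_library optional named character vector of known TEs.
#' @param prefix family name prefix.
#' @param params list from [census_params()].
#' @return list of family objects: name, consensus, end5_30, end3_30,
#'   annotation, subfamilies, element_ids, discarded count attribute.
#' @export
name_families <- function(elements, te_library = NULL, prefix = "SynHel",
                          params = census_params()) {
  p <- params
  fams <- list()
  discarded <- 0L
  for (ei in seq_along(elements)) {
    cons <- elements[[ei]]$consensus
    ann <- annotate_against_library(cons, te_library)
    if (ann$is_non_helitron) { discarded <- discarded + 1L; next }
    hit <- assign_family(cons, fams, t = p$family_t, W = p$family_w,
                         subfamily_t = p$subfamily_t)
    if (is.na(hit$family)) {
      fi <- length(fams) + 1L
      fams[[fi]] <- list(
        name = sprintf("%s-%d", prefix, fi), consensus = cons,
        end5_30 = substr(cons, 1L, p$family_w),
        end3_30 = substr(cons, nchar(cons) - p$family_w + 1L, nchar(cons)),
        annotation = ann$annotation,
        subfamilies = list(list(name = sprintf("%s-%da", prefix, fi),
                                exemplar = cons)),
        element_ids = ei)
    } else {
      f <- fams[[hit$family]]
      f$element_ids <- c(f$element_ids, ei)
      if (is.na(hit$subfamily)) {
        si <- length(f$subfamilies) + 1L
        f$subfamilies[[si]] <- list(
          name = sprintf("%s-%d%s", prefix, hit$family, letters[si]),
          exemplar = cons)
      }
      fams[[hit$family]] <- f
    }
  }
  attr(fams, "discarded") <- discarded
  fams
}

## ---- per-family statistics -------------------------------------------------

## SantaLucia unified nearest-neighbor free energies (dG37, kcal/mol),
## keyed by the top-strand dinucleotide of a Watson-Crick stack.
NN_DG37 <- c(AA = -1.00, TT = -1.00, AT = -0.88, TA = -0.58,
             CA = -1.45, TG = -1.45, GT = -1.44, AC = -1.44,
             CT = -1.28, AG = -1.28, GA = -1.30, TC = -1.30,
             CG = -2.17, GC = -2.24, GG = -1.84, CC = -1.84)
NN_INIT <- c(GC = 0.98, AT = 1.03)   # per terminal pair

#' Terminal-hairpin stem stability proxy (-dG)
#'
#' Nearest-neighbor stacking free energy summed over the Watson-Crick paired
#' positions of the 3'-terminal hairpin stem (SantaLucia unified dG37
#' parameters, plus terminal-pair initiation). Reported as -dG, so larger
#' values mean a more stable stem. This is a stem-stability score, not a
#' whole-element secondary-structure folding energy.
#'
#' @param consensus family consensus sequence.
#' @param params list from [end_params()].
#' @return -dG in kcal/mol (0 if no terminal hairpin is found).
#' @export
hairpin_dg_proxy <- function(consensus, params = end_params()) {
  p <- params
  p$require_host_t <- FALSE           # consensus ends at the CTRR itself
  hits <- find_end_structures(consensus, params = p)
  hits <- hits[hits$strand == "+", , drop = FALSE]
  if (nrow(hits) == 0) return(0)
  h <- hits[which.max(hits$sl_ctrr_end), ]
  arm5 <- substr(consensus, h$sl_arm5_start + 1L, h$sl_arm5_end)
  arm3 <- substr(consensus, h$sl_arm3_start + 1L, h$sl_arm3_end)
  stem_dg(arm5, arm3)
}

stem_dg <- function(arm5, arm3) {
  L <- nchar(arm5)
  a <- strsplit(arm5, "")[[1]]
  b <- rev(strsplit(arm3, "")[[1]])   # b[t] pairs with a[t]
  comp <- c(A = "T", T = "A", C = "G", G = "C", N = "?")
  paired <- comp[a] == b
  dg <- 0
  for (t in seq_len(L - 1))
    if (paired[t] && paired[t + 1])
      dg <- dg + NN_DG37[[paste0(a[t], a[t + 1])]]
  ends <- which(paired)
  if (length(ends)) {
    for (e in c(ends[1], ends[length(ends)]))
      dg <- dg + if (a[e] %in% c("G", "C")) NN_INIT[["GC"]] else NN_INIT[["AT"]]
  }
  -dg
}

#' Per-family summary report
#'
#' @param family family object (needs `name`, `consensus`, `annotation`).
#' @param calls copy calls for this family ([call_copies()] output).
#' @param genome named character vector of scaffolds.
#' @return one-row data.frame: counts, length range, AT%, -dG proxy,
#'   genome bp and genome fraction.
#' @export
family_report <- function(family, calls, genome) {
  stopifnot(all(calls$family == family$name))
  copies <- calls[calls$kind == "copy", , drop = FALSE]
  lens <- copies$end - copies$start
  data.frame(
    family = family$name,
    n_subfamilies = length(family$subfamilies),
    copy_count = nrow(copies),
    fragment_count = sum(calls$kind == "fragment"),
    intact_count = sum(calls$intact),
    length_min = if (nrow(copies)) min(lens) else NA_integer_,
    length_max = if (nrow(copies)) max(lens) else NA_integer_,
    at_percent = 100 * at_content(family$consensus),
    neg_dG = hairpin_dg_proxy(family$consensus),
    genome_bp = sum(calls$end - calls$start),
    genome_fraction = sum(calls$end - calls$start) / sum(nchar(genome)),
    annotation = family$annotation,
    stringsAsFactors = FALSE)
}

#' Chromosomal distribution of copy calls
#'
#' Chi-square goodness-of-fit of per-chromosome counts against expectation
#' proportional to chromosome length, plus a per-bin occupancy table
#' (`nbins` uniform segments per chromosome).
#'
#' @param calls copy-call data.frame.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param nbins segments per chromosome.
#' @return list(per_chrom, per_bin, p_value, statistic).
#' @export
chromosome_distribution <- function(calls, chrom_lengths, nbins = 100L) {
  if (!all(calls$seq_id %in% names(chrom_lengths)))
    stop("chromosome absent from length table: ",
         paste(setdiff(unique(calls$seq_id), names(chrom_lengths)),
               collapse = ", "))
  counts <- vapply(names(chrom_lengths),
                   function(ch) sum(calls$seq_id == ch), integer(1))
  ct <- stats::chisq.test(counts, p = chrom_lengths / sum(chrom_lengths))
  mids <- (calls$start + calls$end) / 2
  bins <- pmin(nbins, floor(mids / (chrom_lengths[calls$seq_id] / nbins)) + 1L)
  per_bin <- as.data.frame(table(seq_id = calls$seq_id, bin = bins),
                           stringsAsFactors = FALSE)
  per_bin$bin <- as.integer(per_bin$bin)
  list(per_chrom = data.frame(seq_id = names(chrom_lengths), count = counts,
                              length = unname(chrom_lengths)),
       per_bin = per_bin,
       p_value = unname(ct$p.value), statistic = unname(ct$statistic))
}

#' Detect chimeric families (new elements from combinations of old ones)
#'
#' A child family is reported when two non-overlapping segments (overlap at
#' most `max_overlap` of the child length) from two distinct parent
#' consensuses, each at `min_id`+ identity, jointly cover at least `cov` of
#' the child consensus. Segment orientations are recorded.
#'
#' @param families list of family objects (>= 3).
#' @param cov,min_id,max_overlap,min_seg detection thresholds.
#' @return data.frame: child, parent5, strand5, parent3, strand3, breakpoint
#'   coordinates on the child, coverage.
#' @export
detect_chimeric_families <- function(families, cov = 0.80, min_id = 0.80,
                                     max_overlap = 0.10, min_seg = 80L) {
  if (length(families) < 3) return(empty_chimera())
  nm <- vapply(families, `[[`, character(1), "name")
  out <- list()
  for (ci in seq_along(families)) {
    child <- families[[ci]]$consensus
    clen <- nchar(child)
    segs <- list()
    for (pi in seq_along(families)) {
      if (pi == ci) next
      h <- best_local_hit(families[[pi]]$consensus, child)
      if (is.null(h) || h$identity < min_id || h$length < min_seg) next
      segs[[length(segs) + 1L]] <- data.frame(
        parent = nm[pi], cstart = h$b_start, cend = h$b_end,
        strand = h$strand, identity = h$identity)
    }
    if (length(segs) < 2) next
    segs <- do.call(rbind, segs)
    best <- NULL
    for (i in seq_len(nrow(segs) - 1)) for (j in seq(i + 1, nrow(segs))) {
      ov <- min(segs$cend[i], segs$cend[j]) - max(segs$cstart[i], segs$cstart[j])
      if (ov > max_overlap * clen) next
      union_len <- (segs$cend[i] - segs$cstart[i]) +
                   (segs$cend[j] - segs$cstart[j]) - max(0, ov)
      if (union_len < cov * clen) next
      if (is.null(best) || union_len > best$coverage_bp) {
        first <- if (segs$cstart[i] <= segs$cstart[j]) i else j
        second <- if (first == i) j else i
        best <- data.frame(
          child = nm[ci],
          parent5 = segs$parent[first], strand5 = segs$strand[first],
          parent3 = segs$parent[second], strand3 = segs$strand[second],
          break5 = segs$cend[first], break3 = segs$cstart[second],
          coverage_bp = union_len, child_len = clen,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_chimera())
  rownames(res) <- NULL
  res
}

empty_chimera <- function() {
  data.frame(child = character(), parent5 = character(), strand5 = character(),
             parent3 = character(), strand3 = character(),
             break5 = integer(), break3 = integer(),
             coverage_bp = integer(), child_len = integer())
}

#' Genome-wide census over all families
#'
#' Searches every family consensus, calls copies/fragments, and resolves
#' overlapping calls from different families in favour of the highest
#' identity x length score (ties to the lower family index).
#'
#' @param families list of family objects.
#' @param genome named character vector of scaffolds.
#' @param params list from [census_params()].
#' @return data.frame of resolved copy calls for all families.
#' @export
census_genome <- function(families, genome, params = census_params()) {
  all_calls <- list()
  for (fi in seq_along(families)) {
    f <- families[[fi]]
    hsps <- search_genome(f$consensus, genome, params = params)
    cc <- call_copies(hsps, f$consensus, genome, family = f$name,
                      params = params)
    if (nrow(cc)) { cc$family_index <- fi; all_calls[[length(all_calls) + 1L]] <- cc }
  }
  calls <- do.call(rbind, all_calls)
  if (is.null(calls)) return(call_copies(data.frame(seq_id = character(),
    strand = character(), sstart = integer(), send = integer(),
    qstart = integer(), qend = integer(), length = integer(),
    identity = numeric(), score = numeric(), evalue = numeric()),
    "N/A", genome))
  score <- calls$identity * (calls$end - calls$start)
  ord <- order(-score, calls$family_index)
  keep <- rep(TRUE, nrow(calls))
  for (i in ord) {
    if (!keep[i]) next
    lap <- which(keep & calls$seq_id == calls$seq_id[i] &
                 seq_len(nrow(calls)) != i &
                 pmin(calls$end, calls$end[i]) -
                 pmax(calls$start, calls$start[i]) >
                 0.5 * (calls$end - calls$start))
    lap <- lap[score[lap] <= score[i] &
               (score[lap] < score[i] |
                calls$family_index[lap] > calls$family_index[i])]
    keep[lap] <- FALSE
  }
  calls <- calls[keep, , drop = FALSE]
  calls$family_index <- NULL
  rownames(calls) <- NULL
  calls[order(calls$seq_id, calls$start), , drop = FALSE]
}
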