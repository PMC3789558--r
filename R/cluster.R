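## Pipeline steps II-IV: upstream window extraction from end-structure hits,
## greedy identity clustering of the fixed-width 3'-end windows,
## bidirectional member extension, center-star multiple alignment, consensus
## building, and automated element-boundary calling.

#' Default clustering / consensus parameters
#'
#' `window` = 30 bp matches the family-definition window (terminal 30 bp
#' identity > 80%). `min_cluster_size` = 3: a consensus from fewer members is
#' unreliable. Boundary automation thresholds: 60% member agreement over a
#' 10-column sliding window, TC search range 50 columns around the agreement
#' drop-off. Identity is always matches / alignment columns with gaps counted
#' as mismatches.
#'
#' @return named list of parameters.
#' @export
cluster_params <- function() {
  list(window = 30L, t_id = 0.80, min_cluster_size = 3L,
       ext_cap = 15000L, max_members = 20L,
       match = 1, mismatch = -1, gap = -6, band = 64L,
       agree_min = 0.60, agree_window = 10L, contig_window = 50L,
       tc_search = 50L,
       require_host_a = TRUE, min_element = 60L,
       dedupe_cov = 0.90, dedupe_id = 0.80)
}

#' Extract fixed-width windows ending at each hit's CTRR
#'
#' The window covers the `W` strand-local bases ending at (and including) the
#' last CTRR base of each end-structure hit. Hits too close to the contig
#' start are dropped (recorded in the `dropped` attribute).
#'
#' @param hits data.frame from [scan_genome_ends()].
#' @param genome named character vector of scaffolds.
#' @param W window width (bp).
#' @return `hits` with a `window` column; dropped rows removed.
#' @export
extract_window <- function(hits, genome, W = 30L) {
  if (nrow(hits) == 0) { hits$window <- character(0); return(hits) }
  n <- nchar(genome)[hits$seq_id]
  lo <- hits$sl_ctrr_end - W
  keep <- lo >= 0L
  win <- character(nrow(hits))
  oc <- oriented_cache(genome)
  for (i in which(keep)) {
    s <- oc(hits$seq_id[i], hits$strand[i])
    win[i] <- substr(s, lo[i] + 1L, hits$sl_ctrr_end[i])
  }
  out <- hits[keep, , drop = FALSE]
  out$window <- win[keep]
  attr(out, "dropped") <- hits[!keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy centroid clustering of end windows
#'
#' Candidates are processed in deterministic order: unique window strings by
#' descending abundance, then lexicographic. Each joins the first existing
#' centroid with ungapped identity strictly above `t_id` over the full
#' window, else founds a new cluster. Clusters smaller than `min_size` are
#' discarded.
#'
#' @param windows character vector of equal-length windows.
#' @param t_id identity threshold (strict >).
#' @param min_size minimum cluster size retained.
#' @return list of clusters: `list(id, centroid, members)` with `members`
#'   indexing into `windows`.
#' @export
greedy_cluster <- function(windows, t_id = 0.80, min_size = 3L) {
  if (length(windows) == 0) return(list())
  if (length(unique(nchar(windows))) != 1L) stop("mixed window lengths")
  tab <- table(windows)
  uw <- names(tab)[order(-as.integer(tab), names(tab), method = "radix")]
  assign_u <- greedy_assign_cpp(uw, t_id)           # centroid index into uw
  cent_of <- stats::setNames(uw[assign_u], uw)      # window -> centroid window
  cents <- unique(uw[assign_u])                     # founding order
  out <- lapply(seq_along(cents), function(ci) {
    cw <- cents[ci]
    members <- which(cent_of[windows] == cw)
    list(id = sprintf("CL%d", ci), centroid = cw, members = members)
  })
  out <- Filter(function(cl) length(cl$members) >= min_size, out)
  # renumber after size filtering
  for (i in seq_along(out)) out[[i]]$id <- sprintf("CL%d", i)
  out
}

ungapped_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  sum(av == bv) / length(av)
}

#' Extend cluster members bidirectionally
#'
#' Retains at most `max_members` members (highest window identity to the
#' centroid first, ties broken lexicographically by window then by genomic
#' position), then extends each symmetrically around its window up to `cap`
#' total length, truncating (and flagging) at contig edges. Extended
#' sequences are strand-local: they read 5' to 3' along the element.
#'
#' @param cluster one element of the [greedy_cluster()] result.
#' @param hits windowed hits table ([extract_window()] output).
#' @param genome named character vector of scaffolds.
#' @param cap maximum total extended length (bp).
#' @param max_members maximum number of members retained.
#' @return data.frame: member index, coordinates, extended sequence, `anchor`
#'   (position in `seq` of the last CTRR base, 1-based), edge flags.
#' @export
extend_members <- function(cluster, hits, genome, cap = 15000L,
                           max_members = 20L) {
  idx <- cluster$members
  w <- hits$window[idx]
  ident <- vapply(w, ungapped_identity, numeric(1), b = cluster$centroid)
  ord <- order(-ident, w, hits$seq_id[idx], hits$start[idx], method = "radix")
  idx <- idx[ord][seq_len(min(length(idx), max_members))]
  W <- nchar(cluster$centroid)
  ext <- as.integer(floor((cap - W) / 2))
  oc <- oriented_cache(genome)
  rows <- lapply(idx, function(i) {
    sid <- hits$seq_id[i]; st <- hits$strand[i]
    n <- nchar(genome[[sid]])
    hi0 <- hits$sl_ctrr_end[i]
    lo <- max(0L, hi0 - W - ext)
    hi <- min(n, hi0 + ext)
    s <- oc(sid, st)
    data.frame(member = i, seq_id = sid, strand = st,
               sl_lo = lo, sl_hi = hi,
               anchor = hi0 - lo,
               seq = substr(s, lo + 1L, hi),
               clipped5 = lo == 0L && (hi0 - W - ext) < 0L,
               clipped3 = hi == n && (hi0 + ext) > n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

edit_distance_banded <- function(a, b, band = -1L) {
  edit_distance_cpp(a, b, band)
}

#' Center-star multiple alignment
#'
#' The center is the sequence minimising the summed pairwise edit distance
#' (banded for long inputs). Every other sequence is globally aligned to the
#' center (match +1, mismatch -1, gap -2) and the pairwise alignments are
#' merged under "once a gap, always a gap".
#'
## Pairwise global alignment of two sequences sharing a structural anchor
## (e.g. the last CTRR base). The two sides of the anchor are aligned
## independently within a +/- band corridor after clipping to the shorter
## side; unpaired excess on the longer side becomes edge gaps. Anchoring is
## essential for mostly-nonhomologous extensions: an unconstrained global
## alignment of long random flanks will happily shear the homologous core
## to harvest chance matches.
anchored_pair_align <- function(a, b, anchor_a, anchor_b,
                                match, mismatch, gap, band) {
  La <- anchor_a; Lb <- anchor_b
  L <- min(La, Lb)
  Ta <- nchar(a) - La; Tb <- nchar(b) - Lb
  TT <- min(Ta, Tb)
  up <- align_cpp(substr(a, La - L + 1L, La), substr(b, Lb - L + 1L, Lb),
                  match, mismatch, gap, band = band, local = FALSE)
  dn <- align_cpp(substr(a, La + 1L, La + TT), substr(b, Lb + 1L, Lb + TT),
                  match, mismatch, gap, band = band, local = FALSE)
  lead_a <- if (La > L) substr(a, 1L, La - L) else strrep("-", Lb - L)
  lead_b <- if (Lb > L) substr(b, 1L, Lb - L) else strrep("-", La - L)
  tail_a <- if (Ta > TT) substr(a, La + TT + 1L, nchar(a))
            else strrep("-", Tb - TT)
  tail_b <- if (Tb > TT) substr(b, Lb + TT + 1L, nchar(b))
            else strrep("-", Ta - TT)
  list(a_aln = paste0(lead_a, up$a_aln, dn$a_aln, tail_a),
       b_aln = paste0(lead_b, up$b_aln, dn$b_aln, tail_b),
       score = up$score + dn$score)
}

anchored_edit_distance <- function(a, b, anchor_a, anchor_b, band) {
  L <- min(anchor_a, anchor_b)
  TT <- min(nchar(a) - anchor_a, nchar(b) - anchor_b)
  edit_distance_cpp(substr(a, anchor_a - L + 1L, anchor_a),
                    substr(b, anchor_b - L + 1L, anchor_b), band) +
    edit_distance_cpp(substr(a, anchor_a + 1L, anchor_a + TT),
                      substr(b, anchor_b + 1L, anchor_b + TT), band) +
    abs(anchor_a - anchor_b) +
    abs((nchar(a) - anchor_a) - (nchar(b) - anchor_b))
}

#' @param seqs character vector (1-20 sequences).
#' @param match,mismatch,gap alignment scores.
#' @param band DP band half-width (used when sequences are long; `-1` = full).
#' @param anchors optional per-sequence anchor positions (a shared structural
#'   coordinate, e.g. the last CTRR base); when given, pairwise alignments
#'   are split at the anchor and banded around it, which keeps the
#'   homologous core aligned even when flank lengths differ.
#' @return list: `msa` (gapped rows, input order), `center` (index).
#' @export
center_star_align <- function(seqs, match = 1, mismatch = -1, gap = -2,
                              band = -1L, anchors = NULL) {
  n <- length(seqs)
  stopifnot(n >= 1)
  if (n == 1) return(list(msa = seqs, center = 1L))
  pair_dist <- function(i, j) {
    if (!is.null(anchors))
      anchored_edit_distance(seqs[i], seqs[j], anchors[i], anchors[j], band)
    else
      edit_distance_banded(seqs[i], seqs[j],
                           if (band < 0) -1L
                           else band + abs(nchar(seqs[i]) - nchar(seqs[j])))
  }
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- pair_dist(i, j)
    dmat[i, j] <- d; dmat[j, i] <- d
  }
  center <- which.min(rowSums(dmat))
  cs <- seqs[center]
  nc <- nchar(cs)
  others <- setdiff(seq_len(n), center)
  # per-alignment center gap profile: gaps_after[i+1] = gaps after residue i
  gaps <- matrix(0L, nrow = n, ncol = nc + 1L)
  blocks <- vector("list", n)   # member chars per center gap slot + residues
  for (j in others) {
    al <- if (!is.null(anchors))
      anchored_pair_align(cs, seqs[j], anchors[center], anchors[j],
                          match, mismatch, gap, band)
    else
      align_cpp(cs, seqs[j], match, mismatch, gap,
                band = if (band < 0) -1L
                       else band + abs(nchar(cs) - nchar(seqs[j])),
                local = FALSE)
    ca <- strsplit(al$a_aln, "", fixed = TRUE)[[1]]
    sa <- strsplit(al$b_aln, "", fixed = TRUE)[[1]]
    slot <- cumsum(ca != "-")            # 0 = before first center residue
    g <- tabulate(slot[ca == "-"] + 1L, nbins = nc + 1L)
    gaps[j, ] <- g
    blocks[[j]] <- list(ca = ca, sa = sa, slot = slot)
  }
  final_gaps <- apply(gaps, 2, max)          # slot i+1 = gaps after residue i
  cumg <- cumsum(final_gaps)                 # gaps up to and incl. slot i+1
  pos_res <- cumg[seq_len(nc)] + seq_len(nc) # final column of center residue r
  slot_start <- c(0L, pos_res)               # last column before slot's block
  total <- nc + cumg[nc + 1L]
  rows <- character(n)
  cres <- strsplit(cs, "", fixed = TRUE)[[1]]
  row_c <- rep("-", total)
  row_c[pos_res] <- cres
  rows[center] <- paste(row_c, collapse = "")
  for (j in others) {
    bl <- blocks[[j]]
    is_res <- bl$ca != "-"
    row_j <- rep("-", total)
    row_j[pos_res[bl$slot[is_res]]] <- bl$sa[is_res]
    if (any(!is_res)) {
      gslot <- bl$slot[!is_res]
      rank <- stats::ave(seq_along(gslot), gslot, FUN = seq_along)
      row_j[slot_start[gslot + 1L] + rank] <- bl$sa[!is_res]
    }
    rows[j] <- paste(row_j, collapse = "")
  }
  stopifnot(length(unique(nchar(rows))) == 1L)
  list(msa = rows, center = center)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa, "", fixed = TRUE))
}

## modal non-gap base per MSA column (input: members x positions character
## matrix); ties broken A > C > G > T. Returns "" for all-gap columns.
column_consensus <- function(m) {
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, bases))
  top <- max.col(counts, ties.method = "first")  # column order = A,C,G,T
  out <- bases[top]
  out[rowSums(counts) == 0] <- ""
  out
}

#' Majority-rule consensus of an MSA
#'
#' Columns with gap fraction above `gap_drop` are dropped; remaining columns
#' take the majority base (ties A > C > G > T).
#'
#' @param msa character vector of equal-length gapped rows.
#' @param gap_drop drop columns whose gap fraction exceeds this.
#' @return consensus DNA string.
#' @export
build_consensus <- function(msa, gap_drop = 0.5) {
  stopifnot(length(msa) >= 1)
  m <- msa_matrix(msa)
  gapfrac <- colMeans(m == "-")
  keep <- gapfrac <= gap_drop
  cons <- column_consensus(m[, keep, drop = FALSE])
  paste(cons[cons != ""], collapse = "")
}

col_of_residue <- function(gapped_row, residue_idx) {
  which(strsplit(gapped_row, "", fixed = TRUE)[[1]] != "-")[residue_idx]
}

## exact mean/sd of the modal-base fraction of n i.i.d. draws from base
## probabilities p (length 4). With few rows the modal fraction of a random
## column is large (~0.6 for n = 4), so agreement thresholds must be
## calibrated against this null rather than fixed.
null_modal_stats <- function(n, p) {
  mu <- 0; m2 <- 0
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    d <- n - a - b - cc
    pr <- stats::dmultinom(c(a, b, cc, d), prob = p)
    f <- max(a, b, cc, d) / n
    mu <- mu + pr * f
    m2 <- m2 + pr * f * f
  }
  list(mu = mu, sd = sqrt(max(0, m2 - mu * mu)))
}

#' Automated element-boundary calling
#'
#' The 3' boundary is the MSA column of the centroid's last CTRR base (known
#' from the end structure). The 5' boundary is the outermost column where
#' mean member agreement with the column consensus over a sliding
#' `agree_window` is at least `agree_min` inside the element and drops below
#' it immediately outside, and where the consensus begins `TC` with the
#' preceding host column majority `A` (searched within `tc_search` columns of
#' the agreement drop-off). Elements with no TC-compatible boundary are
#' rejected with a reason code.
#'
#' @param msa gapped rows (from [center_star_align()]).
#' @param anchor_col MSA column index (1-based) of the centroid's CTRR last
#'   base.
#' @param params list from [cluster_params()].
#' @return list with `consensus`, `col5`, `col3`, `boundary_confidence`,
#'   `agreement`, and `reject_reason` (`NULL` on success).
#' @export
call_boundaries <- function(msa, anchor_col, params = cluster_params()) {
  p <- params
  m <- msa_matrix(msa)
  ncols <- ncol(m)
  cons <- column_consensus(m)
  agree <- sapply(seq_len(ncols), function(cc)
    if (cons[cc] == "") 0 else mean(m[, cc] == cons[cc]))
  w <- p$agree_window
  # calibrate the agreement threshold against the null modal fraction for
  # this row count and base composition (small alignments have high null
  # agreement; z = 4 over the sliding window keeps false drop-offs rare)
  base_freq <- table(factor(m[m != "-"], levels = c("A", "C", "G", "T")))
  base_freq <- (base_freq + 1) / sum(base_freq + 1)
  nstats <- null_modal_stats(nrow(m), as.numeric(base_freq))
  thr <- max(p$agree_min, nstats$mu + 4 * nstats$sd / sqrt(w))
  inside_mean <- function(c0) {
    cols <- c0:min(ncols, c0 + w - 1L); mean(agree[cols])
  }
  outside_mean <- function(c0) {
    cols <- max(1L, c0 - w):(c0 - 1L)
    if (c0 == 1L) 0 else mean(agree[cols])
  }
  cand <- integer(0)
  for (c0 in seq_len(anchor_col)) {
    if (inside_mean(c0) >= thr && outside_mean(c0) < thr)
      cand <- c(cand, c0)
  }
  if (length(cand) == 0)
    return(list(reject_reason = "no_agreement_dropoff"))
  gapfrac <- colMeans(m == "-")
  eff <- which(gapfrac <= 0.5 & cons != "")   # columns that survive consensus
  # outermost drop-off with a TC-compatible boundary nearby wins; the
  # element must be contiguous (agreement sustained in every sliding
  # contig_window through to the anchor), which rejects drop-offs caused by
  # shared repeats further out in the flanks
  cw <- min(p$contig_window, anchor_col)
  cum <- cumsum(c(0, agree))
  contiguous_ok <- function(d) {
    if (anchor_col - d + 1L <= cw) return(mean(agree[d:anchor_col]) >= thr)
    starts <- d:(anchor_col - cw + 1L)
    min((cum[starts + cw] - cum[starts]) / cw) >= thr
  }
  col5 <- NA_integer_
  for (d in cand) {
    if (!contiguous_ok(d)) next
    lo <- max(1L, d - 5L); hi <- min(anchor_col - 1L, d + p$tc_search)
    tc_cand <- integer(0)
    for (c0 in eff[eff >= lo & eff <= hi]) {
      nxt <- eff[eff > c0][1L]
      if (is.na(nxt)) break
      if (cons[c0] == "T" && cons[nxt] == "C") {
        if (p$require_host_a) {
          host <- rev(eff[eff < c0])[1L]
          if (is.na(host) || cons[host] != "A") next
        }
        tc_cand <- c(tc_cand, c0)
      }
    }
    if (length(tc_cand)) {
      # the true boundary maximises the agreement contrast: element-level
      # agreement just inside, flank-level just outside
      score <- vapply(tc_cand, function(c0)
        inside_mean(c0) - outside_mean(c0), numeric(1))
      col5 <- tc_cand[which.max(score)]
      break
    }
  }
  if (is.na(col5))
    return(list(reject_reason = "no_tc_boundary"))
  keep <- eff[eff >= col5 & eff <= anchor_col]
  consensus <- paste(cons[keep], collapse = "")
  if (nchar(consensus) < p$min_element)
    return(list(reject_reason = "too_short"))
  if (!startsWith(consensus, "TC"))
    return(list(reject_reason = "consensus_not_tc"))
  if (!substr(consensus, nchar(consensus) - 3L, nchar(consensus)) %in% CTRR_MOTIFS)
    return(list(reject_reason = "consensus_not_ctrr"))
  list(consensus = consensus, col5 = col5, col3 = anchor_col,
       boundary_confidence = inside_mean(col5), agreement = agree,
       reject_reason = NULL)
}

## map element MSA columns back to each member's genomic interval
member_loci_from_msa <- function(msa, ext, col5, col3, genome) {
  rows <- lapply(seq_along(msa), function(j) {
    chars <- strsplit(msa[j], "", fixed = TRUE)[[1]]
    res_cols <- which(chars != "-")
    inside <- res_cols[res_cols >= col5 & res_cols <= col3]
    if (length(inside) < 1) return(NULL)
    r1 <- match(inside[1], res_cols)          # residue indices in member seq
    r2 <- match(inside[length(inside)], res_cols)
    sl_start <- ext$sl_lo[j] + r1 - 1L
    sl_end <- ext$sl_lo[j] + r2
    n <- nchar(genome[[ext$seq_id[j]]])
    pp <- sl_to_plus(sl_start, sl_end, n, ext$strand[j])
    data.frame(seq_id = ext$seq_id[j], start = pp$start, end = pp$end,
               strand = ext$strand[j], member = ext$member[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

#' Remove redundant (contained) consensus elements
#'
#' A consensus covered over at least `cov` of its length at `min_id` identity
#' by a longer consensus is dropped. Chance interior end structures shared by
#' every copy of a family otherwise produce truncated duplicates of the
#' family consensus; this containment filter automates the curation step that
#' collapses them.
#'
#' @param elements list of boundary-called elements (each with `$consensus`).
#' @param cov,min_id containment coverage and identity thresholds.
#' @return filtered list.
#' @export
dedupe_elements <- function(elements, cov = 0.90, min_id = 0.80) {
  if (length(elements) <= 1) return(elements)
  lens <- vapply(elements, function(e) nchar(e$consensus), integer(1))
  ord <- order(-lens)
  drop <- logical(length(elements))
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (drop[i]) next
    for (b in seq_along(ord)) {
      j <- ord[b]
      if (i == j || drop[j] || lens[j] > lens[i]) next
      if (lens[j] == lens[i] && j < i) next
      hit <- best_local_hit(elements[[j]]$consensus, elements[[i]]$consensus)
      if (!is.null(hit) &&
          hit$length >= cov * lens[j] && hit$identity >= min_id)
        drop[j] <- TRUE
    }
  }
  elements[!drop]
}

## best local alignment of a vs b (either orientation), summary stats only
best_local_hit <- function(a, b) {
  pick <- NULL
  for (q in c(a, revcomp(a))) {
    al <- align_cpp(q, b, 1, -1, -2, local = TRUE)
    if (nchar(al$a_aln) == 0) next
    cols <- nchar(al$a_aln)
    id <- ungapped_identity(al$a_aln, al$b_aln)
    h <- list(score = al$score, length = cols, identity = id,
              a_start = al$a_start, a_end = al$a_end,
              b_start = al$b_start, b_end = al$b_end,
              strand = if (identical(q, a)) "+" else "-")
    if (is.null(pick) || h$score > pick$score) pick <- h
  }
  pick
}

#' Build consensus elements from end-structure hits
#'
#' Runs window extraction, greedy clustering, member extension, center-star
#' alignment, consensus building, boundary calling and redundancy removal.
#'
#' @param hits data.frame from [scan_genome_ends()].
#' @param genome named character vector of scaffolds.
#' @param params list from [cluster_params()].
#' @return list with `elements` (accepted consensus elements, each carrying
#'   `consensus`, `member_loci`, `msa`, `cluster_id`, `boundary_confidence`)
#'   and `rejections` (data.frame of cluster id + reason).
#' @export
build_families <- function(hits, genome, params = cluster_params()) {
  p <- params
  hw <- extract_window(hits, genome, W = p$window)
  clusters <- greedy_cluster(hw$window, t_id = p$t_id,
                             min_size = p$min_cluster_size)
  elements <- list()
  rej <- list()
  for (cl in clusters) {
    ext <- extend_members(cl, hw, genome, cap = p$ext_cap,
                          max_members = p$max_members)
    al <- center_star_align(ext$seq, match = p$match, mismatch = p$mismatch,
                            gap = p$gap, band = p$band, anchors = ext$anchor)
    anchor_col <- col_of_residue(al$msa[al$center], ext$anchor[al$center])
    bc <- call_boundaries(al$msa, anchor_col, params = p)
    if (!is.null(bc$reject_reason)) {
      rej[[length(rej) + 1L]] <- data.frame(cluster = cl$id,
                                            reason = bc$reject_reason)
      next
    }
    loci <- member_loci_from_msa(al$msa, ext, bc$col5, bc$col3, genome)
    elements[[length(elements) + 1L]] <- list(
      cluster_id = cl$id, consensus = bc$consensus,
      member_loci = loci, msa = al$msa,
      boundary_confidence = bc$boundary_confidence)
  }
  elements <- dedupe_elements(elements, cov = p$dedupe_cov, min_id = p$dedupe_id)
  list(elements = elements,
       rejections = if (length(rej)) do.call(rbind, rej)
                    else data.frame(cluster = character(), reason = character()),
       dropped_candidates = attr(hw, "dropped"))
}
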