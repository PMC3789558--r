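## Insertion dating (Kimura 2-parameter distances, T = k/2r), family
## diversity (pairwise mismatch distributions with burst-modality
## classification), and neighbor-joining trees.

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura 2-parameter distance between two aligned sequences
#'
#' `k = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` the transition and
#' `Q` the transversion fraction over retained sites. Sites where either
#' sequence has a gap or `N` are excluded (pairwise deletion).
#'
#' @param a,b equal-length aligned strings (may contain `-`/`N`).
#' @return K2P distance (substitutions/site).
#' @export
kimura2p <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("kimura2p(): zero retained sites after pairwise deletion")
  av <- av[ok]; bv <- bv[ok]
  n <- length(av)
  diff <- av != bv
  ts <- diff & (TRANSITIONS[av] == bv)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("kimura2p(): distance saturated (P=", round(P, 3),
         ", Q=", round(Q, 3), ")")
  -0.5 * log(w1 * sqrt(w2))
}

#' Insertion age from a K2P distance
#'
#' `T = k / (2 r)` with `r` the neutral substitution rate per site per year
#' (default 1.56e-8).
#'
#' @param k K2P distance (>= 0).
#' @param r neutral rate, substitutions/site/year.
#' @return age in years.
#' @export
age_from_k <- function(k, r = 1.56e-8) {
  stopifnot(r > 0)
  if (any(k < 0)) stop("age_from_k(): negative k")
  k / (2 * r)
}

#' Pairwise mismatch distribution of aligned family members
#'
#' Counts differing columns (both bases non-gap, non-N) for every unordered
#' pair of members; the histogram uses integer bins of width 1.
#'
#' @param aligned character vector of >= 3 equal-length aligned member
#'   sequences.
#' @return list: `diffs` (per-pair counts, length n(n-1)/2), `hist` (named
#'   integer vector over difference counts).
#' @export
mismatch_distribution <- function(aligned) {
  n <- length(aligned)
  if (n < 3) stop("mismatch_distribution(): need >= 3 members")
  stopifnot(length(unique(nchar(aligned))) == 1L)
  m <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  diffs <- integer(n * (n - 1) / 2)
  idx <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    idx <- idx + 1L
    ok <- valid[i, ] & valid[j, ]
    diffs[idx] <- sum(m[i, ok] != m[j, ok])
  }
  h <- table(factor(diffs, levels = 0:max(diffs)))
  list(diffs = diffs, hist = stats::setNames(as.integer(h), names(h)))
}

#' Classify the modality of a mismatch distribution
#'
#' The per-pair difference counts are smoothed with a Gaussian kernel
#' (Silverman's rule-of-thumb bandwidth). Local maxima of the density count
#' as peaks when their height is at least `peak_frac` of the global maximum
#' and the valley separating adjacent peaks drops at least `valley_frac`
#' below the smaller of the two. 1 peak = unimodal (a single expansion
#' burst), 2 = bimodal, >= 3 = multimodal. Invariant to rescaling the
#' histogram counts.
#'
#' @param x either the list from [mismatch_distribution()], a named histogram
#'   vector, or a raw vector of pairwise differences.
#' @param peak_frac minimum peak height as a fraction of the global maximum.
#' @param valley_frac required relative valley depth between peaks.
#' @return one of `"unimodal"`, `"bimodal"`, `"multimodal"`.
#' @export
classify_modality <- function(x, peak_frac = 0.10, valley_frac = 0.50) {
  if (is.list(x) && !is.null(x$diffs)) {
    sample <- x$diffs
  } else if (!is.null(names(x))) {
    counts <- as.numeric(x)
    vals <- as.numeric(names(x))
    if (sum(counts) < 1) return("unimodal")
    # rescale histogram to a manageable sample; modality is scale-invariant
    scale <- max(1, sum(counts) / 5000)
    reps <- round(counts / scale)
    if (sum(reps) < 10) reps <- counts
    sample <- rep(vals, reps)
  } else {
    sample <- as.numeric(x)
  }
  if (length(sample) < 10)
    stop("classify_modality(): need >= 10 pairwise differences")
  if (stats::sd(sample) == 0) return("unimodal")
  # Silverman's rule, floored at the histogram bin width (1 difference) so
  # that integer discreteness cannot masquerade as multimodality
  d <- stats::density(sample, bw = max(stats::bw.nrd0(sample), 1))
  y <- d$y
  n <- length(y)
  locmax <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) locmax <- c(1L, locmax)
  if (y[n] > y[n - 1]) locmax <- c(locmax, n)
  locmax <- locmax[y[locmax] >= peak_frac * max(y)]
  if (length(locmax) <= 1) return("unimodal")
  # merge adjacent peaks whose separating valley is too shallow
  peaks <- locmax[order(locmax)]
  kept <- peaks[1]
  for (pk in peaks[-1]) {
    prev <- kept[length(kept)]
    valley <- min(y[prev:pk])
    smaller <- min(y[prev], y[pk])
    if (valley <= (1 - valley_frac) * smaller) {
      kept <- c(kept, pk)
    } else if (y[pk] > y[prev]) {
      kept[length(kept)] <- pk
    }
  }
  c("unimodal", "bimodal")[match(min(length(kept), 3L), c(1L, 2L),
                                 nomatch = NA)] -> lab
  if (is.na(lab)) "multimodal" else lab
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (via the standard NJ implementation in
#' \pkg{ape}); additive matrices are recovered exactly. Negative branch
#' lengths are clamped to zero and flagged in the `clamped` attribute.
#'
#' @param d symmetric numeric matrix with zero diagonal, size >= 3, row/col
#'   names used as taxon labels.
#' @return an [ape::as.phylo] tree (unrooted, binary for >= 3 taxa) with a
#'   `clamped` attribute (number of clamped branches).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("nj_tree(): non-finite distances")
  if (nrow(d) < 3) stop("nj_tree(): need >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("nj_tree(): matrix not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("nj_tree(): nonzero diagonal")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tr <- ape::nj(d)
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Write trees to a newick file
#' @param trees a `phylo` or list of `phylo` objects.
#' @param path output file.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ape::write.tree(do.call(c, lapply(trees, identity)), file = path)
  invisible(path)
}

#' Date every copy of every family
#'
#' For each copy call, the genomic sequence is globally aligned to its family
#' consensus and the K2P distance and implied age are computed
#' (copy-vs-consensus, as for master-element dating; mismatch distributions
#' are copy-vs-copy and computed separately).
#'
#' @param calls copy-call data.frame (intact copies are dated; fragments are
#'   skipped).
#' @param families list of family objects.
#' @param genome named character vector of scaffolds.
#' @param r neutral substitution rate per site per year.
#' @param band DP band half-width for the alignment.
#' @return data.frame: copy id, family, k, age_years.
#' @export
date_copies <- function(calls, families, genome, r = 1.56e-8, band = 64L) {
  cons <- stats::setNames(
    lapply(families, `[[`, "consensus"),
    vapply(families, `[[`, character(1), "name"))
  use <- which(calls$kind == "copy")
  rows <- lapply(use, function(i) {
    s <- oriented_seq(genome[[calls$seq_id[i]]], calls$strand[i])
    n <- nchar(genome[[calls$seq_id[i]]])
    sl <- if (calls$strand[i] == "+") c(calls$start[i], calls$end[i])
          else c(n - calls$end[i], n - calls$start[i])
    copy <- substr(s, sl[1] + 1L, sl[2])
    cs <- cons[[calls$family[i]]]
    al <- align_cpp(copy, cs, 1, -1, -2,
                    band = band + abs(nchar(copy) - nchar(cs)), local = FALSE)
    k <- tryCatch(kimura2p(al$a_aln, al$b_aln), error = function(e) NA_real_)
    data.frame(copy_id = sprintf("%s:%d-%d(%s)", calls$seq_id[i],
                                 calls$start[i], calls$end[i],
                                 calls$strand[i]),
               family = calls$family[i], intact = calls$intact[i],
               k = k, age_years = if (is.na(k)) NA_real_ else age_from_k(k, r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(copy_id = character(), family = character(),
                      intact = logical(), k = numeric(),
                      age_years = numeric()))
  rownames(out) <- NULL
  out
}

#' Extract aligned copies of one family for diversity analysis
#'
#' Copies are globally aligned to the family consensus; the consensus
#' coordinate frame (columns where the consensus has no gap) makes the rows
#' mutually aligned.
#'
#' @param calls copy calls of one family.
#' @param consensus family consensus.
#' @param genome named character vector of scaffolds.
#' @param band DP band half-width.
#' @return character vector of aligned copy sequences (consensus frame).
#' @export
aligned_family_copies <- function(calls, consensus, genome, band = 64L) {
  use <- which(calls$kind == "copy")
  vapply(use, function(i) {
    s <- oriented_seq(genome[[calls$seq_id[i]]], calls$strand[i])
    n <- nchar(genome[[calls$seq_id[i]]])
    sl <- if (calls$strand[i] == "+") c(calls$start[i], calls$end[i])
          else c(n - calls$end[i], n - calls$start[i])
    copy <- substr(s, sl[1] + 1L, sl[2])
    al <- align_cpp(copy, consensus, 1, -1, -2,
                    band = band + abs(nchar(copy) - nchar(consensus)),
                    local = FALSE)
    cs <- strsplit(al$b_aln, "", fixed = TRUE)[[1]]
    paste(strsplit(al$a_aln, "", fixed = TRUE)[[1]][cs != "-"], collapse = "")
  }, character(1))
}
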