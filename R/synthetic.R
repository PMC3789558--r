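## Synthetic AT-rich genomes with planted Helitron families diverged under a
## star-burst model, plus ground-truth tables, synthetic gene models and
## companion protein/EST/cDNA sets. Everything is deterministic under a
## fixed seed.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, at_fraction = 0.62) {
  p <- c(at_fraction / 2, (1 - at_fraction) / 2,
         (1 - at_fraction) / 2, at_fraction / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a master Helitron element
#'
#' The master starts with `TC`, ends with a random CTRR motif, and carries a
#' perfect 8-bp-stem / 4-nt-loop hairpin 5-15 nt upstream of the CTRR; the
#' interior is i.i.d. sequence with the requested AT bias. The returned
#' string has attributes `protect3_start` (0-based start of the 3' terminal
#' structure: hairpin arms through CTRR) and `sep` (hairpin-CTRR spacer).
#'
#' @param length total element length (>= 200).
#' @param at_fraction AT fraction of the interior.
#' @param seed optional RNG seed (`NULL` = use the current RNG stream).
#' @return DNA string with structure attributes.
#' @export
make_master <- function(length, at_fraction = 0.62, seed = NULL) {
  if (length < 200) stop("make_master(): length < 200")
  if (!is.null(seed)) set.seed(seed)
  sep <- sample(5:15, 1)
  ctrr <- sample(CTRR_MOTIFS, 1)
  arm5 <- random_dna(8, at_fraction)
  loop <- random_dna(4, at_fraction)
  interior_len <- length - 2L - 8L - 4L - 8L - sep - 4L
  interior <- random_dna(interior_len, at_fraction)
  seq <- paste0("TC", interior, arm5, loop, revcomp(arm5),
                random_dna(sep, at_fraction), ctrr)
  stopifnot(nchar(seq) == length)
  attr(seq, "protect3_start") <- 2L + interior_len
  attr(seq, "sep") <- sep
  seq
}

## exact K2P per-site substitution probabilities at distance d with
## transition:transversion expectation ratio R
k2p_site_probs <- function(d, R = 2) {
  bt <- d / (2 * R + 2)           # beta * t (each transversion type)
  at <- d * R / (R + 1)           # alpha * t
  P <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  Q <- 0.5 - 0.5 * exp(-4 * bt)
  c(P = P, Q = Q)
}

#' Mutate a master into a diverged copy
#'
#' Sites substitute independently under the Kimura 2-parameter process so
#' that the expected K2P distance to the master equals `target_k` with the
#' configured transition:transversion ratio. The 3' terminal structure
#' (hairpin arms through CTRR) is always exempt so the copy remains a
#' detectable end-structure candidate; the 5' `TC` is additionally exempt
#' when `intact = TRUE`.
#'
#' @param master string from [make_master()] (or any DNA string; provide
#'   `protect3_start` to shield a 3' block).
#' @param target_k expected K2P divergence (0 <= k < 0.5).
#' @param ts_tv_ratio expected transition:transversion count ratio.
#' @param seed optional RNG seed.
#' @param intact protect the 5' TC.
#' @param protect3_start 0-based start of the protected 3' block (defaults to
#'   the master's attribute; `NA` disables).
#' @return mutated DNA string.
#' @export
mutate_copy <- function(master, target_k, ts_tv_ratio = 2, seed = NULL,
                        intact = TRUE,
                        protect3_start = attr(master, "protect3_start")) {
  if (target_k < 0 || target_k >= 0.5)
    stop("mutate_copy(): target_k must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  x <- strsplit(as.character(master), "", fixed = TRUE)[[1]]
  n <- length(x)
  pq <- k2p_site_probs(target_k, ts_tv_ratio)
  u <- stats::runif(n)
  protected <- logical(n)
  if (intact) protected[1:2] <- TRUE
  if (!is.null(protect3_start) && !is.na(protect3_start))
    protected[(protect3_start + 1L):n] <- TRUE
  ts_idx <- which(u < pq["P"] & !protected)
  tv_idx <- which(u >= pq["P"] & u < pq["P"] + pq["Q"] & !protected)
  x[ts_idx] <- TRANSITIONS[x[ts_idx]]
  if (length(tv_idx)) {
    tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                   C = c("A", "G"), T = c("A", "G"))
    pick <- stats::runif(length(tv_idx)) < 0.5
    x[tv_idx] <- mapply(function(b, p) tv_map[[b]][p + 1L],
                        x[tv_idx], pick)
  }
  paste(x, collapse = "")
}

#' Default simulation configuration
#'
#' The standard study conditions: a 2-Mb AT-rich (62%) chromosome carrying
#' three Helitron families of 50 copies each at per-copy divergences
#' k = 0.02, 0.05 and 0.08 from their masters (star phylogeny, single
#' burst), 20% of copies 5'-truncated, and one family carrying a captured
#' host-gene exon fragment. Eight synthetic multi-exon genes provide the
#' protein/EST/cDNA companions.
#'
#' @param seed RNG seed.
#' @return nested configuration list for [simulate_genome()].
#' @export
default_sim_config <- function(seed = 1L) {
  list(
    genome_length = 2e6, at_fraction = 0.62, seed = seed,
    n_genes = 8L, min_spacing = 300L,
    families = list(
      list(name = "famA", n_copies = 50L, master_length = 800L,
           target_k = 0.02, ts_tv_ratio = 2, truncated_fraction = 0.2,
           capture = NULL, capture_fraction = 0),
      list(name = "famB", n_copies = 50L, master_length = 1200L,
           target_k = 0.05, ts_tv_ratio = 2, truncated_fraction = 0.2,
           capture = list(donor = "gene1", length = 300L),
           capture_fraction = 1),
      list(name = "famC", n_copies = 50L, master_length = 1600L,
           target_k = 0.08, ts_tv_ratio = 2, truncated_fraction = 0.2,
           capture = NULL, capture_fraction = 0)))
}

## random stop-free coding sequence beginning ATG, length divisible by 3
random_cds <- function(n_codons) {
  codons <- character(n_codons)
  codons[1] <- "ATG"
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(n_codons)[-1]) {
    repeat {
      cd <- paste(sample(BASES, 3, replace = TRUE), collapse = "")
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  paste(codons, collapse = "")
}

#' Simulate a genome with planted Helitron families
#'
#' Generates an AT-biased background, splices in synthetic multi-exon genes
#' (stop-free coding sequence), inserts diverged element copies at `A|T`
#' dinucleotides (so every insertion is flanked by a 5' A and a 3' T),
#' applies per-family 5' truncation (uniform 20-80% of copies marked
#' truncated) and master-level gene-fragment capture, and returns the
#' genome together with a ground-truth table, gene models and companion
#' protein/EST/cDNA sets.
#'
#' @param config list from [default_sim_config()].
#' @return list: `genome` (named character vector), `truth` (per-element
#'   data.frame), `genes` (gene/exon interval table), `proteins`, `cdna`,
#'   `ests` (named character vectors), `orfs` (cDNA ORF coordinates),
#'   `masters` (named character vector), `config`.
#' @export
simulate_genome <- function(config = default_sim_config()) {
  set.seed(config$seed)
  glen <- as.integer(config$genome_length)
  bg <- random_dna(glen, config$at_fraction)

  ## ---- genes: utr5+cds1 | intron | cds2 | intron | cds3+utr3 ----
  n_genes <- config$n_genes
  utr <- 60L; cds_len <- c(300L, 300L, 300L); intr <- 200L
  gene_span <- utr + sum(cds_len) + 2L * intr + utr
  gene_starts <- integer(0)
  cand <- sort(sample.int(glen - gene_span - 1L, n_genes * 20))
  for (s in cand) {
    if (all(abs(s - gene_starts) > gene_span + config$min_spacing))
      gene_starts <- c(gene_starts, s)
    if (length(gene_starts) == n_genes) break
  }
  if (length(gene_starts) < n_genes) stop("could not place genes")
  genes <- list(); proteins <- character(0); cdna <- character(0)
  orfs <- list(); exon_iv <- list()
  bg_chars <- strsplit(bg, "", fixed = TRUE)[[1]]
  for (gi in seq_len(n_genes)) {
    g0 <- gene_starts[gi]
    id <- sprintf("gene%d", gi)
    cds_seq <- lapply(cds_len / 3L, random_cds)
    # exon/intron layout (0-based offsets within the gene)
    e1 <- c(0L, utr + cds_len[1])
    e2 <- c(e1[2] + intr, e1[2] + intr + cds_len[2])
    e3 <- c(e2[2] + intr, e2[2] + intr + cds_len[3] + utr)
    # splice stop-free CDS into the background
    put <- function(off, s)
      bg_chars[(g0 + off + 1L):(g0 + off + nchar(s))] <<-
        strsplit(s, "", fixed = TRUE)[[1]]
    put(utr, cds_seq[[1]])
    put(e2[1], cds_seq[[2]])
    put(e3[1], cds_seq[[3]])
    genes[[gi]] <- rbind(
      data.frame(seq_id = "chr1", start = g0, end = g0 + gene_span,
                 strand = "+", type = "gene", ID = id),
      data.frame(seq_id = "chr1",
                 start = g0 + c(e1[1], e2[1], e3[1]),
                 end = g0 + c(e1[2], e2[2], e3[2]),
                 strand = "+", type = "exon",
                 ID = sprintf("%s.exon%d", id, 1:3)))
    exon_iv[[gi]] <- cbind(g0 + c(e1[1], e2[1], e3[1]),
                           g0 + c(e1[2], e2[2], e3[2]))
    cds_all <- paste(unlist(cds_seq), collapse = "")
    utr5 <- substr(bg, g0 + 1L, g0 + utr)
    utr3 <- substr(bg, g0 + e3[1] + cds_len[3] + 1L, g0 + gene_span)
    proteins[id] <- as.character(
      Biostrings::translate(Biostrings::DNAString(cds_all)))
    cdna[id] <- paste0(utr5, cds_all, utr3)
    orfs[[gi]] <- data.frame(cdna_id = id, orf_start = utr,
                             orf_end = utr + sum(cds_len))
  }
  bg <- paste(bg_chars, collapse = "")
  genes <- do.call(rbind, genes)
  exon_iv <- do.call(rbind, exon_iv)

  ## ESTs: two 300-bp windows per cDNA
  ests <- character(0)
  for (id in names(cdna)) {
    for (r in 1:2) {
      s0 <- sample.int(nchar(cdna[[id]]) - 300L, 1)
      ests[sprintf("EST_%s_%d", id, r)] <- substr(cdna[[id]], s0, s0 + 299L)
    }
  }

  ## ---- masters (with optional captured exon fragment) ----
  masters <- character(0); protect3 <- integer(0); captures <- list()
  for (f in config$families) {
    m <- make_master(f$master_length, config$at_fraction)
    p3 <- attr(m, "protect3_start")
    cap_iv <- NULL
    if (!is.null(f$capture)) {
      donor <- f$capture$donor
      fl <- f$capture$length
      dseq <- cdna[[donor]]
      # captured fragments come from the coding region so that the
      # translated search against the donor protein can recover them
      d0 <- sample(seq(utr + 1L, utr + sum(cds_len) - fl), 1)
      frag <- substr(dseq, d0, d0 + fl - 1L)
      at <- sample(seq(50L, p3 - 50L), 1)   # interior, clear of the termini
      m <- paste0(substr(m, 1, at), frag, substr(m, at + 1L, nchar(m)))
      p3 <- p3 + fl
      cap_iv <- data.frame(donor = donor, start = at, end = at + fl)
    }
    masters[f$name] <- m
    protect3[f$name] <- p3
    captures[[f$name]] <- cap_iv
  }

  ## ---- copies ----
  copies <- list()
  for (f in config$families) {
    m <- masters[[f$name]]
    n_tr <- round(f$n_copies * f$truncated_fraction)
    trunc <- c(rep(TRUE, n_tr), rep(FALSE, f$n_copies - n_tr))
    trunc <- sample(trunc)
    for (ci in seq_len(f$n_copies)) {
      s <- mutate_copy(m, f$target_k, f$ts_tv_ratio, intact = !trunc[ci],
                       protect3_start = protect3[[f$name]])
      tf <- 0
      if (trunc[ci]) {
        tf <- stats::runif(1, 0.2, 0.8)
        cut <- floor(tf * nchar(s))
        s <- substr(s, cut + 1L, nchar(s))
      }
      has_cap <- !is.null(captures[[f$name]]) &&
        stats::runif(1) <= f$capture_fraction &&
        (!trunc[ci] || floor(tf * nchar(m)) < captures[[f$name]]$start)
      copies[[length(copies) + 1L]] <- list(
        family = f$name, seq = s, intact = !trunc[ci], trunc_frac = tf,
        target_k = f$target_k,
        strand = sample(c("+", "-"), 1),
        captured = has_cap)
    }
  }

  ## ---- insertion at A|T dinucleotides, outside exons ----
  at_sites <- gregexpr("AT", bg, fixed = TRUE)[[1]]   # 1-based A position
  pts <- as.integer(at_sites)                          # insert after the A
  in_exon <- rep(FALSE, length(pts))
  for (r in seq_len(nrow(exon_iv)))
    in_exon <- in_exon | (pts > exon_iv[r, 1] & pts < exon_iv[r, 2])
  pts <- pts[!in_exon]
  pts <- pts[sample.int(length(pts))]    # random order, spread genome-wide
  chosen <- integer(0)
  for (p in pts) {
    if (length(chosen) == length(copies)) break
    if (!length(chosen) || min(abs(p - chosen)) > config$min_spacing)
      chosen <- c(chosen, p)
  }
  if (length(chosen) < length(copies))
    stop("insufficient AT insertion sites")
  chosen <- sort(chosen)
  ord <- sample(seq_along(copies))   # random copy-to-site assignment
  ins <- data.frame(point = chosen, copy = ord)

  ## build final genome and offset features
  elem_seq <- vapply(ins$copy, function(i) {
    s <- copies[[i]]$seq
    if (copies[[i]]$strand == "-") revcomp(s) else s
  }, character(1))
  elem_len <- nchar(elem_seq)
  pieces <- character(2L * nrow(ins) + 1L)
  prev <- 0L
  for (i in seq_len(nrow(ins))) {
    pieces[2L * i - 1L] <- substr(bg, prev + 1L, ins$point[i])
    pieces[2L * i] <- elem_seq[i]
    prev <- ins$point[i]
  }
  pieces[length(pieces)] <- substr(bg, prev + 1L, glen)
  genome <- c(chr1 = paste(pieces, collapse = ""))

  shift_of <- function(pos)   # offset for an original-coordinate position
    vapply(pos, function(x) sum(elem_len[ins$point <= x]), numeric(1))
  genes$start <- as.integer(genes$start + shift_of(genes$start))
  genes$end <- as.integer(genes$end + shift_of(genes$end))

  offs <- cumsum(c(0, elem_len))[seq_len(nrow(ins))]
  truth <- data.frame(
    element_id = sprintf("el%03d", seq_len(nrow(ins))),
    family = vapply(ins$copy, function(i) copies[[i]]$family, character(1)),
    seq_id = "chr1",
    start = as.integer(ins$point + offs),
    end = as.integer(ins$point + offs + elem_len),
    strand = vapply(ins$copy, function(i) copies[[i]]$strand, character(1)),
    intact = vapply(ins$copy, function(i) copies[[i]]$intact, logical(1)),
    trunc_frac = vapply(ins$copy, function(i) copies[[i]]$trunc_frac,
                        numeric(1)),
    target_k = vapply(ins$copy, function(i) copies[[i]]$target_k, numeric(1)),
    captured = vapply(ins$copy, function(i) copies[[i]]$captured, logical(1)),
    stringsAsFactors = FALSE)

  list(genome = genome, truth = truth, genes = genes,
       proteins = proteins, cdna = cdna, ests = ests,
       orfs = do.call(rbind, orfs), masters = masters, config = config)
}

#' Write simulation artifacts to a directory
#'
#' Emits genome.fa, truth.tsv, genes.gff3, proteins.fa, cdna.fa, ests.fa and
#' orfs.tsv.
#'
#' @param sim list from [simulate_genome()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gff3(sim$genes, file.path(dir, "genes.gff3"),
             type = NULL, extra_cols = c("type", "ID"))
  write_fasta(sim$proteins, file.path(dir, "proteins.fa"))
  write_fasta(sim$cdna, file.path(dir, "cdna.fa"))
  write_fasta(sim$ests, file.path(dir, "ests.fa"))
  utils::write.table(sim$orfs, file.path(dir, "orfs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
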