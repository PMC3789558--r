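## windowed candidates, greedy clustering, extension, center-star MSA,
## consensus and boundary calling

make_scan_fixture <- function(n_elements = 6, seed = 1, at = 0.62,
                              spacing = 400) {
  set.seed(seed)
  master <- make_master(300, at)
  parts <- character(0)
  for (i in seq_len(n_elements))
    parts <- c(parts, rand_dna(spacing, at), "A",
               mutate_copy(master, 0.03), "T")
  g <- c(chr1 = paste(c(parts, rand_dna(spacing, at)), collapse = ""))
  list(genome = g, master = master)
}

test_that("extract_window takes W bases ending at the CTRR, both strands", {
  fx <- make_scan_fixture()
  hits <- scan_genome_ends(fx$genome)
  hw <- extract_window(hits, fx$genome, W = 30L)
  expect_true(all(nchar(hw$window) == 30))
  oc <- helitronscan:::oriented_cache(fx$genome)
  for (i in seq_len(nrow(hw))) {
    s <- oc(hw$seq_id[i], hw$strand[i])
    expect_equal(hw$window[i],
                 substr(s, hw$sl_ctrr_end[i] - 29, hw$sl_ctrr_end[i]))
    expect_true(substr(hw$window[i], 27, 30) %in%
                  c("CTAA", "CTAG", "CTGA", "CTGG"))
  }
})

test_that("a hit too close to the contig start is dropped and logged", {
  set.seed(2)
  # element CTRR ends 28 bp into the contig (< W = 30)
  g <- c(chr1 = paste0(make_end_construct(lead = 0, tail = 10),
                       rand_dna(200)))
  hits <- scan_genome_ends(g)
  near <- hits[hits$sl_ctrr_end < 30, ]
  hw <- extract_window(hits, g, W = 30L)
  expect_true(all(hw$sl_ctrr_end >= 30))
  dropped <- attr(hw, "dropped")
  expect_equal(nrow(dropped), nrow(near))
})

test_that("greedy clustering honours the strict 80% identity rule", {
  expect_length(greedy_cluster(rep(strrep("ACGTA", 6), 10), min_size = 3), 1)
  # 7/30 differences = 76.7% identity < 80% -> separate clusters
  w1 <- strrep("A", 30)
  w2 <- paste0(strrep("C", 7), strrep("A", 23))
  cl <- greedy_cluster(rep(c(w1, w2), each = 3), t_id = 0.80, min_size = 3)
  expect_length(cl, 2)
  # exactly 24/30 = 80% is NOT > 80% -> still separate
  w3 <- paste0(strrep("C", 6), strrep("A", 24))
  cl3 <- greedy_cluster(rep(c(w1, w3), each = 3), min_size = 3)
  expect_length(cl3, 2)
  # 25/30 > 80% -> merged
  w4 <- paste0(strrep("C", 5), strrep("A", 25))
  cl4 <- greedy_cluster(rep(c(w1, w4), each = 3), min_size = 3)
  expect_length(cl4, 1)
  expect_error(greedy_cluster(c("ACGT", "ACGTA", "ACGTA")), "mixed")
})

test_that("planted-partition windows are recovered exactly", {
  set.seed(12)
  centers <- replicate(3, rand_dna(30, at = 0.5))
  # centers must be mutually distant; regenerate if not
  while (min(utils::combn(3, 2, function(ij)
    30 - sum(strsplit(centers[ij[1]], "")[[1]] ==
             strsplit(centers[ij[2]], "")[[1]]))) < 12)
    centers <- replicate(3, rand_dna(30, at = 0.5))
  windows <- character(0); truth <- integer(0)
  for (ci in 1:3) for (r in 1:67) {
    w <- strsplit(centers[ci], "")[[1]]
    flip <- sample(30, sample(0:3, 1))   # <= 10% divergence
    w[flip] <- sample(c("A", "C", "G", "T"), length(flip), replace = TRUE)
    windows <- c(windows, paste(w, collapse = ""))
    truth <- c(truth, ci)
  }
  keep <- seq_len(200)
  cl <- greedy_cluster(windows[keep], t_id = 0.80, min_size = 3)
  expect_length(cl, 3)
  got <- integer(200)
  for (i in seq_along(cl)) got[cl[[i]]$members] <- i
  expect_equal(length(unique(paste(truth[keep], got))), 3)
})

test_that("extend_members keeps at most 20 members ranked by identity", {
  fx <- make_scan_fixture(n_elements = 25, seed = 5)
  hits <- scan_genome_ends(fx$genome)
  hw <- extract_window(hits, fx$genome)
  cl <- greedy_cluster(hw$window, min_size = 3)
  big <- cl[[which.max(sapply(cl, function(x) length(x$members)))]]
  expect_gte(length(big$members), 21)
  ext <- extend_members(big, hw, fx$genome, cap = 2000, max_members = 20)
  expect_equal(nrow(ext), 20)
  # oracle ranking: identity desc, then window lexicographic
  idx <- big$members
  ident <- vapply(hw$window[idx], helitronscan:::ungapped_identity,
                  numeric(1), b = big$centroid)
  ord <- order(-ident, hw$window[idx], hw$seq_id[idx], hw$start[idx],
               method = "radix")
  expect_equal(ext$member, unname(idx[ord][1:20]))
  # extension capped and anchored at the CTRR end
  expect_true(all(nchar(ext$seq) <= 2000))
  for (i in seq_len(nrow(ext)))
    expect_true(substr(ext$seq[i], ext$anchor[i] - 3, ext$anchor[i]) %in%
                  c("CTAA", "CTAG", "CTGA", "CTGG"))
})

test_that("extension truncates (and flags) at the contig edge", {
  set.seed(6)
  con <- make_end_construct(lead = 30, tail = 10)
  g <- c(chr1 = paste0(con, rand_dna(3000)))
  hits <- scan_genome_ends(g)
  hw <- extract_window(hits, g)
  h1 <- hw[which.min(hw$sl_ctrr_end), ]
  cl <- list(id = "CL1", centroid = h1$window, members = which(
    hw$sl_ctrr_end == h1$sl_ctrr_end & hw$strand == h1$strand))
  ext <- extend_members(cl, hw, g, cap = 5000)
  expect_equal(ext$sl_lo[1], 0L)
  expect_true(ext$clipped5[1])
})

test_that("center-star alignment handles the textbook cases", {
  same <- center_star_align(rep("ACGTACGT", 4))
  expect_equal(same$msa, rep("ACGTACGT", 4))

  al <- center_star_align(c("ACGT", "AGT"))
  expect_equal(nchar(al$msa[1]), 4)
  expect_equal(gsub("-", "", al$msa[2]), "AGT")
  expect_equal(sum(strsplit(al$msa[2], "")[[1]] == "-"), 1)

  single <- center_star_align("ACGT")
  expect_equal(single$msa, "ACGT")
})

test_that("center-star rows degap to their inputs and columns cover them", {
  set.seed(8)
  base <- rand_dna(120)
  seqs <- vapply(1:6, function(i) {
    s <- mutate_copy(base, 0.08, protect3_start = NA, intact = FALSE)
    if (i %% 2 == 0) s <- paste0(s, rand_dna(5)) # length variation
    s
  }, character(1))
  al <- center_star_align(seqs)
  expect_true(all(nchar(al$msa) == nchar(al$msa[1])))
  expect_gte(nchar(al$msa[1]), max(nchar(seqs)))
  expect_identical(gsub("-", "", al$msa), unname(seqs))
  # center minimises summed pairwise edit distance
  dm <- sapply(seqs, function(a) sapply(seqs, function(b) c(utils::adist(a, b))))
  expect_equal(al$center, unname(which.min(rowSums(dm))))
})

test_that("anchored center-star keeps the shared core aligned across flanks", {
  set.seed(18)
  core <- rand_dna(200)
  seqs <- c(paste0(rand_dna(50), core, rand_dna(20)),
            paste0(rand_dna(30), mutate_copy(core, 0.05, protect3_start = NA,
                                             intact = FALSE), rand_dna(40)),
            paste0(rand_dna(45), mutate_copy(core, 0.05, protect3_start = NA,
                                             intact = FALSE), rand_dna(25)))
  anchors <- c(50 + 200, 30 + 200, 45 + 200)
  banded <- center_star_align(seqs, band = 64L, anchors = anchors)
  expect_identical(gsub("-", "", banded$msa), unname(seqs))
  # the anchor (core end) lands in the same MSA column for every row, and
  # the core columns are near-identical across rows
  cols <- vapply(seq_along(seqs), function(i)
    helitronscan:::col_of_residue(banded$msa[i], anchors[i]), integer(1))
  expect_equal(cols, rep(cols[1], 3))
  m <- helitronscan:::msa_matrix(banded$msa)
  core_cols <- (cols[1] - 199):cols[1]
  agree <- colMeans(m[, core_cols] == m[rep(1, 3), core_cols])
  expect_gt(mean(agree), 0.9)
})

test_that("build_consensus applies majority, tie order, and gap dropping", {
  expect_equal(build_consensus(rep("ACGT", 3)), "ACGT")
  expect_equal(build_consensus(c("AAG", "AAG", "GAG")), "AAG")
  # tie A vs G resolved to A; all-gap-majority column dropped
  expect_equal(build_consensus(c("A-C", "G-C", "ATC", "G-C")), "AC")
  # 2/4 gaps = 0.5 not > 0.5 -> kept
  expect_equal(build_consensus(c("A-", "A-", "AT", "AT")), "AT")
})

test_that("consensus of a simulated star family recovers the master", {
  set.seed(9)
  master <- rand_dna(400, at = 0.62)
  copies <- replicate(20, mutate_copy(master, 0.05, protect3_start = NA,
                                      intact = FALSE))
  al <- center_star_align(copies)
  cons <- build_consensus(al$msa)
  expect_gte(helitronscan:::ungapped_identity(cons, master), 0.99)
})

test_that("boundary calling lands on the planted TC with uniform A|T context", {
  set.seed(14)
  master <- make_master(300, 0.62)
  # members: element + distinct random flanks, inserted A|<element>|T
  n <- 12
  seqs <- vapply(seq_len(n), function(i)
    paste0(rand_dna(150), "A", mutate_copy(master, 0.03), "T", rand_dna(60)),
    character(1))
  anchors <- nchar(seqs) - 61L   # last CTRR base
  al <- center_star_align(seqs, gap = -6, band = 64L, anchors = anchors)
  anchor_col <- helitronscan:::col_of_residue(al$msa[al$center],
                                              anchors[al$center])
  bc <- call_boundaries(al$msa, anchor_col)
  expect_null(bc$reject_reason)
  expect_equal(nchar(bc$consensus), 300)
  expect_gte(helitronscan:::ungapped_identity(bc$consensus, master), 0.97)
})

test_that("boundary calling rejects when no TC-compatible start exists", {
  set.seed(15)
  # shared core that starts GG (not TC): no valid boundary
  core <- paste0("GG", rand_dna(200, 0.62))
  con <- make_end_construct(lead = 0, tail = 0)
  n <- 8
  seqs <- vapply(seq_len(n), function(i)
    paste0(rand_dna(120), core, con), character(1))
  anchors <- nchar(seqs) - 1L   # construct ends CTRR+T; CTRR last base
  al <- center_star_align(seqs, gap = -6, band = 64L, anchors = anchors)
  anchor_col <- helitronscan:::col_of_residue(al$msa[al$center],
                                              anchors[al$center])
  bc <- call_boundaries(al$msa, anchor_col)
  expect_false(is.null(bc$reject_reason))
})

test_that("contained duplicate consensuses are removed", {
  set.seed(16)
  master <- rand_dna(600)
  prefix <- substr(master, 1, 350)
  els <- list(list(consensus = master), list(consensus = prefix),
              list(consensus = rand_dna(500)))
  kept <- dedupe_elements(els)
  expect_length(kept, 2)
  expect_true(any(vapply(kept, function(e) e$consensus == master, logical(1))))
  expect_false(any(vapply(kept, function(e) e$consensus == prefix, logical(1))))
})
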