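## translated gene-capture search, autonomy flagging, transcript
## classification, cDNA partition, and the insertion-context test

make_capture_fixture <- function(seed = 1, frag_codons = 100) {
  set.seed(seed)
  cds <- helitronscan:::random_cds(frag_codons + 60)
  protein <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  frag <- substr(cds, 61, 60 + 3 * frag_codons)   # in-frame coding fragment
  element <- paste0("TC", rand_dna(200, 0.62), frag, rand_dna(150, 0.62),
                    "CTAG")
  list(element = element, protein = protein, frag = frag,
       frag_start = 202L, frag_end = 202L + nchar(frag))
}

test_that("an embedded coding exon is recovered with the correct frame", {
  fx <- make_capture_fixture(1)
  frs <- translated_search(fx$element, c(gene1 = fx$protein))
  expect_equal(nrow(frs), 1)
  expect_equal(frs$protein_id, "gene1")
  expect_lte(frs$evalue, 1e-10)
  # recovered interval covers the planted fragment (within codon jitter)
  expect_lte(abs(frs$start - fx$frag_start), 3)
  expect_lte(abs(frs$end - fx$frag_end), 3)
  off <- as.integer(substr(frs$frame, 2, 2)) - 1L
  expect_true(startsWith(frs$frame, "F"))
  expect_equal((fx$frag_start - off) %% 3, 0)
})

test_that("TE-flagged proteins are excluded and thresholds are monotone", {
  fx <- make_capture_fixture(2)
  prots <- c(gene1 = fx$protein, transposase = fx$protein)
  frs <- translated_search(fx$element, prots, te_flags = c(FALSE, TRUE))
  expect_true(all(frs$protein_id == "gene1"))
  none <- translated_search(fx$element, prots["transposase"],
                            te_flags = TRUE)
  expect_equal(nrow(none), 0)
  expect_equal(nrow(translated_search(fx$element, character(0))), 0)
  # raising the E cutoff never decreases the fragment count
  loose <- modifyList(capture_params(), list(e_same = 1e-2))
  tight <- modifyList(capture_params(), list(e_same = 1e-30))
  n_loose <- nrow(translated_search(fx$element, c(g = fx$protein),
                                    params = loose))
  n_tight <- nrow(translated_search(fx$element, c(g = fx$protein),
                                    params = tight))
  n_mid <- nrow(translated_search(fx$element, c(g = fx$protein)))
  expect_gte(n_loose, n_mid)
  expect_gte(n_mid, n_tight)
})

test_that("overlapping hits to one element region merge into one fragment", {
  set.seed(3)
  cds <- helitronscan:::random_cds(120)
  protein <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  element <- paste0("TC", rand_dna(90, 0.62), cds, rand_dna(90, 0.62), "CTGA")
  # the full protein and its two overlapping halves -> one merged fragment
  prots <- c(full = protein,
             half1 = substr(protein, 1, 70),
             half2 = substr(protein, 50, 120))
  frs <- translated_search(element, prots)
  expect_equal(nrow(frs), 1)
  expect_equal(frs$protein_id, "full")   # best E annotates the merge
})

test_that("capture census reports exact planted fractions", {
  set.seed(4)
  fx <- make_capture_fixture(4)
  plain <- replicate(8, paste0("TC", rand_dna(400, 0.62), "CTAA"))
  elements <- setNames(c(fx$element, plain),
                       paste0("el", 1:9))
  cen <- capture_census(elements, c(gene1 = fx$protein))
  expect_equal(cen$fraction_capturing, 1 / 9)
  expect_equal(cen$total_fragments, 1L)
  expect_equal(cen$distinct_genes, 1L)
  expect_equal(sum(cen$per_element$n_fragments >= 0), 9)
})

test_that("autonomy needs Rep AND helicase hits inside a long ORF", {
  set.seed(5)
  rep_cds <- helitronscan:::random_cds(120)
  hel_cds <- substr(helitronscan:::random_cds(181), 4, 543) # no ATG/stop
  orf <- paste0(rep_cds, hel_cds, "TAA")   # single ORF >= 900 nt
  expect_equal(nchar(orf) %% 3, 0)
  element <- paste0("TC", rand_dna(100, 0.62), orf, rand_dna(100, 0.62),
                    "CTGG")
  rep_prot <- as.character(Biostrings::translate(Biostrings::DNAString(rep_cds)))
  hel_prot <- as.character(Biostrings::translate(Biostrings::DNAString(hel_cds)))
  res <- detect_autonomous(c(copy1 = element), c(Rep1 = rep_prot),
                           c(Hel1 = hel_prot))
  expect_true(res$autonomous_candidate)
  expect_false(is.null(res$orf))
  # Rep hit only -> not flagged
  res2 <- detect_autonomous(c(copy1 = element), c(Rep1 = rep_prot),
                            c(Hel1 = paste(rep(c("W", "Y"), 100),
                                           collapse = "")))
  expect_false(res2$autonomous_candidate)
  # frameshift breaks the ORF -> not flagged
  broken <- paste0("TC", rand_dna(100, 0.62), substr(orf, 1, 500), "G",
                   substr(orf, 501, nchar(orf)), rand_dna(100, 0.62), "CTGG")
  res3 <- detect_autonomous(c(copy1 = broken), c(Rep1 = rep_prot),
                            c(Hel1 = hel_prot))
  expect_false(res3$autonomous_candidate)
})

test_that("find_orfs locates long ATG-initiated frames on both strands", {
  set.seed(6)
  cds <- helitronscan:::random_cds(110)   # 330 nt ORF
  s <- paste0(rand_dna(50, 0.62), cds, "TAA", rand_dna(50, 0.62))
  orfs <- find_orfs(s, min_nt = 300)
  expect_gte(nrow(orfs), 1)
  plus <- orfs[orfs$strand == "+", ]
  expect_true(any(plus$start == 50 & plus$end >= 50 + 330))
  orfs_rc <- find_orfs(revcomp(s), min_nt = 300)
  expect_true(any(orfs_rc$strand == "-"))
})

test_that("transcript classes follow the precedence rules", {
  set.seed(7)
  gene <- helitronscan:::random_cds(150)          # 450 nt
  captured <- substr(gene, 1, 300)
  # lightly diverged captured copy: the transcript still matches the element
  # above the 99% bar, but matches the parental gene better
  diverged <- mutate_copy(captured, 0.005, protect3_start = NA, intact = FALSE)
  helitron <- paste0("TC", rand_dna(150, 0.62), diverged,
                     rand_dna(100, 0.62), "CTAG")
  # transcript = exact parental exon: closer to the gene than the element
  t_par <- substr(gene, 1, 300)
  res <- classify_transcript(t_par, helitron, parental_gene = gene)
  expect_equal(res$class, "parental")
  # transcript = exact element interior -> helitron_derived
  t_hel <- substr(helitron, 50, 420)
  res2 <- classify_transcript(t_hel, helitron, parental_gene = gene)
  expect_equal(res2$class, "helitron_derived")
  expect_false(res2$parental_untested)
  # footprint spanning the element boundary -> chimeric
  res3 <- classify_transcript(t_hel, helitron, parental_gene = gene,
                              footprint = c(900, 1600),
                              element_interval = c(1000, 1560))
  expect_equal(res3$class, "chimeric")
  # matched region inside a flagged transposase ORF
  res4 <- classify_transcript(t_hel, helitron,
                              transposase_orf = c(10, 600))
  expect_equal(res4$class, "helitron_transposase")
  expect_true(res4$parental_untested)
  # a transcript that does not reach the identity/E bar is an error
  expect_error(classify_transcript(rand_dna(300), helitron), "identity")
})

test_that("split_cdna partitions coordinates exactly", {
  cdna <- strrep("ACGTT", 20)   # 100 nt
  parts <- split_cdna(cdna, 10, 70)
  expect_equal(nchar(parts$utr5), 10)
  expect_equal(nchar(parts$orf), 60)
  expect_equal(nchar(parts$utr3), 30)
  expect_equal(paste0(parts$utr5, parts$orf, parts$utr3), cdna)
  whole <- split_cdna(cdna, 0, 99 - (99 %% 3))
  expect_equal(nchar(whole$utr5), 0)
  expect_error(split_cdna(cdna, 10, 71), "divisible")
  expect_error(split_cdna(cdna, -1, 59), "range")
  expect_equal(matched_cdna_parts(0, 10, 10, 70, 100), "utr5")
  expect_equal(matched_cdna_parts(5, 80, 10, 70, 100),
               c("utr5", "orf", "utr3"))
  expect_equal(matched_cdna_parts(20, 60, 10, 70, 100), "orf")
})

test_that("insertion-context classes are exclusive and conserved", {
  genes <- rbind(
    data.frame(seq_id = "chr1", start = 10000, end = 16000, strand = "+",
               type = "gene", ID = "g1"),
    data.frame(seq_id = "chr1", start = c(10000, 14000), end = c(11000, 16000),
               strand = "+", type = "exon", ID = c("g1.e1", "g1.e2")))
  copies <- data.frame(
    seq_id = "chr1",
    start = c(10100, 12000, 16500, 40000),
    end = c(10200, 12100, 16600, 40100))
  res <- insertion_context_test(copies, genes,
                                c(chr1 = 1e5), n_perm = 99, seed = 1)
  expect_equal(as.integer(res$observed), c(1L, 1L, 1L, 1L))
  expect_equal(sum(res$observed), nrow(copies))
  expect_equal(res$classes, c("exon", "intron", "within_1kb", "beyond_1kb"))
})

test_that("copies planted inside introns give a significant intron excess", {
  set.seed(8)
  genes <- rbind(
    data.frame(seq_id = "chr1", start = 50000, end = 56000, strand = "+",
               type = "gene", ID = "g1"),
    data.frame(seq_id = "chr1", start = c(50000, 55000),
               end = c(50500, 56000), strand = "+", type = "exon",
               ID = c("e1", "e2")))
  copies <- data.frame(seq_id = "chr1",
                       start = round(seq(50600, 54500, length.out = 40)),
                       end = round(seq(50600, 54500, length.out = 40)) + 50)
  res <- insertion_context_test(copies, genes, c(chr1 = 1e6),
                                n_perm = 999, seed = 2)
  expect_lte(res$p_values[["intron"]], 0.002)
})

test_that("permutation p-values are order-invariant for a fixed seed", {
  set.seed(9)
  genes <- data.frame(seq_id = "chr1", start = 2000, end = 5000,
                      strand = "+", type = "gene", ID = "g")
  copies <- data.frame(seq_id = "chr1", start = c(100, 3000, 8000),
                       end = c(200, 3100, 8100))
  r1 <- insertion_context_test(copies, genes, c(chr1 = 2e4),
                               n_perm = 199, seed = 7)
  r2 <- insertion_context_test(copies[c(3, 1, 2), ], genes, c(chr1 = 2e4),
                               n_perm = 199, seed = 7)
  expect_equal(r1$p_values, r2$p_values)
  expect_error(insertion_context_test(
    data.frame(seq_id = "chr1", start = 0, end = 3e4), genes,
    c(chr1 = 2e4), n_perm = 9, seed = 1), "longer")
})
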