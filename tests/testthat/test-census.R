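## seeded genome search, copy/fragment rules, family naming, reports,
## chromosome distribution and chimera detection

make_family <- function(consensus, name = "fam1") {
  list(name = name, consensus = consensus,
       end5_30 = substr(consensus, 1, 30),
       end3_30 = substr(consensus, nchar(consensus) - 29, nchar(consensus)),
       annotation = "Novel",
       subfamilies = list(list(name = paste0(name, "a"),
                               exemplar = consensus)),
       element_ids = 1L)
}

test_that("an exact planted copy is found as a single covering HSP", {
  set.seed(101)
  cons <- rand_dna(1000, at = 0.6)
  g <- c(chr1 = paste0(rand_dna(40000), cons, rand_dna(59000)))
  hsps <- search_genome(cons, g)
  expect_equal(nrow(hsps), 1)
  expect_equal(hsps$sstart, 40000)
  expect_equal(hsps$send, 41000)
  expect_equal(hsps$identity, 1)
  expect_lt(hsps$evalue, 1e-6)
})

test_that("no retained HSPs arise from pure random background", {
  set.seed(102)
  cons <- rand_dna(500, at = 0.6)
  fp <- 0
  for (i in 1:20) {
    g <- c(chr1 = rand_dna(50000, at = 0.6))
    fp <- fp + nrow(search_genome(cons, g))
  }
  expect_equal(fp, 0)
})

test_that("a copy mutated to ~75% identity is rejected", {
  set.seed(103)
  cons <- rand_dna(800, at = 0.6)
  x <- strsplit(cons, "")[[1]]
  flip <- sample(800, 200)   # 75% identity
  x[flip] <- vapply(x[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  g <- c(chr1 = paste0(rand_dna(5000), paste(x, collapse = ""),
                       rand_dna(5000)))
  hsps <- search_genome(cons, g)
  expect_true(nrow(hsps) == 0 || all(hsps$identity > 0.80 & hsps$length <= 800))
})

test_that("minus-strand copies are reported in consensus coordinates", {
  set.seed(104)
  cons <- rand_dna(600, at = 0.6)
  g <- c(chr1 = paste0(rand_dna(3000), revcomp(cons), rand_dna(3000)))
  hsps <- search_genome(cons, g)
  expect_equal(nrow(hsps), 1)
  expect_equal(hsps$strand, "-")
  expect_equal(hsps$sstart, 3000)
  expect_equal(hsps$send, 3600)
  expect_equal(hsps$qstart, 0)
  expect_equal(hsps$qend, 600)
})

test_that("seeded search agrees with full Smith-Waterman on small instances", {
  set.seed(105)
  for (i in 1:20) {
    cons <- rand_dna(sample(200:400, 1), at = 0.6)
    n_copies <- sample(0:2, 1)
    parts <- rand_dna(2000)
    truth <- 0
    for (cc in seq_len(n_copies)) {
      parts <- c(parts, mutate_copy(cons, runif(1, 0, 0.1),
                                    protect3_start = NA, intact = FALSE),
                 rand_dna(1500))
      truth <- truth + 1
    }
    g <- c(chr1 = paste(parts, collapse = ""))
    hsps <- search_genome(cons, g)
    # Smith-Waterman oracle via Biostrings on the full subject, iteratively
    # masking found hits
    subj <- g[[1]]
    sw_hits <- 0
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    repeat {
      al <- Biostrings::pairwiseAlignment(cons, subj, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 0, gapExtension = 2)
      pid <- Biostrings::nmatch(al) / Biostrings::nchar(al)
      if (Biostrings::nchar(al) <= 80 || pid <= 0.80) break
      sw_hits <- sw_hits + 1
      s0 <- Biostrings::start(Biostrings::subject(al))
      w <- Biostrings::width(Biostrings::subject(al))
      substr(subj, s0, s0 + w - 1) <- strrep("N", w)
    }
    expect_equal(nrow(hsps), sw_hits)
    expect_equal(nrow(hsps), truth)
  }
})

test_that("call_copies applies the intact-copy and fragment rules", {
  set.seed(106)
  cons <- make_master(600, 0.62)
  p3 <- attr(cons, "protect3_start")
  # full copy (A|element|T context), one 5'-truncated copy, two tandem copies
  full1 <- mutate_copy(cons, 0.05)
  trunc <- substr(mutate_copy(cons, 0.05), 241, 600)  # 40% 5'-truncated
  g <- c(chr1 = paste0(rand_dna(2000), "A", full1, "T",
                       rand_dna(2000), "A", trunc, "T",
                       rand_dna(2000), "A", mutate_copy(cons, 0.05), "T",
                       rand_dna(200), "A", mutate_copy(cons, 0.05), "T",
                       rand_dna(2000)))
  hsps <- search_genome(as.character(cons), g)
  calls <- call_copies(hsps, as.character(cons), g, family = "fam1")
  copies <- calls[calls$kind == "copy", ]
  frags <- calls[calls$kind == "fragment", ]
  expect_equal(nrow(copies), 3)          # tandem copies stay separate
  expect_true(all(copies$intact))
  expect_gte(nrow(frags), 1)             # truncated copy -> fragment(s)
  expect_false(any(frags$intact))
  # every intact call literally starts TC and ends CTRR
  for (i in which(calls$intact)) {
    s <- helitronscan:::oriented_seq(g[[1]], calls$strand[i])
    n <- nchar(g[[1]])
    sl <- if (calls$strand[i] == "+") c(calls$start[i], calls$end[i])
          else c(n - calls$end[i], n - calls$start[i])
    expect_equal(substr(s, sl[1] + 1, sl[1] + 2), "TC")
    expect_true(substr(s, sl[2] - 3, sl[2]) %in%
                  c("CTAA", "CTAG", "CTGA", "CTGG"))
  }
})

test_that("annotation against a library discards non-Helitron best hits", {
  set.seed(107)
  helitron <- rand_dna(500)
  line_te <- rand_dna(500)
  lib <- c("HelX class=Helitron" = helitron, "LINE1 class=LINE" = line_te)
  expect_equal(annotate_against_library(helitron, lib),
               list(annotation = "HelX", is_non_helitron = FALSE))
  res <- annotate_against_library(line_te, lib)
  expect_true(res$is_non_helitron)
  expect_equal(res$annotation, "LINE1")
  novel <- annotate_against_library(rand_dna(400), lib)
  expect_equal(novel$annotation, "Novel")
  expect_equal(annotate_against_library(rand_dna(400), NULL)$annotation,
               "Novel")
})

test_that("family assignment uses both 30-bp termini with strict > 0.80", {
  set.seed(108)
  cons <- make_master(400, 0.62)
  fam <- make_family(as.character(cons))
  # identical element joins family and subfamily
  expect_equal(assign_family(as.character(cons), list(fam)),
               list(family = 1L, subfamily = 1L))
  # same termini, diverged interior -> same family, new subfamily
  x <- strsplit(as.character(cons), "")[[1]]
  interior <- 40:340
  flip <- sample(interior, 150)
  x[flip] <- vapply(x[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  div <- paste(x, collapse = "")
  hit <- assign_family(div, list(fam))
  expect_equal(hit$family, 1L)
  expect_true(is.na(hit$subfamily))
  # exactly 24/30 on both termini (80%, not >80%) -> new family
  y <- strsplit(as.character(cons), "")[[1]]
  for (pos in list(3:8, seq(nchar(cons) - 25, nchar(cons) - 20))) {
    y[pos] <- vapply(y[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  hit2 <- assign_family(paste(y, collapse = ""), list(fam))
  expect_true(is.na(hit2$family))
  expect_error(assign_family("TCAA", list(fam)), "shorter")
})

test_that("family_report aggregates counts and delegates AT content", {
  set.seed(109)
  cons <- make_master(500, 0.62)
  fam <- make_family(as.character(cons))
  calls <- data.frame(
    seq_id = "chr1", start = c(0, 1000, 3000), end = c(500, 1480, 3200),
    strand = "+", family = "fam1", kind = c("copy", "copy", "fragment"),
    intact = c(TRUE, FALSE, FALSE), identity = 0.95, evalue = 1e-20,
    has_TC = c(TRUE, FALSE, FALSE), has_CTRR = c(TRUE, TRUE, TRUE))
  g <- c(chr1 = rand_dna(10000))
  rep <- family_report(fam, calls, g)
  expect_equal(rep$copy_count, 2)
  expect_equal(rep$fragment_count, 1)
  expect_equal(rep$intact_count, 1)
  expect_equal(c(rep$length_min, rep$length_max), c(480, 500))
  expect_equal(rep$at_percent, 100 * at_content(as.character(cons)))
  expect_equal(rep$genome_bp, 500 + 480 + 200)
  expect_equal(rep$genome_fraction, 1180 / 10000)
})

test_that("the -dG proxy is more stable for GC-rich stems", {
  gc_stem <- helitronscan:::stem_dg("GCGCGCGC", revcomp("GCGCGCGC"))
  at_stem <- helitronscan:::stem_dg("ATATATAT", revcomp("ATATATAT"))
  expect_gt(gc_stem, at_stem)
  expect_gt(at_stem, 0)
  # a consensus with a terminal hairpin gets a positive score
  set.seed(110)
  cons <- make_master(300, 0.62)
  expect_gt(hairpin_dg_proxy(as.character(cons)), 0)
})

test_that("chromosome distribution chi-square behaves at the extremes", {
  lens <- setNames(rep(1e6, 10), paste0("chr", 1:10))
  set.seed(111)
  # uniform placement: p typically large; all calls on chr1: p tiny
  unif <- data.frame(seq_id = sample(names(lens), 500, replace = TRUE),
                     start = 0, end = 100)
  unif$start <- floor(runif(500, 0, 1e6 - 100)); unif$end <- unif$start + 100
  cd <- chromosome_distribution(unif, lens)
  expect_gt(cd$p_value, 1e-4)
  expect_equal(sum(cd$per_chrom$count), 500)
  expect_equal(sum(cd$per_bin$Freq), 500)

  onechr <- data.frame(seq_id = "chr1", start = seq(0, 499000, 1000),
                       end = seq(100, 499100, 1000))
  cd2 <- chromosome_distribution(onechr, lens)
  expect_lt(cd2$p_value, 1e-6)
  expect_error(chromosome_distribution(
    data.frame(seq_id = "chrX", start = 0, end = 10), lens), "absent")
})

test_that("constructed chimeras are detected with correct orientations", {
  set.seed(112)
  a <- make_family(paste0("TC", rand_dna(700), "CTAG"), "famA")
  b <- make_family(paste0("TC", rand_dna(700), "CTGG"), "famB")
  childseq <- paste0(substr(a$consensus, 1, 350),
                     substr(b$consensus, 352, 704))
  child <- make_family(childseq, "famC")
  res <- detect_chimeric_families(list(a, b, child))
  got <- res[res$child == "famC", ]
  expect_equal(nrow(got), 1)
  expect_setequal(c(got$parent5, got$parent3), c("famA", "famB"))
  expect_equal(got$strand5, "+"); expect_equal(got$strand3, "+")
  expect_lt(abs(got$break5 - 350), 20)
  expect_lt(abs(got$break3 - 350), 20)

  # forward A + reverse B
  child2 <- make_family(paste0(substr(a$consensus, 1, 350),
                               revcomp(substr(b$consensus, 1, 353))), "famD")
  res2 <- detect_chimeric_families(list(a, b, child2))
  got2 <- res2[res2$child == "famD", ]
  expect_equal(nrow(got2), 1)
  strands <- setNames(c(got2$strand5, got2$strand3),
                      c(got2$parent5, got2$parent3))
  expect_equal(unname(strands["famA"]), "+")
  expect_equal(unname(strands["famB"]), "-")

  # unrelated families -> empty
  c3 <- make_family(paste0("TC", rand_dna(700), "CTAA"), "famE")
  res3 <- detect_chimeric_families(list(a, b, c3))
  expect_equal(nrow(res3), 0)
  expect_equal(nrow(detect_chimeric_families(list(a, b))), 0)
})
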