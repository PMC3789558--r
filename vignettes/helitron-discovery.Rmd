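---
title: "Structure-based Helitron discovery: models, parameters and design"
author: "helitronscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based Helitron discovery: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Helitrons are class-2 transposable elements thought to move by rolling-circle
replication. Unlike other DNA transposons they carry no terminal inverted
repeats and create no target-site duplication; their diagnostic features are
purely sequence-structural: a `TC` dinucleotide at the 5' terminus, a `CTRR`
motif (`R` = purine) at the 3' terminus, a short palindromic hairpin a few
nucleotides upstream of the `CTRR`, and a strong preference for inserting
between the `A` and `T` of an `AT` dinucleotide — so that an intact insertion
reads `A | TC ... CTRR | T` on the host strand. Because the termini, not the
internal sequence, define the element, homology search against known
repeats misses novel families; a structure-based scan does not.

`helitronscan` implements that scan and everything downstream of it:

1. **End-structure scan** (`scan_genome_ends`): every `CTRRT` occurrence on
   either strand is tested for an upstream hairpin at a compatible
   separation. One structure is reported per motif site (longest stem, then
   fewest mismatches, then leftmost).
2. **End-window clustering** (`greedy_cluster`): the 30 bp ending at each
   candidate's `CTRR` are clustered greedily at strictly >80% ungapped
   identity. The 30-bp window matches the family-definition rule used for
   naming, so cluster membership and family membership are measured on the
   same footing.
3. **Extension, alignment, boundary calling** (`extend_members`,
   `center_star_align`, `call_boundaries`): up to 20 members per cluster are
   extended symmetrically (15 kb total by default), multiply aligned, and
   the 5' element boundary is called automatically from the member-agreement
   profile plus the `TC`/host-`A` signature (see below). The 3' boundary is
   the last `CTRR` base, known from the end structure.
4. **Census** (`search_genome`, `call_copies`): each family consensus is
   searched genome-wide with an 11-mer seeded, DP-refined local alignment.
   Loci reaching both consensus ends (E < 1e-6, >80 bp, >80% identity)
   are copies — intact when the genomic sequence literally begins `TC` and
   ends on a `CTRR`; loci matching only internal regions are fragments.
5. **Evolutionary analysis** (`kimura2p`, `age_from_k`,
   `mismatch_distribution`, `classify_modality`, `nj_tree`): insertion ages
   from copy-vs-consensus Kimura 2-parameter distances via `T = k/2r`
   (`r` = 1.56e-8 substitutions/site/year), expansion-burst structure from
   copy-vs-copy pairwise-difference histograms, and neighbor-joining trees.
6. **Functional analysis** (`translated_search`, `capture_census`,
   `detect_autonomous`, `classify_transcript`, `insertion_context_test`):
   gene-fragment capture by six-frame BLOSUM62 local alignment against a
   protein set, autonomous-candidate flagging (Rep + helicase homology
   inside a >=900-nt ORF), EST/cDNA transcript classification, and an
   insertion-context permutation test.

The distinction between the two distance uses matters: ages are computed
copy-vs-family-consensus (the consensus approximates the master element, so
`k` measures time since the copy left it), while mismatch distributions are
copy-vs-copy (two copies of one burst are separated by twice the burst age,
and a mixture of bursts produces multiple modes).

## Key parameters

| key | default | meaning |
|---|---|---|
| `end$stem_min/stem_max` | 6 / 20 bp | hairpin stem length bounds |
| `end$max_mismatch(_frac)` | 3 / 20% | stem mismatch budget |
| `end$loop_min/loop_max` | 2 / 10 nt | hairpin loop bounds |
| `end$sep_min/sep_max` | 2 / 20 nt | hairpin-to-CTRR separation |
| `end$require_host_t` | TRUE | require the host `T` after `CTRR` |
| `cluster$window` | 30 bp | end window = family-rule window |
| `cluster$t_id` | 0.80 | window identity threshold (strict >) |
| `cluster$min_cluster_size` | 3 | smallest cluster kept |
| `cluster$ext_cap` | 15000 bp | member extension cap |
| `cluster$max_members` | 20 | members aligned per cluster |
| `census$evalue_max/min_len/min_id` | 1e-6 / 80 / 0.80 | copy thresholds |
| `census$chain_gap` | 15 kb | HSP chaining gap cap |
| `capture$e_same/e_other` | 1e-10 / 1e-5 | capture E cutoffs (same/other species) |
| `capture$est_id/est_evalue` | 0.99 / 1e-10 | transcript match bar |
| `capture$orf_min_nt` | 900 | autonomy ORF floor |
| `evolution$r` | 1.56e-8 | neutral rate, subs/site/year |

Hairpin geometry is not part of the structural definition itself; the
defaults above follow the structure-based search tradition and every one is
a configuration key. The E-value thresholds are read in the conventional
shorthand (`e-10` meaning 1e-10).

## Boundary automation

Manual boundary curation is replaced by a rule on the member MSA. Let the
per-column *agreement* be the fraction of rows equal to the column's modal
base (gaps count as disagreement). The 5' boundary is the outermost column
where

* mean agreement over a 10-column window is at or above the threshold
  inside and below it immediately outside,
* agreement stays at threshold level in every sliding 50-column window from
  there to the 3' anchor (*contiguity* — this rejects drop-offs caused by a
  second shared repeat further out in the flanks), and
* the consensus begins `TC` with the preceding host column majority `A`
  (searched within 50 columns of the drop-off; among qualifying `TC` starts
  the one maximizing the inside-minus-outside agreement contrast wins).

Two numerical choices deserve explanation:

* **Null-calibrated threshold.** The nominal 60% agreement threshold is
  meaningful only when the null (unrelated-sequence) agreement is well below
  it. For an alignment of *n* rows, the expected modal-base fraction of a
  random column is large when *n* is small (about 0.60 for *n* = 4). The
  threshold is therefore raised to
  `max(0.60, mu_null + 4 * sd_null / sqrt(10))`, with the null moments
  computed exactly from the multinomial distribution of the observed base
  composition. For 10-20 rows this reduces to the nominal 60%.
* **Anchored member alignment.** All cluster members share a structural
  anchor (the last `CTRR` base). Pairwise member alignments are split at
  that anchor and banded (+/-64) around it, with unpaired excess flank
  becoming edge gaps, and the member-MSA gap penalty is -6. An
  unconstrained global alignment of multi-kilobase, mostly non-homologous
  extensions will shear the homologous element apart to harvest chance
  matches in the flanks — with match +1/mismatch -1/gap -2 the optimal
  alignment of two random DNA flanks reaches ~55% column identity, which
  destroys the agreement contrast the boundary rule depends on. The
  anchored, banded, high-gap-cost alignment keeps the element pinned while
  leaving flank junk unaligned. (`center_star_align` itself retains the
  conventional -2 default for general use; the pipeline overrides it.)

After boundary calling, a consensus covered over >=90% of its length at
>=80% identity by a longer consensus is dropped. Chance `CTRR`+hairpin
structures *inside* an element are shared by every copy of its family and
would otherwise emit truncated duplicates of the family consensus; the
containment filter automates the curation step that collapses them.

## The E-value surrogate

The census scores local alignments with match +1/mismatch -1/gap -2 and
converts scores via the Karlin-Altschul form `E = K m n exp(-lambda S)` with
fixed constants `lambda = 1.33`, `K = 0.621`. At a fixed cutoff any strictly
monotone transform of the score behaves identically, so these constants are
reproducibility anchors, not estimates; the retention rule additionally
requires >80 bp aligned and >80% identity, which dominate in practice.

## The synthetic genome

`simulate_genome` emulates the study conditions end to end: a 2-Mb,
62%-AT background; eight multi-exon genes with stop-free coding sequence
(providing proteins, cDNAs with known ORF coordinates, and ESTs); and three
Helitron families of 50 copies each diverged from their masters at
k = 0.02, 0.05 and 0.08 under the exact Kimura 2-parameter site process
(transition:transversion 2:1), with 20% of copies 5'-truncated by a uniform
20-80% and one family carrying a 300-bp captured coding fragment. Master
lengths are 800/1200/1600 bp, within the short-to-mid range of reported
Helitron families and small enough that the 15-kb extension window always
spans the whole element. Copies insert only at `A|T` dinucleotides outside
exons, on random strands, with at least 300 bp between insertion points.

The generator deliberately idealises several things: substitutions only (no
indels by default), a star phylogeny per family (one burst; two-burst
histories are simulated by mixing two divergence cohorts), no nested
insertions, and exact terminal conservation (the 3' structural block is
exempt from substitution for all copies — a copy whose `CTRR` mutated is
not a detectable candidate by definition — and the 5' `TC` for intact
copies). Passing the planted-recovery tests therefore demonstrates that the
pipeline logic is correct under its own model assumptions; it does not
demonstrate robustness to indel-rich, nested, or degenerate-ended real
repeats, which is why every threshold is configurable.

## Problem sizes and calibration designs

The validation suite uses: the 2-Mb default simulation for end-to-end
recovery; 100 random 500-nt windows for the hairpin-enumeration oracle; 20
small (<= 3 kb) instances against full Smith-Waterman; 1000 random pairs
for the K2P counting oracle; additive matrices up to n = 8 for
neighbor-joining; 200 copies at k = 0.06 for estimator consistency; 20
replicates each of single-burst (20 copies, k = 0.04) and two-burst
(16 copies at k = 0.01 + 4 at k = 0.08) histories for modality
calibration — the old burst is kept small so its internal pairs stay below
the 10% peak threshold, as expected of a burst mostly eroded by deletion;
and 100/50 null replicates for the chi-square and permutation calibrations.

Other numerical decisions: `classify_modality` floors the kernel bandwidth
at 1 (the histogram bin width) so integer discreteness cannot masquerade as
multimodality; `mutate_copy` uses the exact K2P transition probabilities at
the target distance, so the estimator-consistency checks test the estimator,
not a simulation shortcut; seeded search skips diagonal groups with fewer
than 2 seeds (a qualifying HSP seeds ~6+ times); and copy termini are
projected from consensus coordinates and snapped to the nearest `TC`/`CTRR`
within 3 bp, which is what makes intact calls exact rather than
alignment-jitter-limited.

## Known limitations

* Families whose copies are all 5'-degenerate (no `TC`) are invisible, as
  for any strictly structure-based scan; the same applies to atypical
  termini.
* The boundary caller assumes members share no flanking homology beyond the
  element; segmental duplications that carry flanks along would extend the
  called element up to the duplication boundary.
* The -dG proxy scores only the terminal hairpin stem
  (SantaLucia nearest-neighbor dG37); it is not comparable to whole-element
  secondary-structure folding energies.
* `center_star_align` is a star alignment: adequate for star-like repeat
  families, inferior to progressive methods for deep hierarchical
  divergence.
* Transcript classification requires resolvable genomic footprints to
  separate chimeric from element-internal transcripts; short ESTs without
  footprints stay in the broader `helitron_derived` class.
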