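---
title: "Methods: sequence-based chrY genotyping and mutation-rate estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based chrY genotyping and mutation-rate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yseqpanel)
```

This vignette documents the models and numerical conventions behind
`yseqpanel`: how Y-STR alleles are called from amplicon reads, how Y-SNP
haplogroups are assigned, how microsatellite mutation rates are estimated
from genealogical pairs, what the synthetic-data generator emulates, and
which design choices were genuinely open.

## The genotyping problem

A chrY MPS amplicon panel types two marker classes in one run. Y-STRs are
short tandem repeats with per-meiosis mutation rates around 10⁻³–10⁻² per
locus; because the Y is haploid, each locus copy carries a single allele,
and multi-copy loci (2 or 4 near-identical copies in chrY palindromes)
yield a small multiset of alleles. Y-SNPs are essentially unique-event
biallelic markers whose derived state places a sample on a branch of the
male phylogeny. STR reads must be resolved at sequence level (repeat
structure, flanking variants), while SNP calls reduce to a thresholded
pileup.

## Y-STR calling

**Read assignment.** Each locus is identified by exact 15-bp anchors on
both sides of the amplicon. A read is assigned when its 5' anchor (or, for
the opposite orientation, the reverse complement) matches within
`min_anchor_match` mismatches and the 3' anchor is found near the read
end. The default tolerance of 1 mismatch per anchor accepts reads carrying
one sequencing error in the anchor while keeping the chance of cross-locus
capture negligible (two random 15-mers within one mismatch are vanishingly
unlikely); raising it is only advisable for panels with homologous targets.

**Decomposition.** An anchor-trimmed sequence is parsed as
`prefix + blocks + suffix` against the configured structure. Fixed motifs
and interruption stretches must match exactly; variable motifs are matched
maximally *with backtracking*, i.e. the unique leftmost-longest parse.
Backtracking matters whenever one motif is a prefix of its successor
(`GT[n]GTCT[n]`: the maximal GT run would otherwise swallow the GT of
GTCT). Candidate prefix lengths are tried reference-first within
`flank_tol` (±3 bp by default), and a parse succeeds only if the residual
suffix length is also within tolerance; flank substitutions relative to the
reference are reported as variants (isoallele annotations), not failures.
The allele call is the summed count of the variable blocks, so compound
loci report per-motif counts and two alleles with equal total length but
different splits (7+15 vs 8+14) stay distinct.

The ±3 bp tolerance is a compromise: it absorbs small indel variation in
flanks, while sequences whose flanks deviate further — typically homology
capture from elsewhere in the genome — are rejected with a reason
(`flank_too_short`, `flank_too_long`, `block_missing`). A consequence of
tolerance-based parsing is that a read truncated by a few bases can be
re-interpreted as a shorter allele with a shortened suffix; this does not
arise in practice because assignment requires both anchors.

**Stutter filtering.** PCR slippage produces ladder artifacts mostly one
(sometimes two) repeats below a true allele, strongest for dinucleotide
motifs. A candidate is flagged as stutter when a higher-count candidate
exists with identical flanks and all but one variable block equal, the
differing block one or two repeats higher, and the candidate's depth below
a unit-length-specific fraction of the parent's: 0.5 for dinucleotides,
0.15 for tri/tetra, 0.10 for penta/hexa, halved at n−2. The top-count
sequence is never flagged. These ratios are deliberately permissive upper
bounds on observed stutter proportions; the assay itself publishes no
ratios, so they are exposed as parameters.

**Candidate walk and `no_data`.** Candidates are examined in decreasing
read-count order (ties broken lexicographically for determinism). Only the
top `4 × copy_count` are considered; if none passes decomposition, or the
locus total is below `min_reads = 10`, the locus is `no_data` — a value,
not an error. For indistinguishable multi-copy loci the `copy_count`
strongest genuine survivors are reported sorted from short to long allele;
when fewer distinct sequences survive than copies (equal-allele copies
collapse into one sequence at roughly summed depth), copies are allocated
to survivors by read-depth share. This allocation is a heuristic: with
heavily imbalanced copy depths it can mis-apportion copies, which is one
reason multi-copy loci are compared under parsimony downstream.

**Paired-end consensus.** Both ends are called independently. Equal calls
merge; differing calls are resolved in favour of the end whose repeat
region begins fewer bases from its anchor, because base-call error grows
with cycle number, so the end that reaches the repeat earlier has read it
more accurately; equal offsets fall back to higher supporting depth, and a
`no_data` end defers to the other.

## Y-SNP calling and haplogroup assignment

Bases with Phred quality below 20 are excluded from the pileup. A marker
is called only with ≥ 10 quality-passing reads and a majority fraction
≥ 0.90 (applied to quality-passing reads only) equal to its ancestral or
derived allele; anything else is `no_call`. These thresholds are monotone:
raising either can only turn calls into `no_call`.

Haplogroup labels encode their own ancestry (`R1a1a` descends from
`R1a1`), so the tree is built by longest-present-prefix parentage with a
conventional virtual root `Y` above the main letters; an explicit parent
table can override the prefix rule for panels using non-nested
nomenclature. The assignment is the deepest node with at least one derived
call whose root path contains no contradicted node, where a node is
contradicted when its ancestral calls outnumber its derived calls. Ties
prefer more derived support along the path, then the lexicographically
first label. Markers with unknown phylogenetic position and private
markers are reported but never drive the assignment. The
majority-per-node conflict rule is our choice — the thresholds say nothing
about conflicting calls — and is deliberately symmetric and configurable
upstream of any error model.

## Mutation rates from genealogical pairs

For a pair separated by *m* meioses, each locus called in both samples
contributes repeat-count differences; loci `no_data` in either sample are
excluded from that locus's meiosis denominator, which is why per-locus
denominators fluctuate across a panel. Single-copy and compound loci
compare per-motif counts, so two parallel one-step mutations in different
motifs are both counted even when the summed allele is unchanged — the
case hidden from fragment-length analysis.

Indistinguishable multi-copy loci are compared under parsimony.
`steps_min` is the minimum total |step| over all copy-to-copy assignments
(the least number of changes explaining the data); `steps_max` bounds the
other direction, after copies with identical repeat vectors are paired
off. The cancellation step is deliberate: without it, two unchanged copies
could be "explained" by a crossed assignment with two opposing mutations,
so identical call vectors would not compare to zero. The midpoint
`(steps_min + steps_max)/2` is the difference estimate carried into rates,
and all three are reported.

The per-locus rate is the frequentist direct count `differences / m` with
an exact Clopper–Pearson 95% interval (beta quantiles on the half-up
rounded difference count; the point estimate keeps the unrounded
midpoint). Rates are classed on the unrounded value: slow < 10⁻³ ≤
moderate < 5·10⁻³ ≤ fast < 10⁻² ≤ rapid, with zero-difference loci
`non_mutating`. Panel-wide rates divide grand totals and are reported with
both the exact interval and a normal approximation (the approximation is
what aggregate summaries of this size conventionally print). Comparison to
a literature rate uses the one-sample chi-square goodness-of-fit on
(events, non-events), which equals the two-sided score test; it is a large
sample approximation and should be read qualitatively when expected event
counts are small.

Individualization uses independence across loci:
`P(≥1 difference) = 1 − Π(1 − r_l)^g`, reducing to `1 − (1−r)^{Lg}` for a
uniform rate. The kinship-screening threshold `max_allowed_differences`
inverts the Poisson-binomial distribution of the total difference count by
exact convolution of per-locus binomials — no Monte-Carlo error, cost
`O((Lg)²)` at worst, trivial at panel scale.

Discrimination capacity is the plain `1 − Σ p_i²` over allele frequencies
(multi-copy loci contribute their sorted allele vector as one categorical
allele, as fragment-analysis kits treat them); an unbiased `n/(n−1)`
variant is available because the estimator behind published tables is
ambiguous. Rate–size correlation defaults to Spearman rank correlation —
rates are heavy-tailed across loci — with Pearson as an option.

## The synthetic-data generator

The generator is the package's study population. Defaults encode the
assay conditions the pipeline targets: paired-end 2×300 bp reads, mean
per-marker depth 150 with a negative-binomial spread (`size = 3`,
matching the wide per-locus depth ranges seen on MiSeq amplicon panels;
`size = Inf` gives deterministic depth for noise-free tests), per-base
substitution error 0.002, stutter ratios 0.30/0.12/0.10/0.05 by motif
unit length with an n−2 decay of 0.3 and an optional gain component,
constant Phred 35 qualities (the pipeline's only quality use is the Q20
SNP filter), and an optional depth decay per 100 bp of amplicon length to
emulate degraded input. Pedigree transmission mutates each locus with
probability `rate × copy_count` per meiosis, one-step with probability
0.83 and a geometric multi-step tail, reflecting at the locus's
repeat-count range boundaries (biological allele ranges are bounded).
SNP amplicons are simulated at the same 150-read mean depth; calling
saturates far below that, so nothing depends on matching the much higher
SNP depths a real run produces.

What it does *not* emulate: PCR chimeras, index hopping, contamination
and mixtures, alignment artifacts, quality degradation along the read,
and real flanking sequence (SNP amplicon contexts are synthetic,
generated deterministically from the marker position). Passing tests
therefore demonstrate the correctness of the calling logic under a
realistic noise model, not robustness to every artifact of a real
sequencer.

## Numerical conventions and problem sizes

* Ties between equal-count candidate sequences are broken
  lexicographically; copies are reported sorted short-to-long; percentage
  ratios round half-up.
* Fractional difference midpoints are rounded half-up only for interval
  computation; point rates keep the unrounded value.
* The end-to-end recovery checks run 20 simulated samples on the 30-locus
  demonstration panel with error-free reads at deterministic depth;
  parsimony is verified against factorial brute force on 1,000 random
  copy vectors; decomposition round-trips on 10,000 random in-structure
  sequences.
* The interval-coverage study plants a rate of 5·10⁻³ over 4,822
  transfers per locus (about 24 expected events) across 1,000 simulated
  loci. Exact binomial intervals are conservative; at a few hundred
  transfers per locus their true coverage sits near 97–98%, so a coverage
  study at vanishing expected counts would measure the discreteness of
  the binomial rather than the estimator. The chosen size matches the
  largest per-locus transfer count a four-copy marker accumulates in a
  genealogical study of this scale.

## Known limitations

* Copy allocation for multi-copy loci with fewer survivors than copies is
  depth-proportional and can be wrong under extreme depth imbalance.
* The stutter filter is rule-based; it does not learn locus-specific
  stutter ratios from data.
* `steps_max` is a documented convention, not a reconstruction of any
  published over-estimation rule; published bracketed ranges of this form
  cannot be reproduced exactly from printed tables.
* Haplogroup assignment assumes the prefix-encoded nomenclature unless an
  explicit parent table is supplied, and treats each marker's
  ancestral/derived states as error-free labels of the positions file.
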