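---
title: "Allele dosage, expression and divergence at polyploid loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele dosage, expression and divergence at polyploid loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polydosage)
```

## The problem

Highly polyploid genomes — sugarcane being the extreme case this package was
built around — carry many near-identical copies (haplotypes) of each locus,
distributed over homeologous chromosome groups. Sequencing recovers some of
those haplotypes (here, from BAC clones), cytology fixes how many copies must
exist, and transcriptome reads carry the allelic signal of *all* copies,
including the ones that were never sequenced. Three questions follow:

1. **Cataloguing** — which variants distinguish the recovered haplotypes,
   how dense are they, and which sites are diagnostic between homeologous
   region copies?
2. **Expression** — which gene haplotypes are actually transcribed, given
   that reads must be assigned at 100% identity to count as haplotype
   evidence?
3. **Dosage** — when ploidy says `P` copies but only `H < P` haplotypes were
   recovered, does the transcriptome allele ratio at each SNP match the
   genomic ratio, and which allele does the missing haplotype carry?

Around this core, the package dates duplications and LTR retrotransposon
insertions with a strict molecular clock and places duplications on
neighbor-joining trees.

## The dosage model

At a SNP carried by `x` of the `H` observed haplotypes, the genomic variant
dosage `v` is either `x` (the missing haplotype carries the common allele)
or `x + (P - H)` (it carries the variant). If the variant was never seen
genomically, only the missing haplotype can carry it, and both hypotheses
coincide at `v = P - H`. Under equal per-copy expression, the variant read
count `k` among `n` reads covering the site is Binomial(`n`, `v/P`), and
each hypothesis is tested with the exact two-sided binomial test; the
two-sided p-value sums the probabilities of all outcomes no more likely than
the observed one (relative tolerance `1e-7`, the convention of classical
exact tests — no normal approximation). A hypothesis is *accepted* when
`p >= alpha` (default 0.05): the transcriptome ratio is compatible with that
genomic dosage.

Two conventions matter for reproducing published tables:

* **Exact fractions.** Null proportions are `v/P` as fractions (`5/8`, not
  the display rounding `0.63`); printed proportions are recovered by
  rounding half-up to two decimals.
* **Per-site overrides.** `run_dosage_table()` normally derives both
  hypotheses from `observed_variant_count` and the ploidy context, but a
  table can carry explicit `v_common`/`g_common`/`v_variant`/`g_variant`
  columns, in which case the null is `v / (v + g)` for that row. The bundled
  CENP-C table needs this: one site prints hypothesis support summing to 7
  rather than 8, so its published p-value is only reproducible from the
  printed dosages. Sites inside a duplicated segment are reported but not
  tested — reads from the paralogous copy make the ratio uninterpretable.

No multiple-testing correction is applied; the acceptance summary counts
sites where at least one hypothesis is accepted, which is the quantity the
original analysis reports (17 of 24 testable CENP-C SNPs).

## Expression classification

Reads are assigned to haplotype CDS sequences as exact substrings (both
strands). This is a desk-scale stand-in for mapping with Bowtie2 followed by
re-mapping at 100% identity: the decision rule — only perfect-identity reads
count as haplotype evidence — is the same. A haplotype is

* **expressed** if reads cover its whole CDS, or at least one of its
  *exclusive* SNPs (variant state carried by no other haplotype) is
  supported by at least `min_reads` reads (default 6);
* **not expressed** if it has exclusive SNPs but none are supported;
* **undetermined** if it has no exclusive SNPs and no full coverage —
  indistinguishable from its relatives.

Reads that mismatch every haplotype are unassigned and contribute to no
tally; reads containing `N` count toward coverage but never toward variant
coverage. For dosage tallies (as opposed to expression calls) reads are
placed against a *single* reference haplotype with a mismatch budget
(`assign_reads(..., max_mismatch = )`, seed-and-verify placement), because
reads carrying novel alleles of the missing haplotype must still be placed —
mirroring the original mapping at 90% similarity.

## Distances and dating

* `JC69`: `d = -(3/4) ln(1 - 4p/3)`; flagged saturated at `p >= 3/4`.
* `K2P`: `d = -(1/2) ln(1 - 2P - Q) - (1/4) ln(1 - 2Q)` with transitions and
  transversions separated; reduces exactly to JC69 when `P = p/3`,
  `Q = 2p/3`.
* `NG86`: synonymous/nonsynonymous sites by single-base neighbour
  enumeration per codon, differences averaged over all minimal mutational
  pathways, then JC-corrected into `dS` and `dN`. Conventions chosen where
  the method leaves room: stop-codon *neighbours* count as nonsynonymous in
  site counting; *pathways* through stop codons are excluded from averaging
  (all pathways are used if every one hits a stop); site counts are averaged
  over the two sequences, making the statistic symmetric. Codons containing
  a gap or ambiguity in either sequence are excluded pairwise.

Dating is the strict clock `T = d / (2r)`. Rate presets are `6.5e-9`
substitutions/site/year for coding and `1.3e-8` for noncoding sequence
(grass nuclear calibrations); both are plain numbers and can be replaced.
For coding comparisons `dS` is the default dating distance, with `dN`
reported alongside — the choice is exposed rather than hard-coded because
either convention is defensible. LTR insertion ages use the same formula on
the distance between an element's two terminal repeats, K2P by default (the
common convention for LTR dating; JC69 selectable). Gap/`N` columns are
pairwise-deleted everywhere; saturated distances propagate as flags
(`valid = FALSE`, `NA` ages), never as exceptions.

## Trees

`neighbor_joining()` is the classic Saitou–Nei agglomeration. Two
conventions are pinned for determinism and reproducibility:

* ties in the Q-criterion are broken by the lexicographically smallest label
  pair, so the tree does not depend on input order;
* negative branch lengths are clamped to zero with the deficit moved to the
  sibling branch, preserving path lengths.

On additive matrices the algorithm is exact (verified in the tests against
an exhaustive-topology least-squares oracle for up to six leaves, and
against `ape::nj`). Saturated pairs abort matrix construction with an error
listing the offending pairs rather than building a partial tree. Rooting
places the root at the midpoint of the outgroup's pendant edge; monophyly is
an exact clade-set test. Bootstrap support is not implemented.

## What the synthetic generator emulates

`simulate_locus()` draws an ancestral sequence, optionally splits off a
paralogous region copy at a duplication age, radiates each family along a
star tree, and emits `H` of `P` haplotypes as "observed" while the truth set
records all of them — reproducing the studied design: ploidy 8 with 7
recovered haplotypes, or ploidy 10 with 9, one haplotype always implied but
unsequenced. `simulate_reads()` draws unspliced CDS fragments
haplotype-by-haplotype with multinomial expression weights (weight 0
silences a haplotype; the genomically missing haplotype is still expressed),
uniform starts, and independent per-base errors.

Default conditions: 600-bp locus, star radiation 0.5 My at the coding rate
(matching the observed within-region haplotype divergence scale of
0.3–0.7 My), depth 500, 100-bp reads, per-base error 0.1%. The error rate is
a stand-in — the original RNA-seq error model is not stated — and the
haplotype tree is a star, which understates rate variation among haplotype
lineages. Substitutions follow the exact JC transition probabilities, so
evolving along consecutive branches composes correctly; indels are limited
to configurable fixed deletions (enough to exercise frameshift and
deletion-variant paths, not a realistic indel process). Reads are error-free
fragments of the CDS with no splicing, no coverage bias and no quality
scores. Passing tests on this generator therefore demonstrate the
correctness of the decision rules and estimators under the stated model, not
robustness to alignment artefacts, mapping bias or expression heterogeneity
in real data.

All randomness flows from one integer seed per generator call
(`simulate_reads` defaults to `seed + 1` so a locus and its reads are
jointly reproducible); outputs are byte-identical under identical seeds.

## Numerical choices and degenerate inputs

* Degenerate nulls `p0 = 0` or `1` return p-value 1 exactly when the
  observation matches (`k = 0` resp. `k = n`), else 0 — this is how the
  `v = 0` hypothesis of an undetected-in-genome SNP behaves.
* Zero-coverage sites are reported untestable (`NA`), not errors; zero
  variants give a flagged-undefined SNP density, not a division error.
* Variant polarity: the majority state is "common"; exact ties are broken
  lexicographically (smaller state is common). Adjacent polymorphic columns
  merge into one multi-base substitution only when carried by an identical
  haplotype set; contiguous gap runs with an identical gapped set collapse
  to one indel event, and a deletion that duplicates its flanking sequence
  is flagged as a tandem-repeat deletion.
* SNP density uses the ungapped reference length (not alignment columns) as
  denominator; homeolog-collapse identity uses matches over columns not
  gapped in both sequences, `N` never counting as a match, with
  single-linkage grouping strictly above the threshold.
* Translation never fails on ambiguity: codons containing non-ACGT become
  `X`; a frameshift is flagged from length arithmetic
  (`L mod 3 != 0` or `L != 3(expected + 1)`), a premature stop from the
  first in-frame stop, and an ORF whose stop is never reached is flagged
  incomplete.

## Problem sizes

The test-suite and calibration sizes are chosen to give stable statistics at
interactive cost: the binomial implementation is checked against brute-force
enumeration for every `k` at `n <= 200` over eight null proportions; NJ
against the exhaustive topology oracle for 4–6 leaves; clock recovery over
200 replicate pairs (1–2 kb); the null rejection rate of the dosage test
over 2000 draws at `n = 500`; and silenced-haplotype detection over 100
simulated loci at depth 500. The published worked examples run in well under
a second.

## Limitations

* Read assignment is ungapped and exact (or Hamming-budgeted); spliced
  alignment, indel-tolerant mapping and quality-aware genotyping are out of
  scope, as are assembly, gene prediction and repeat discovery.
* Ploidy enters as configuration (from cytology); the package does not
  estimate it from segregation data.
* The clock is strict; rate heterogeneity and ML substitution models are
  not modelled, and NG86 is the only codon-aware distance.
* Indel dosage is not tallied from reads (indel records pass through with
  `NA` counts); the published deletion rows are testable because their
  counts are given.
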