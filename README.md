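# polydosage

Allele dosage, allele-specific expression and divergence analysis for
highly polyploid loci.

Polyploid crops such as sugarcane carry many near-identical copies
(haplotypes) of every locus, spread across homeologous chromosome groups.
Sequencing (e.g. from BAC clones) recovers some of those haplotypes,
cytology fixes how many copies must exist, and transcriptome reads carry the
allelic signal of all copies — including the ones never sequenced.
`polydosage` implements the analyses that connect these three data sources
for a locus with ploidy `P` and `H` recovered haplotypes:

* **Haplotype catalogue** — variant calling among aligned haplotypes (SNPs,
  multi-base substitutions, indels, tandem-repeat deletions), SNP densities
  on the reference, diagnostic SNPs between homeologous region copies,
  collapse of >99%-identical clones into homeologs, gene-haplotype grouping
  by identical CDS, and frameshift / premature-stop detection.
* **Expression evidence** — read assignment to haplotype CDS at 100%
  identity (both strands), per-SNP coverage and variant-coverage tallies,
  and classification of each gene haplotype as expressed / not expressed /
  undetermined (detection threshold: ≥ 6 reads on a haplotype-exclusive
  SNP).
* **Missing-haplotype dosage test** — the core statistic. At a SNP carried
  by `x` observed haplotypes, the missing haplotype carries either the
  common allele (genomic dosage `v = x`) or the variant (`v = x + P − H`);
  a SNP absent from the genomic haplotypes pins both hypotheses at
  `v = P − H`. Each hypothesis is tested with the **exact two-sided
  binomial test** of the transcriptome counts `k/n` against the exact
  fraction `v/P` (small-probability summation, no normal approximation),
  accepting at `p ≥ α` (default 0.05).
* **Molecular clock** — p, JC69, K2P and Nei–Gojobori (NG86) `dS`/`dN`
  distances; divergence dating by `T = d/2r` (coding rate `6.5e-9`,
  noncoding `1.3e-8` subs/site/year); LTR retrotransposon insertion ages
  from the divergence of an element's two terminal repeats.
* **Phylogeny** — neighbor-joining with deterministic tie-breaking and
  negative-branch clamping, outgroup rooting, exact monophyly tests
  (`ape::phylo` objects throughout).
* **Synthetic data** — a fully seeded generator for polyploid loci
  (P haplotypes, one unobserved), duplication scenarios, LTR pairs and
  allele-specific read sets with complete truth records, so every stage is
  testable without downloads.

User-facing functions take data frames first and return tibbles, so
pipelines compose with the pipe; fitted dosage tables support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

The package bundles the published per-SNP count tables for the sugarcane
*HP600* and *CENP-C* genes (ploidy 8, seven recovered haplotypes, one
missing). Re-running the dosage test over the *CENP-C* table:

```r
library(polydosage)

tab <- run_dosage_table(cenpc_snps(), ploidy = 8)
tab
#> <dosage_table> 50 sites (24 tested, ploidy 8, alpha 0.05)
#> >=1 hypothesis accepted at 17/24 tested sites (71%)

glance(tab)
#> # A tibble: 1 × 5
#>   n_sites n_tested n_accepted prop_accepted alpha
#>     <int>    <int>      <int>         <dbl> <dbl>
#> 1      50       24         17         0.708  0.05
```

26 sites fall inside the segment duplicated between the two homeologous
regions and are reported but not tested (reads from the paralog confound
the ratio). Of the 24 testable SNPs, 17 accept at least one
missing-haplotype hypothesis — the genomic dosage explains the
transcriptome ratio at 71% of sites, consistent with roughly equal
per-copy expression.

A single site, by hand — 101 variant reads among 443 covering the first
*HP600* SNP, carried by 1 of 7 observed haplotypes:

```r
h <- build_hypotheses(detected = TRUE, observed_variant_count = 1,
                      ploidy = 8, observed = 7)
test_snp_dosage(443, 101, h)
#> # A tibble: 2 × 9
#>   scenario     genomic_variant genomic_common proportion p_value accept coverage
#>   <chr>                  <int>          <int>      <dbl>   <dbl> <lgl>     <dbl>
#> 1 missing_com…               1              7      0.125 2.32e-9 FALSE       443
#> 2 missing_var…               2              6      0.25  2.98e-1 TRUE        443
```

The observed ratio (0.23) rejects a dosage of 1/8 (p = 2.3e-9) but is
compatible with 2/8 (p = 0.30): the missing haplotype most plausibly
carries the variant allele at this site.

Dating an LTR insertion from a simulated element of known age:

```r
sim <- simulate_ltr_pair(age = 2.3e6, rate = 1.3e-8, length = 2000, seed = 7)
ltr_insertion_age(sim$ltr5, sim$ltr3, rate = 1.3e-8)
#> # A tibble: 1 × 5
#>   model      d        rate age_years valid
#>   <chr>  <dbl>       <dbl>     <dbl> <lgl>
#> 1 K2P   0.0636 0.000000013  2447136. TRUE
```

The two terminal repeats have diverged `d = 0.064` substitutions/site,
dating the insertion at `d/2r ≈ 2.4` My against a true age of 2.3 My.

See `vignette("polyploid-dosage")` for the model, conventions and
limitations.

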