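---
title: "Targeted SNP discovery in duplicated genomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted SNP discovery in duplicated genomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrsnp)
```

# The discovery model

`utrsnp` targets polymorphism discovery in annotated full-length cDNAs
(FLIcs) of species carrying a recent genome duplication. The central
difficulty is not finding sequence differences — it is deciding which
differences are allelic. Three confounders dominate:

1. **paralogous sequence variants (PSVs)** — fixed differences between
   co-amplified paralogous loci that look like SNPs;
2. **sequencing errors** in single-pass EST reads, concentrated at the
   read ends;
3. **alignment artifacts** inside low-complexity runs, where a real
   difference cannot be placed unambiguously.

The package addresses each with an explicit, testable rule rather than a
score. Two discovery routes share one validation back end:

* the *3'UTR-primed* route designs a 350–450 bp amplicon entirely inside
  the 3'UTR — long enough to scan several hundred bases per gene, short
  enough for full bidirectional Sanger coverage — and discovers variants
  directly during panel genotyping;
* the *in silico* route first mines candidate sites from EST-to-cDNA
  alignments, then designs a short 130–170 bp amplicon spanning each
  candidate (short products limit the chance of co-amplifying a large
  intron from genomic DNA, since primers designed on transcript
  coordinates may straddle exon boundaries).

## Validation and the PSV rule

Genotypes come from per-individual Sanger consensus sequences aligned to
the amplicon; heterozygous positions carry IUPAC ambiguity codes, `N` is
a missing call (excluded from all counts, mirroring manual exclusion of
low-quality chromatogram positions). A column with more than two alleles
is flagged and set aside — the model is strictly bi-allelic.

For a bi-allelic site with genotype counts (hom-ref, het, hom-alt) over
the called individuals:

* **carrier rule** — the *rare* allele is the one with the lower sample
  allele count (ties resolve to the non-reference allele), and a carrier
  is an individual with at least one copy. Validation requires ≥ 2
  carriers. We read the rule as a count of individuals, not chromosomes,
  because single-carrier observations are exactly the ones a lone
  sequencing artifact can produce. A site with exactly one carrier is
  reported as `unconfirmed_single_carrier` with a request for extension
  typing; when 5 extension individuals are supplied, every rule is
  re-tested on the pooled 15 (pooling, not a second independent test —
  the protocol extends the same panel).
* **PSV rule** — if *every* called individual is heterozygous the site is
  excluded as a PSV. Under Hardy–Weinberg equilibrium the probability of
  that pattern is $(2pq)^n$, maximized at $p=q=0.5$, giving
  $0.5^{10} \approx 0.001$ for the default panel of $n=10$; that number
  is the significance level of the exclusion. Only *total*
  heterozygosity excludes. The natural generalization — the exact
  conditional probability of at least the observed heterozygote count
  when the $2n$ observed allele copies are paired at random (Levene's
  distribution, computed by `het_excess_exact()`) — is always reported
  but never auto-excludes, because partial excess is also produced by
  genuine population structure and small-sample noise; a configurable
  threshold would silently change headline behavior. With fewer than 6
  called individuals $(2pq)^n$ loses discrimination, so such sites carry
  a low-power flag.
* **amplicon QC** — before genotyping, a two-individual screen failing
  with ≥ 5 heterozygous columns (pooled over the screen individuals —
  the union, since either individual's chromatogram would have triggered
  manual rejection) marks the amplicon as co-amplified and drops it.

## Mining filters

EST reads are aligned to their FLIc by global alignment with free end
gaps (the read is a fragment of the transcript): match +1, mismatch −2,
gap opening −5 for the first gapped base and −2 per extension. The
parameters are conventional; what matters downstream is that they are
fixed, making alignments — and hence the candidate set — deterministic.
Filters, in their order of intent (the final candidate set is provably
order-independent; the test suite checks this against a brute-force
per-column oracle):

* **identity floor** 0.96 over aligned columns;
* **minimum aligned length** 100 columns. A database E-value cutoff
  cannot be reproduced without the database; a minimum aligned length
  combined with the identity floor dominates it for transcript-scale
  alignments and is self-contained, so we use that instead;
* **paralog rule** — more than 4 differences (mismatch or gap columns)
  inside any sliding 100-column window rejects the whole read as
  paralog-derived. A looser variant (> 3 per 100 bp) appears in informal
  descriptions of this rule; 4 is the operational default here and the
  threshold is configurable;
* **end trim** — differences within the first or last 50 bases of the
  read, *in the read's own coordinates*, are ignored: the rule targets
  read-end quality decay, which travels with the read, not with the
  target;
* **repeat mask** — differences inside homopolymer runs ≥ 5 nt or
  di-/tri-nucleotide tandem repeats ≥ 3 units on the target are ignored.
  "Simple repeat" has no canonical micro-definition at this scale; these
  thresholds are deliberate, configurable operationalizations.

Evidence from multiple reads is merged per site: a per-read rejection is
an evidence filter, not a site veto, so a site rejected through one read
but supported cleanly by another remains a candidate (one clean
supporting read suffices by default; the count is configurable).

## Primer design

The designer is a self-contained scorer rather than a wrapper around an
external design tool: the only constraints the protocol fixes are the
product-size ranges, the 60 °C Tm optimum, and the M13 tails, and an
exhaustive search over primer positions (lengths 18–24 nt) under those
constraints is cheap at transcript scale. Melting temperatures use
nearest-neighbor thermodynamics (SantaLucia 1998 unified parameters) at
fixed standard conditions — 50 mM monovalent salt, 0.25 µM oligo with
the CT/4 approximation — so Tm is a pure function of sequence; the
Wallace rule is available for hand checks. The pair score penalizes
|Tm − 60| per primer, product-length deviation from the range midpoint,
GC outside 0.35–0.65, and 3'-end complementarity ≥ 4 nt between the
primers (a primer-dimer proxy). Size ranges are *hard* constraints:
infeasible pairs are never scored, so no returned design can violate
them. Ties break leftmost-then-shortest, making the design deterministic.
A 3'UTR shorter than the minimum product size fails with reason
`utr_too_short` rather than silently relaxing the range. EPIC mode only
applies its 200–250 bp size range on transcript coordinates — true
intron crossing needs genomic sequence — and is marked experimental.

# The simulator: what it emulates, and what it does not

`sim_config()` defaults encode the study conditions: a 10-individual
diploid panel plus 5 extension individuals, 3'UTRs of 200–800 nt, and a
DIP fraction of 16/79 (the observed SNP/DIP split among discovered
polymorphisms). Values the protocol does not fix are package choices,
set once: CDS lengths 300–1500 nt (typical mRNA coding lengths), 5 ESTs
per gene of 300–600 nt at a 1 % per-base substitution error rate
(single-pass EST quality), a 0.5 paralog fraction, paralog divergence
0.03/bp in the 3'UTR reduced ×0.3 in the CDS (purifying selection), 25 %
of reads paralog-derived, and planted minor-allele frequencies drawn
from {0.05, 0.1, 0.25, 0.5}. Base composition is uniform with no
transition/transversion bias (no substitution model is implied by the
protocol; uniform is the minimal assumption). DIPs are single-base
deletions — the minimal case — and EST errors are substitutions only by
default so alignment columns stay well defined; an indel-error mode
exists as a flag. An optional flag plants poly-G/C runs (6–10 nt) to
exercise the repeat mask.

Panel sampling is exact Hardy–Weinberg: two independent allele draws per
individual per site. Heterozygous single-base deletions in consensus
strings are encoded as the lowercase reference base — Sanger consensus
software has no standard encoding for a base/gap heterozygote
(frameshifted double traces), so this is an explicit artifact convention
of the file dialect, documented in `read_panel()`.

What the simulator does **not** model: coalescent genealogies,
recombination, selection, linkage between sites, realistic quality
scores, chromatogram-level artifacts, or wet-lab attrition (failed PCRs,
multiple gel bands). Consequently, passing recovery tests show that the
*rules* behave as specified under their own assumptions — they do not
certify discovery rates on real data, where attrition and non-HWE
structure dominate the published success-rate tables.

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; every file format and
  report is 1-based inclusive. The conversion happens only at IO
  boundaries.
* All reported rates round half *up* at the printed precision (two
  decimals for rates, nearest 10 bp for density); base R's half-to-even
  rounding does not reproduce conventional printed tables. A zero
  denominator reports `-`, never `NaN`.
* The 2×2 method comparison is Pearson chi-square *without* continuity
  correction by default — the uncorrected statistic is the conventional
  one for this comparison — with Yates and Fisher (one- and two-sided)
  always co-reported. Zero margins are an error.
* `validate_variant()` treats an extension call introducing a third
  allele as an error rather than silently re-classifying the site.
* Reverse-complement read orientation is recovered only when the
  orientation search is enabled; FLIcs are sense-strand by construction,
  so it is off by default.

# Problem sizes in the test suite

The suite sizes its simulations to make each statistical check sharp but
cheap: 1000 paralog pairs for the divergence expectation, 10⁴ genotype
draws for the Hardy–Weinberg goodness-of-fit, 500 replicates per MAF for
the exact carrier-probability recovery test (tolerance 3 standard
errors), 20 error-free replicates for total PSV exclusion, 8 + 4
simulated instances (targets ≤ 2 kb) for the brute-force mining oracle,
100 random tables for the chi-square oracle (tolerance 10⁻⁸), and 200
simulated genes for the design size-range property.

# Known limitations

* Bi-allelic only; multi-allelic columns are flagged and excluded rather
  than modeled.
* The paralog/identity filters assume a single dominant paralog; a
  mixture of several highly similar copies can pass windows that a
  joint model would catch.
* Primer design has no secondary-structure thermodynamics or multiplex
  compatibility; the dimer proxy is 3'-end complementarity only.
* DIP handling is single-base; longer indels would need both a richer
  consensus encoding and VCF normalization beyond left-anchoring.
* EPIC designs are size-range-only (experimental), as noted above.
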