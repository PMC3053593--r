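# utrsnp

Targeted discovery of SNPs and small deletion–insertion polymorphisms
(DIPs) in annotated genes of species with duplicated genomes.

## The problem

In partially tetraploid species such as salmonids, a recent whole-genome
duplication left large numbers of near-identical paralogous gene copies.
PCR primers placed in conserved coding sequence routinely co-amplify a
paralog, and a fixed difference between the two loci — a *paralogous
sequence variant* (PSV) — then masquerades as a SNP. Genomic reference
sequence is often unavailable in such species, so intron-primed strategies
cannot be used at scale. What is available are full-length-sequenced cDNAs
(FLIcs), annotated with the complete coding sequence (CDS) and the
complete 3' untranslated region (3'UTR).

`utrsnp` implements a discovery pipeline built on two observations about
3'UTRs: they are weakly conserved, so (i) their polymorphism density is
higher than in coding sequence and (ii) paralogs have diverged most there,
allowing locus-specific priming. The package provides:

* **3'UTR-primed amplicon design** — primer pairs inside the 3'UTR
  amplifying 350–450 bp products (nearest-neighbor melting temperatures,
  60 °C optimum, universal M13 sequencing tails);
* **in silico candidate-SNP mining** — ESTs aligned to their FLIc, with
  the filter chain: ≥ 96 % alignment identity, minimum aligned length,
  differences in the first/last 50 bases of a read ignored (read-end
  quality decay), differences inside homopolymers/simple repeats ignored,
  and any read with > 4 differences per 100 aligned bp rejected as
  paralog-derived; short 130–170 bp validation amplicons around surviving
  candidates;
* **diploid-panel validation** — per-individual Sanger consensus calls
  (IUPAC heterozygote codes) over each amplicon in a small panel
  (n = 10 by default). A site is approved only if the rare allele is
  carried by ≥ 2 individuals (a single carrier triggers typing of 5 more
  individuals and re-testing on the pooled 15); amplicons whose
  two-individual screen shows ≥ 5 heterozygous sites are dropped as
  co-amplified;
* **PSV exclusion** — a true SNP segregates according to Hardy–Weinberg
  expectations, while a co-amplified PSV is heterozygous in *every*
  individual. Under HWE the all-heterozygote probability is
  `(2pq)^n`, maximized at `p = q = 0.5`; with n = 10 that is
  `0.5^10 ≈ 0.001`, so the all-heterozygote pattern is excluded as a PSV.
  An exact conditional heterozygote-excess probability (random pairing of
  the observed allele copies) is reported alongside;
* **a synthetic-data generator** — duplicated targets with tunable
  paralog divergence (lower in the CDS than in the 3'UTR), planted
  SNPs/DIPs at chosen minor-allele frequencies, HWE panel sampling, and
  error-bearing ESTs — so the whole pipeline is testable against known
  ground truth;
* **summary statistics** — per-stage success rates, conversion rate,
  polymorphism density, and 2×2 chi-square / Fisher comparisons of
  discovery methods.

## Worked example

A small synthetic dataset (two duplicated genes, two planted SNPs each, a
10 + 5 individual panel) ships in `inst/extdata`:

```r
library(utrsnp)
ex <- function(f) system.file("extdata", f, package = "utrsnp")
flics  <- read_flics(ex("sim_targets.fa"), ex("sim_annot.tsv"))
refs   <- vapply(flics, function(f) extract_utr3(f)$sequence, "")
panels <- read_panel(ex("sim_panel.fa"), refs = refs)

g <- genotype_panels(panels, flics)
g$summary[, c("amplicon_id", "position", "ref", "alt", "status",
              "carriers", "p", "all_het_p")]
#>   amplicon_id position ref alt    status carriers    p    all_het_p
#> 1     SIMG001       85   T   A validated        7 0.60 6.492506e-04
#> 2     SIMG001      299   T   G validated        3 0.80 1.125900e-05
#> 3     SIMG002      119   T   A validated        3 0.85 1.162524e-06
#> 4     SIMG002      237   G   A validated        6 0.35 3.802892e-04
```

All four planted SNPs are recovered and validated: each rare allele has at
least two carriers, and no site shows the all-heterozygote PSV signature
(`all_het_p` is the HWE probability of the all-heterozygote pattern at the
observed allele frequencies — small values here simply mean the pattern
would have been very surprising, and it was not observed).

Designing a 3'UTR-primed amplicon for the first gene:

```r
design_amplicon(flics[[1]], design_params("utr_primed"))
#> <amplicon_design> SIMG001 [utr_primed]: product 390 bp at [307,697); Tm 60.0/58.9 C; score 1.64
```

The product length respects the hard 350–450 bp range, primers sit inside
the 3'UTR, and both melting temperatures are near the 60 °C optimum.

Summary statistics of a discovery run:

```r
snp_density(66000, 63, 16)      # bp scanned per polymorphism
#> $raw      835.443
#> $rounded  840
all_het_probability(10, 0.5)    # PSV exclusion significance at n = 10
#> 0.0009765625
```

`write_vcf()` emits validated variants as VCF 4.2 (CHROM = transcript
accession, INFO fields `REGION`, `EFFECT`, `CARRIERS`, `ALLHET_P`, GT
columns per panel individual), and `variants_table()` the equivalent TSV.

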