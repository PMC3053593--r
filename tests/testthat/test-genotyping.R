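# consensus-string builders: a column spec is a string of per-individual
# characters; build_calls(c("A...", "R...")) transposes columns to strings
build_calls <- function(cols) {
  n <- nchar(cols[1])
  vapply(seq_len(n), function(i)
    paste(vapply(cols, substr, "", i, i), collapse = ""), "")
}

test_that("two-individual screen fails amplicons with five or more het sites", {
  # 5 heterozygous columns pooled over the two screen individuals
  i1 <- "ARARARCGT"
  i2 <- "AAAAYAYGT"     # het columns: 2,4,6 (i1) + 5,7 (i2) = 5 pooled
  p <- make_panel(c(i1, i2, "AAAAAACGT"))
  qc <- qc_amplicon(p)
  expect_identical(qc$het_site_count, 5L)
  expect_identical(qc$verdict, "fail_multi_het")

  p4 <- make_panel(c("ARARARCGT", "AAAAAAAGT", "AAAAAACGT"))
  qc4 <- qc_amplicon(p4)
  expect_identical(qc4$het_site_count, 3L)
  expect_identical(qc4$verdict, "pass")

  pn <- make_panel(c(strrep("N", 9), strrep("N", 9), "AAAAAACGT"))
  expect_identical(qc_amplicon(pn)$verdict, "fail_quality")
  expect_error(qc_amplicon(p, screen_ids = character(0)), "empty")
  expect_error(qc_amplicon(p, screen_ids = "nope"), "not in panel")
})

test_that("site calling decodes IUPAC columns into genotype counts", {
  # column 1: 7 x A + 3 x R (A/G het); column 2: monomorphic C;
  # column 3: three alleles
  third <- c("A", "C", "G", "A", "A", "A", "A", "A", "A", "A")
  calls <- paste0(c(rep("A", 7), rep("R", 3)), "C", third)
  p <- make_panel(calls)
  sites <- call_sites(p)
  expect_length(sites, 1L)        # monomorphic and multi-allelic columns excluded
  s <- sites[[1]]
  expect_identical(s$position, 0L)
  expect_identical(s$ref_allele, "A")
  expect_identical(s$alt_allele, "G")
  expect_identical(unname(s$genotype_counts), c(7L, 3L, 0L))
  expect_identical(s$carriers_of_rare, 3L)
  expect_identical(s$site_class, "SNP")
  expect_identical(attr(sites, "multi_allelic"), 2L)
})

test_that("N calls are missing data and counts sum to called individuals", {
  calls <- c("A", "A", "N", "M", "C", "A", "N", "A", "M", "A")
  p <- make_panel(calls)
  s <- call_sites(p)[[1]]
  expect_identical(s$n_called, 8L)
  expect_identical(sum(s$genotype_counts), s$n_called)
  expect_identical(unname(s$genotypes[c(3, 7)]), c("./.", "./."))
})

test_that("deletion columns are DIP sites with the gap allele", {
  calls <- c("a", "a", "-", "A", "A", "A", "A", "A", "A", "A")
  s <- call_sites(make_panel(calls, ref = "A"))[[1]]
  expect_identical(s$site_class, "DIP")
  expect_identical(s$ref_allele, "A")
  expect_identical(s$alt_allele, "-")
  expect_identical(unname(s$genotype_counts), c(7L, 2L, 1L))
  expect_identical(s$carriers_of_rare, 3L)
})

test_that("carrier rule: two carriers validate, one requests extension", {
  # (8,2,0): 2 carriers -> validated, p(ref) = 0.9
  calls <- c(rep("A", 8), "R", "R")
  v <- validate_variant(call_sites(make_panel(calls, ref = "A"))[[1]])
  expect_identical(v$status, "validated")
  expect_equal(v$p, 0.9)

  # (9,1,0): single carrier, no extension -> unconfirmed + request
  calls <- c(rep("A", 9), "R")
  v <- validate_variant(call_sites(make_panel(calls, ref = "A"))[[1]])
  expect_identical(v$status, "unconfirmed_single_carrier")
  expect_true(v$extension_requested)

  # extension brings a second carrier among 5 more -> validated on pooled 15
  ext <- c(e1 = "A", e2 = "R", e3 = "A", e4 = "A", e5 = "A")
  v <- validate_variant(call_sites(make_panel(calls, ref = "A"))[[1]],
                        extension = ext)
  expect_identical(v$status, "validated")
  expect_true(v$extension_used)
  expect_identical(v$n_called, 15L)
  expect_identical(v$carriers_of_rare, 2L)

  # extension with no further carrier stays unconfirmed
  v <- validate_variant(call_sites(make_panel(calls, ref = "A"))[[1]],
                        extension = c(e1 = "A", e2 = "A", e3 = "A",
                                      e4 = "A", e5 = "A"))
  expect_identical(v$status, "unconfirmed_single_carrier")
})

test_that("the all-heterozygote pattern is excluded as a PSV at P = 0.5^n", {
  s <- call_sites(make_panel(rep("R", 10), ref = "A"))[[1]]
  chk <- psv_check(s)
  expect_true(chk$is_psv)
  expect_equal(chk$all_het_probability, 0.5^10)
  expect_equal(chk$all_het_probability, 0.0009765625)
  v <- validate_variant(s)
  expect_identical(v$status, "psv_excluded")

  s2 <- call_sites(make_panel(c(rep("A", 5), rep("R", 5)), ref = "A"))[[1]]
  expect_false(psv_check(s2)$is_psv)
  expect_identical(validate_variant(s2)$status, "validated")
})

test_that("exact heterozygote-excess probability matches a pairing oracle", {
  cases <- list(c(1L, 8L, 1L), c(2L, 6L, 2L), c(4L, 5L, 1L))
  set.seed(99)
  for (cs in cases) {
    s <- call_sites(make_panel(
      c(rep("A", cs[1]), rep("R", cs[2]), rep("G", cs[3])), ref = "A"))[[1]]
    exact <- psv_check(s)$het_excess_p
    mc <- oracle_het_excess_mc(cs[1], cs[2], cs[3], B = 4e4)
    se <- sqrt(mc * (1 - mc) / 4e4)
    expect_lt(abs(exact - mc), max(4 * se, 0.005))
  }
  # degenerate: all-het has probability equal to the all-het table mass
  expect_equal(het_excess_exact(0, 2, 0), 2 / 3)  # nA=na=2: {het,het} vs {AA,aa}
})

test_that("allele frequencies are conserved and sum to one", {
  set.seed(12)
  for (r in 1:20) {
    n_alt <- sample(0:2, 10, TRUE, prob = c(0.5, 0.3, 0.2))
    if (length(unique(n_alt)) == 1L) next
    calls <- c("A", "M", "C")[n_alt + 1L]
    s <- call_sites(make_panel(calls, ref = "A"))
    if (!length(s)) next
    v <- validate_variant(s[[1]])
    expect_identical(sum(v$genotype_counts), v$n_called)
    expect_equal(v$p + v$q, 1)
  }
})

test_that("coding-region annotation classifies substitutions and frameshifts", {
  # CDS ATG GCA TAT TGG ...: codon 2 is GCA (Ala)
  seq <- paste0("ATGGCATATTGGAAACCC", strrep("ACGT", 30), "GCTTAA",
                paste(rep("T", 60), collapse = ""))
  L <- nchar(seq)
  rec <- flic_record("C1", seq, cds = interval(0L, L - 60L),
                     utr3 = interval(L - 60L, L))
  # third position of codon GCA (transcript pos 5, 0-based): A->G: GCA->GCG (Ala)
  expect_identical(annotate_region(5L, "A", "G", rec)$cds_effect, "synonymous")
  # second position: GCA->GAA is Ala->Glu
  expect_identical(annotate_region(4L, "C", "A", rec)$cds_effect, "missense")
  # TGG -> TGA is Trp -> stop (transcript pos 11)
  expect_identical(annotate_region(11L, "G", "A", rec)$cds_effect, "nonsense")
  # deletion in CDS
  expect_identical(annotate_region(4L, "C", "-", rec)$cds_effect, "frameshift")
  # UTR position
  ann <- annotate_region(L - 10L, "T", "C", rec)
  expect_identical(ann$region, "UTR3")
  expect_identical(ann$cds_effect, "not_applicable")
  expect_error(annotate_region(L + 5L, "A", "C", rec), "outside")
})

test_that("SNP annotation agrees with translating both alleles at every CDS position", {
  set.seed(77)
  seq <- paste0("ATG", paste(sample(c("A", "C", "G", "T"), 57, TRUE), collapse = ""),
                paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""))
  rec <- flic_record("C2", seq, cds = interval(0L, 60L), utr3 = interval(60L, 160L))
  for (pos in 0:59) {
    ref <- substr(seq, pos + 1, pos + 1)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      got <- annotate_region(pos, ref, alt, rec)$cds_effect
      codon0 <- (pos %/% 3) * 3
      ref_cod <- substr(seq, codon0 + 1, codon0 + 3)
      alt_cod <- ref_cod
      substr(alt_cod, pos - codon0 + 1, pos - codon0 + 1) <- alt
      aa_r <- oracle_translate(ref_cod); aa_a <- oracle_translate(alt_cod)
      want <- if (aa_r == aa_a) "synonymous"
              else if (aa_a == "*") "nonsense" else "missense"
      expect_identical(got, want)
    }
  }
})

test_that("VCF output round-trips through an independent VCF reader", {
  skip_if_not_installed("VariantAnnotation")
  ref <- "ACGTACGTAC"
  calls <- c("AMGTACGTAC", "ACGTACGTAC", "ACGTACGTAC",
             "AMGTACGTAC", "ACGTACGTAC", "ACGTAcGTAC",
             "ACGTAcGTAC", "ACGTACGTAC", "ACGTACGTAC",
             "ACGTACGTAC")
  p <- make_panel(calls, amplicon = "G1", ref = ref)
  res <- genotype_amplicon(p, run_qc = FALSE)
  vcf_path <- tempfile(fileext = ".vcf")
  write_vcf(res$variants, vcf_path, templates = c(G1 = ref))
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "sim")
  rr <- SummarizedExperiment::rowRanges(vcf)
  expect_identical(unname(BiocGenerics::start(rr)), c(2L, 5L))
  expect_identical(as.character(rr$REF), c("C", "AC"))   # SNP + left-anchored DIP
  expect_identical(as.character(unlist(rr$ALT)), c("A", "A"))
  gt <- VariantAnnotation::geno(vcf)$GT
  expect_identical(unname(gt[1, 1:4]), c("0/1", "0/0", "0/0", "0/1"))
  expect_identical(unname(gt[2, 6:7]), c("0/1", "0/1"))
  info <- VariantAnnotation::info(vcf)
  expect_identical(info$CARRIERS, c(2L, 2L))
})

test_that("genotype_panels recovers planted variants with their effects", {
  cfg <- sim_config(seed = 61, n_genes = 4, maf_distribution = 0.5,
                    planted_snps_per_gene = 1, paralog_fraction = 0,
                    dip_fraction = 0)
  sim <- simulate_targets(cfg)
  panels <- simulate_panel(sim, cfg)
  g <- genotype_panels(panels, sim$flics)
  expect_true(all(g$summary$region == "UTR3"))
  # every emitted site is a planted one (error-free panel)
  for (acc in names(panels)) {
    planted <- sim$truth[[acc]]$variants$pos
    got <- vapply(g$results[[acc]]$variants, function(v)
      v$position + sim$flics[[acc]]$utr3[["start"]], 0L)
    expect_true(all(got %in% planted))
  }
  tal <- tally_discovery(g)
  expect_s3_class(tal, "stage_counts")
  expect_lte(tal$genes_with_snp, tal$genes_tested)
})
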