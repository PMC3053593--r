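# helpers building deterministic targets and reads
rand_flic <- function(seed, len = 1000L, acc = "T1") {
  set.seed(seed)
  # reject draws containing simple repeats so filter tests are surgical
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    if (!any(mask_repeats(s))) break
  }
  flic_record(acc, s, utr3 = interval(len - 200L, len))
}

put <- function(seq, pos1, base) { substr(seq, pos1, pos1) <- base; seq }
other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

test_that("an exact substring aligns with identity 1 and no internal gaps", {
  fl <- rand_flic(101)
  est <- substr(fl$sequence, 201, 500)
  a <- align_est(est, fl, est_id = "E1")
  expect_equal(a$identity, 1)
  expect_false(grepl("-", a$aligned_est, fixed = TRUE))
  expect_false(grepl("-", a$aligned_flic, fixed = TRUE))
  expect_identical(a$flic_span, c(200L, 500L))
  expect_identical(a$est_span, c(0L, 300L))
  expect_true(a$usable)
})

test_that("identity counts mismatched aligned columns", {
  fl <- rand_flic(102)
  est <- substr(fl$sequence, 201, 500)
  est <- put(est, 150, other_base(substr(est, 150, 150)))
  a <- align_est(est, fl)
  expect_equal(a$identity, 299 / 300)
})

test_that("reverse-complemented reads are recovered only with the orientation search", {
  fl <- rand_flic(103)
  est <- revcomp(substr(fl$sequence, 201, 500))
  fwd <- align_est(est, fl)
  expect_lt(fwd$identity, 0.96)
  both <- align_est(est, fl, search_revcomp = TRUE)
  expect_identical(both$strand, "-")
  expect_equal(both$identity, 1)
  # oracle: aligning the reverse complement directly gives the same score
  direct <- align_est(revcomp(est), fl)
  expect_equal(both$score, direct$score)
})

test_that("whole-EST filters fire on identity, length and the paralog rule", {
  fl <- rand_flic(104)
  base <- substr(fl$sequence, 101, 400)

  # 16 mismatches over 300 columns -> identity 0.947 < 0.96
  est <- base
  for (p in seq(10, 160, by = 10)) est <- put(est, p, other_base(substr(est, p, p)))
  expect_identical(filter_est(align_est(est, fl))$reason, "identity")

  # 5 mismatches inside one 100-column window, identity 295/300 > 0.96
  est <- base
  for (p in c(120, 140, 160, 180, 200)) est <- put(est, p, other_base(substr(est, p, p)))
  expect_identical(filter_est(align_est(est, fl))$reason, "paralog")

  # 4 mismatches spread over 400 columns -> passes both rules
  est <- substr(fl$sequence, 101, 500)
  for (p in c(60, 160, 260, 360)) est <- put(est, p, other_base(substr(est, p, p)))
  expect_identical(filter_est(align_est(est, fl))$reason, "pass")

  # aligned length below the minimum
  short <- substr(fl$sequence, 101, 180)
  expect_identical(filter_est(align_est(short, fl))$reason, "short")
})

test_that("per-column filters: end trim, interior candidate, repeat mask", {
  fl <- rand_flic(105)
  base <- substr(fl$sequence, 301, 600)

  m1 <- put(base, 30, other_base(substr(base, 30, 30)))
  cands <- mine_candidates(align_est(m1, fl, est_id = "E"), fl)
  expect_identical(cands$status, "rejected_end_trim")

  m2 <- put(base, 150, other_base(substr(base, 150, 150)))
  cands <- mine_candidates(align_est(m2, fl, est_id = "E"), fl)
  expect_identical(cands$status, "candidate")
  expect_identical(cands$pos, 449L)          # 0-based transcript position
  expect_identical(cands$supporters, "E")

  # plant a poly-G run in the target and a difference inside it
  seq2 <- fl$sequence
  substr(seq2, 451, 456) <- "GGGGGG"
  fl2 <- flic_record("T2", seq2, utr3 = fl$utr3)
  est2 <- substr(seq2, 301, 600)
  est2 <- put(est2, 153, "A")                # transcript position 453, in the run
  cands <- mine_candidates(align_est(est2, fl2, est_id = "E"), fl2)
  expect_identical(cands$status, "rejected_repeat")
})

test_that("a site rejected through one EST but clean in another stays a candidate", {
  fl <- rand_flic(106)
  alt <- other_base(substr(fl$sequence, 450, 450))
  near_end <- put(substr(fl$sequence, 421, 720), 30, alt)   # within first 50
  interior <- put(substr(fl$sequence, 301, 600), 150, alt)  # same site, clean
  cands <- mine_candidates(list(align_est(near_end, fl, est_id = "E_end"),
                                align_est(interior, fl, est_id = "E_mid")), fl)
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$status, "candidate")
  expect_identical(cands$supporters, "E_mid")
})

test_that("clean reads from unmutated targets yield zero candidates", {
  cfg <- sim_config(seed = 41, n_genes = 4, paralog_fraction = 0,
                    planted_snps_per_gene = 0, est_error_rate = 0)
  sim <- simulate_targets(cfg)
  ests <- simulate_ests(sim, cfg)
  for (acc in names(sim$flics)) {
    ids <- ests$sources$est_id[ests$sources$gene == acc]
    alns <- lapply(ids, function(id)
      align_est(ests$ests[[id]], sim$flics[[acc]], est_id = id))
    expect_identical(nrow(mine_candidates(alns, sim$flics[[acc]])), 0L)
  }
})

test_that("candidate mining matches the brute-force per-column oracle", {
  # simulated instances (targets <= 2 kb) with errors, variants, paralogs
  for (s in 1:8) {
    cfg <- sim_config(seed = 600 + s, n_genes = 2, paralog_fraction = 1,
                      cds_len_range = c(300, 900), utr3_len_range = c(200, 700),
                      est_error_rate = 0.005, est_per_gene = 6,
                      est_paralog_fraction = 0.3,
                      planted_snps_per_gene = 2, plant_repeats = TRUE)
    sim <- simulate_targets(cfg)
    ests <- simulate_ests(sim, cfg)
    for (acc in names(sim$flics)) {
      fl <- sim$flics[[acc]]
      ids <- ests$sources$est_id[ests$sources$gene == acc]
      alns <- lapply(ids, function(id)
        align_est(ests$ests[[id]], fl, est_id = id))
      got <- mine_candidates(alns, fl)
      want <- oracle_mine(alns, fl$sequence)
      expect_identical(got$pos, want$pos)
      expect_identical(got$flic_allele, want$flic_allele)
      expect_identical(got$est_allele, want$est_allele)
      expect_identical(got$status, want$status)
    }
  }
})

test_that("paralog-derived reads are rejected with high probability", {
  # divergence 0.05, read length 500: expect >= 95% flagged as paralog
  n_rej <- 0L; n_tot <- 0L
  for (s in 1:4) {
    cfg <- sim_config(seed = 700 + s, n_genes = 10, paralog_fraction = 1,
                      paralog_divergence = 0.05, cds_divergence_factor = 1,
                      planted_snps_per_gene = 0, est_error_rate = 0,
                      est_per_gene = 5, est_paralog_fraction = 1,
                      est_len_range = c(500, 500),
                      utr3_len_range = c(600, 600), cds_len_range = c(300, 300))
    sim <- simulate_targets(cfg)
    ests <- simulate_ests(sim, cfg)
    for (i in seq_len(nrow(ests$sources))) {
      src <- ests$sources[i, ]
      a <- align_est(ests$ests[[src$est_id]], sim$flics[[src$gene]])
      v <- filter_est(a)
      n_tot <- n_tot + 1L
      if (!v$keep && v$reason %in% c("paralog", "identity"))
        n_rej <- n_rej + 1L
    }
  }
  expect_identical(n_tot, 200L)
  expect_gte(n_rej / n_tot, 0.95)
})

test_that("mine_snps assigns unmapped ESTs to the best-scoring target", {
  cfg <- sim_config(seed = 51, n_genes = 3, paralog_fraction = 0,
                    planted_snps_per_gene = 0, est_error_rate = 0,
                    est_per_gene = 2)
  sim <- simulate_targets(cfg)
  ests <- simulate_ests(sim, cfg)
  res <- mine_snps(sim$flics, ests$ests)
  # every EST should land on its own gene
  got <- res$est_report$accession[match(ests$sources$est_id,
                                        res$est_report$est_id)]
  expect_identical(got, ests$sources$gene)
})

test_that("repeat masking flags homopolymers and short tandem repeats", {
  m <- mask_repeats("ATTTTTA")             # 5-run of T
  expect_identical(which(m), 2:6)
  m <- mask_repeats("AACACACAGT")          # AC x 3 from pos 2, CA x 3 from pos 3
  expect_identical(which(m), 2:8)
  m <- mask_repeats("GACTACTACTG")         # ACT x 3
  expect_true(all(m[2:10]))
  expect_false(any(mask_repeats("ACGTACGGTCA")))
})
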