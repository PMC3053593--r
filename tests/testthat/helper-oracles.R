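# Independent oracles used across test files. These deliberately avoid the
# package's internal code paths: repeats are found by explicit scanning,
# the mining filters are re-applied column by column, the heterozygote
# distribution is sampled by allele pairing, and the chi-square is the
# hand-written Pearson formula.

# explicit simple-repeat scan: homopolymers >= hp_min, di-/tri-nt tandem
# repeats >= min_units units; returns 1-based masked positions
oracle_repeat_positions <- function(seq, hp_min = 5L, min_units = 3L) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  masked <- logical(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && b[j + 1L] == b[i]) j <- j + 1L
    if (j - i + 1L >= hp_min) masked[i:j] <- TRUE
    i <- j + 1L
  }
  for (u in 2:3) {
    for (s in seq_len(n - u * min_units + 1L)) {
      unit <- b[s:(s + u - 1L)]
      k <- 0L
      while (s + (k + 1L) * u - 1L <= n &&
             all(b[(s + k * u):(s + (k + 1L) * u - 1L)] == unit)) k <- k + 1L
      if (k >= min_units) masked[s:(s + k * u - 1L)] <- TRUE
    }
  }
  which(masked)
}

# brute-force candidate mining: walk each alignment column by column and
# apply every filter independently of mine_candidates' implementation
oracle_mine <- function(alignments, flic_seq, params = mining_params()) {
  rep_pos <- oracle_repeat_positions(flic_seq, params$homopolymer_min,
                                     params$repeat_min_units)
  per_est <- list()
  for (aln in alignments) {
    pb <- strsplit(aln$aligned_est, "")[[1]]
    sb <- strsplit(aln$aligned_flic, "")[[1]]
    ncols <- length(pb)
    is_diff <- pb != sb | pb == "-" | sb == "-"
    # per-column coordinates
    est_before <- aln$est_span[1] + c(0L, cumsum(pb != "-"))[seq_len(ncols)]
    flic_before <- aln$flic_span[1] + c(0L, cumsum(sb != "-"))[seq_len(ncols)]
    # whole-EST classifications
    identity_ok <- mean(pb == sb & pb != "-") >= params$identity_min
    long_enough <- ncols >= params$min_aln_len
    w <- min(100L, ncols)
    paralog <- FALSE
    for (s in seq_len(ncols - w + 1L))
      if (sum(is_diff[s:(s + w - 1L)]) > params$max_diffs_per_100bp) paralog <- TRUE
    for (k in which(is_diff)) {
      fp <- if (sb[k] != "-") flic_before[k] else max(flic_before[k] - 1L, 0L)
      ep <- est_before[k]
      status <-
        if (!identity_ok || !long_enough) "rejected_identity"
        else if (paralog) "rejected_paralog_est"
        else if (ep < params$end_trim || ep >= aln$est_len - params$end_trim)
          "rejected_end_trim"
        else if ((fp + 1L) %in% rep_pos) "rejected_repeat"
        else "candidate"
      per_est[[length(per_est) + 1L]] <- data.frame(
        pos = fp, flic_allele = sb[k], est_allele = pb[k],
        status = status, est_id = aln$est_id)
    }
  }
  if (!length(per_est))
    return(data.frame(pos = integer(0), flic_allele = character(0),
                      est_allele = character(0), status = character(0)))
  d <- do.call(rbind, per_est)
  rank <- c(candidate = 1, rejected_end_trim = 2, rejected_repeat = 3,
            rejected_paralog_est = 4, rejected_identity = 5)
  keys <- split(d, paste(d$pos, d$flic_allele, d$est_allele, sep = "\r"))
  out <- do.call(rbind, lapply(keys, function(g) {
    st <- if (any(g$status == "candidate")) "candidate"
          else names(rank)[min(rank[g$status])]
    data.frame(pos = g$pos[1], flic_allele = g$flic_allele[1],
               est_allele = g$est_allele[1], status = st)
  }))
  out <- out[order(out$pos, out$est_allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Monte-Carlo oracle for the conditional heterozygote-excess probability:
# pair the 2n allele copies at random and count heterozygous pairs
oracle_het_excess_mc <- function(hom_ref, het, hom_alt, B = 2e5) {
  n <- hom_ref + het + hom_alt
  alleles <- c(rep(0L, 2L * hom_ref + het), rep(1L, 2L * hom_alt + het))
  hits <- 0L
  for (b in seq_len(B)) {
    perm <- sample(alleles)
    h <- sum(perm[seq(1L, 2L * n, 2L)] != perm[seq(2L, 2L * n, 2L)])
    if (h >= het) hits <- hits + 1L
  }
  hits / B
}

# exact probability that a planted bi-allelic site (minor allele frequency
# maf, panel size n) ends up validated by the carrier + PSV rules, by
# enumeration of the multinomial genotype-count distribution
oracle_validation_probability <- function(maf, n = 10L) {
  q <- maf
  pr <- 0
  for (i in 0:n) for (j in 0:(n - i)) {
    k <- n - i - j               # i hom-ref, j het, k hom-alt
    w <- exp(lfactorial(n) - lfactorial(i) - lfactorial(j) - lfactorial(k)) *
      ((1 - q)^2)^i * (2 * q * (1 - q))^j * (q^2)^k
    # site is emitted only if both alleles are seen in the panel
    if (!(j > 0 || (i > 0 && k > 0))) next
    ref_ct <- 2L * i + j; alt_ct <- 2L * k + j
    carriers <- if (alt_ct <= ref_ct) j + k else i + j
    if (j == n) next             # all-heterozygote pattern: PSV-excluded
    if (carriers >= 2L) pr <- pr + w
  }
  pr
}

# hand-written Pearson chi-square on a 2x2 table, no correction
oracle_pearson_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# translate a codon with the standard genetic code, by table lookup local
# to the tests
oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# build a tiny panel object from raw consensus strings
make_panel <- function(calls, amplicon = "AMP1", ref = NULL, ext = NULL) {
  panel_genotypes(amplicon, sprintf("i%02d", seq_along(calls)), calls,
                  extension_calls = ext, ref = ref)
}
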