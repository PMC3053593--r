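# Summary statistics of a discovery run: per-stage success rates,
# polymorphism density, the 2x2 method comparison, and the all-heterozygote
# Hardy-Weinberg probability underlying the PSV exclusion rule.

#' Per-stage counts of a discovery run
#'
#' The pipeline is monotone: genes with a discovered SNP <= fragments that
#' yielded a SNP <= fragments passing initial PCR/sequencing <= genes
#' tested (and <= candidates found, for the in silico method).
#'
#' @param method `"utr_primed"` or `"insilico"`.
#' @param genes_tested number of target genes entered.
#' @param candidates_found in silico only: candidate SNPs mined.
#' @param initial_pcr_pass fragments passing the initial PCR + sequencing
#'   screen.
#' @param snps_discovered_fragments fragments in which at least one SNP or
#'   DIP was validated.
#' @param genes_with_snp genes with at least one validated polymorphism.
#' @return list of class `stage_counts`.
#' @export
stage_counts <- function(method = c("utr_primed", "insilico"),
                         genes_tested, candidates_found = NA_integer_,
                         initial_pcr_pass, snps_discovered_fragments,
                         genes_with_snp) {
  method <- match.arg(method)
  x <- list(method = method, genes_tested = as.integer(genes_tested),
            candidates_found = as.integer(candidates_found),
            initial_pcr_pass = as.integer(initial_pcr_pass),
            snps_discovered_fragments = as.integer(snps_discovered_fragments),
            genes_with_snp = as.integer(genes_with_snp))
  if (x$genes_with_snp > x$genes_tested ||
      x$snps_discovered_fragments > x$initial_pcr_pass)
    stop("stage counts must be monotone along the pipeline")
  if (method == "insilico" && !is.na(x$candidates_found) &&
      x$initial_pcr_pass > x$candidates_found)
    stop("initial PCR passes cannot exceed candidates for the in silico method")
  structure(x, class = "stage_counts")
}

rate_entry <- function(num, den) {
  if (is.na(den) || den == 0L)
    return(list(rate = NA_real_, display = "-", fraction = sprintf("%s/%s", num, den)))
  r <- round_half_up(num / den, 2)
  list(rate = r, display = sprintf("%.2f (%d/%d)", r, num, den),
       fraction = sprintf("%d/%d", num, den))
}

#' Per-stage success rates
#'
#' Each rate is numerator/denominator rounded half-up to two decimals and
#' reported with its fraction. The in silico initial-PCR rate is computed
#' against candidates; the UTR-primed one against genes. A zero or missing
#' denominator is reported as `"-"`.
#'
#' @param counts a [stage_counts()].
#' @return data frame with columns `stage`, `numerator`, `denominator`,
#'   `rate`, `display`.
#' @export
success_rates <- function(counts) {
  stopifnot(inherits(counts, "stage_counts"))
  rows <- list()
  add <- function(stage, num, den) {
    e <- rate_entry(num, den)
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, numerator = num, denominator = den,
      rate = e$rate, display = e$display)
  }
  if (counts$method == "insilico") {
    add("candidate_rate", counts$candidates_found, counts$genes_tested)
    add("initial_pcr_rate", counts$initial_pcr_pass, counts$candidates_found)
  } else {
    add("initial_pcr_rate", counts$initial_pcr_pass, counts$genes_tested)
  }
  add("discovery_rate", counts$snps_discovered_fragments, counts$initial_pcr_pass)
  add("overall_success_rate", counts$genes_with_snp, counts$genes_tested)
  do.call(rbind, rows)
}

#' Conversion rate of in silico mining
#'
#' Fraction of genotype-able putative SNPs confirmed polymorphic, as a
#' percentage rounded half-up to the nearest integer.
#'
#' @param n_confirmed validated SNPs.
#' @param n_genotyped putative-SNP fragments that could be genotyped.
#' @return list with `rate` (fraction) and `percent`.
#' @export
conversion_rate <- function(n_confirmed, n_genotyped) {
  stopifnot(n_genotyped > 0)
  r <- n_confirmed / n_genotyped
  list(rate = r, percent = round_half_up(100 * r, 0))
}

#' Polymorphism density
#'
#' Base pairs scanned per bi-allelic polymorphism (SNPs + DIPs), raw and
#' rounded half-up to the nearest 10 bp.
#'
#' @param total_bp_scanned total bases scanned.
#' @param n_snps,n_dips polymorphism counts.
#' @return list with `raw` and `rounded`; both `NA` (with a message in
#'   `note`) when no polymorphisms were found.
#' @export
snp_density <- function(total_bp_scanned, n_snps, n_dips = 0L) {
  stopifnot(total_bp_scanned > 0, n_snps >= 0, n_dips >= 0)
  k <- n_snps + n_dips
  if (k == 0L)
    return(list(raw = NA_real_, rounded = NA_real_,
                note = "no polymorphisms: density undefined"))
  raw <- total_bp_scanned / k
  list(raw = raw, rounded = round_to_nearest(raw, 10), note = NULL)
}

#' 2x2 contingency-table comparison of two discovery methods
#'
#' Pearson chi-square without continuity correction (default report), with
#' the Yates-corrected statistic and Fisher's exact test (two-sided and
#' one-sided) as companions.
#'
#' @param a,b first row (e.g. successes/failures of method 1).
#' @param c,d second row.
#' @return list with `statistic`, `df`, `p_value` (uncorrected Pearson),
#'   `yates` (statistic + p), `fisher` (two-sided and one-sided
#'   `greater` p-values), and the table.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0))
  m <- matrix(counts, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("2x2 test requires positive margins")
  raw <- stats::chisq.test(m, correct = FALSE)
  yat <- stats::chisq.test(m, correct = TRUE)
  f2 <- stats::fisher.test(m, alternative = "two.sided")
  f1 <- stats::fisher.test(m, alternative = "greater")
  list(statistic = unname(raw$statistic), df = 1L,
       p_value = unname(raw$p.value),
       yates = list(statistic = unname(yat$statistic),
                    p_value = unname(yat$p.value)),
       fisher = list(p_two_sided = f2$p.value, p_greater = f1$p.value),
       table = m)
}

#' Probability that every panel individual is heterozygous
#'
#' Under Hardy-Weinberg equilibrium at allele frequency `p`, the
#' probability that all `n` diploid individuals are heterozygous is
#' (2p(1-p))^n, maximized at p = 0.5. With n = 10 the maximum is
#' 0.5^10 = 0.0009765625 (0.001 at three decimals): the significance level
#' of excluding an all-heterozygote site as a paralogous sequence variant.
#'
#' @param n panel size (>= 1).
#' @param p allele frequency in \[0, 1\].
#' @return probability.
#' @export
all_het_probability <- function(n, p) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  (2 * p * (1 - p))^n
}

#' Assemble a run report mirroring the per-stage rate table
#'
#' @param counts_list list of [stage_counts()] (one per method).
#' @param density optional [snp_density()] result.
#' @param path optional base path; writes `<path>.tsv` and `<path>.md`.
#' @return data frame of the combined rate table.
#' @export
run_report <- function(counts_list, density = NULL, path = NULL) {
  if (inherits(counts_list, "stage_counts")) counts_list <- list(counts_list)
  tab <- do.call(rbind, lapply(counts_list, function(cc) {
    r <- success_rates(cc)
    r$method <- cc$method
    r
  }))
  tab <- tab[, c("method", "stage", "numerator", "denominator", "rate", "display")]
  if (!is.null(path)) {
    utils::write.table(tab, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    md <- c("| method | stage | rate |", "|---|---|---|",
            sprintf("| %s | %s | %s |", tab$method, tab$stage, tab$display))
    if (!is.null(density) && !is.na(density$raw))
      md <- c(md, "",
              sprintf("One bi-allelic polymorphism per %.1f bp (~%d bp).",
                      density$raw, as.integer(density$rounded)))
    writeLines(md, paste0(path, ".md"))
  }
  tab
}
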