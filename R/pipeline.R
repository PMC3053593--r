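# High-level pipeline wrappers tying the stages together.

#' Genotype a set of 3'UTR amplicon panels against their targets
#'
#' Applies [genotype_amplicon()] to each panel, annotating against the
#' matching transcript with the 3'UTR offset (panels are assumed aligned
#' to the 3'UTR, as produced by [simulate_panel()]).
#'
#' @param panels named list of [panel_genotypes()] keyed by accession.
#' @param flics named list of [flic_record()] objects.
#' @param qc_threshold multi-heterozygote QC threshold (default 5).
#' @param run_qc logical; skip the two-individual screen with `FALSE`.
#' @return list with `results` (per amplicon: `qc` + `variants`),
#'   `variants` (flat list of all `validated_variant`s) and `summary`
#'   (data frame from [variants_table()]).
#' @export
genotype_panels <- function(panels, flics, qc_threshold = 5L, run_qc = TRUE) {
  results <- list()
  for (acc in names(panels)) {
    flic <- flics[[acc]]
    off <- if (!is.null(flic)) flic$utr3[["start"]] else 0L
    results[[acc]] <- genotype_amplicon(panels[[acc]], flic = flic,
                                        offset = off,
                                        qc_threshold = qc_threshold,
                                        run_qc = run_qc)
  }
  variants <- unlist(lapply(results, `[[`, "variants"), recursive = FALSE)
  list(results = results, variants = variants,
       summary = variants_table(variants))
}

#' Count discovery outcomes of a genotyped panel set
#'
#' @param genotyped result of [genotype_panels()].
#' @param method method label for the [stage_counts()].
#' @param genes_tested,candidates_found totals of the earlier stages (the
#'   simulated runs have no wet-lab attrition, so `genes_tested` defaults
#'   to the number of panels).
#' @return a [stage_counts()].
#' @export
tally_discovery <- function(genotyped, method = "utr_primed",
                            genes_tested = length(genotyped$results),
                            candidates_found = NA_integer_) {
  per_amp <- vapply(genotyped$results, function(r)
    sum(vapply(r$variants, function(v) v$status == "validated", TRUE)) > 0L,
    TRUE)
  passed <- vapply(genotyped$results, function(r)
    is.null(r$qc) || r$qc$verdict == "pass", TRUE)
  stage_counts(method = method, genes_tested = genes_tested,
               candidates_found = candidates_found,
               initial_pcr_pass = sum(passed),
               snps_discovered_fragments = sum(per_amp),
               genes_with_snp = sum(per_amp))
}
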