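# Panel genotyping: amplicon QC, variant-site calling from per-individual
# IUPAC consensus sequences, SNP/DIP validation rules, and exclusion of
# paralogous sequence variants (PSVs).
#
# Validation rules mirror the wet-lab protocol: an amplicon is dropped from
# genotyping when the two-individual screen shows five or more heterozygous
# sites (a co-amplification signature); a candidate site is approved only
# when the rare variant is carried by at least two individuals (a single
# carrier triggers re-typing in five extension individuals and re-testing
# on the pooled panel); and a site heterozygous in every individual is
# excluded as a PSV, since a fixed difference between co-amplified paralogs
# masquerades as a heterozygote in everyone, while a true SNP segregates
# according to Hardy-Weinberg expectations.

#' Screen an amplicon for multi-heterozygote co-amplification
#'
#' Counts heterozygous columns pooled over the screen individuals (union
#' of heterozygous columns). A count at or above `threshold` fails the
#' amplicon; all-N screen sequences fail on quality.
#'
#' @param panel a [panel_genotypes()].
#' @param screen_ids individuals used for the screen (default: the first
#'   two, mirroring the two-individual initial PCR screen).
#' @param threshold heterozygous-site count that fails the amplicon
#'   (default 5, "five or more").
#' @return list of class `amplicon_qc`: `amplicon_id`,
#'   `screen_individuals`, `het_site_count`, `verdict` (`pass`,
#'   `fail_multi_het`, `fail_quality`).
#' @export
qc_amplicon <- function(panel, screen_ids = NULL, threshold = 5L) {
  stopifnot(inherits(panel, "panel_genotypes"))
  if (is.null(screen_ids)) screen_ids <- utils::head(panel$individuals, 2L)
  if (length(screen_ids) == 0L) stop("empty screen set")
  if (!all(screen_ids %in% panel$individuals))
    stop("screen ids not in panel: ",
         paste(setdiff(screen_ids, panel$individuals), collapse = ", "))
  calls <- panel$calls[screen_ids]
  if (all(grepl("^N+$", calls))) {
    verdict <- "fail_quality"; het <- NA_integer_
  } else {
    het_cols <- logical(panel$width)
    for (s in calls) {
      b <- chars(s)
      het_cols <- het_cols | b %in% c(names(.IUPAC2), letters)
    }
    het <- sum(het_cols)
    verdict <- if (het >= threshold) "fail_multi_het" else "pass"
  }
  structure(list(amplicon_id = panel$amplicon_id, screen_individuals = screen_ids,
                 het_site_count = het, verdict = verdict),
            class = "amplicon_qc")
}

# column chars -> per-individual genotypes; returns list(genotypes = list
# of c(a1,a2) or NULL, alleles = distinct alleles observed)
decode_column <- function(col_chars) {
  g <- lapply(col_chars, decode_genotype)
  alleles <- sort(unique(unlist(g)))
  list(genotypes = g, alleles = alleles)
}

# build a variant_site from per-individual genotypes at one column
site_from_genotypes <- function(amplicon_id, position, genotypes, individuals,
                                ref_hint = NULL) {
  alleles <- sort(unique(unlist(genotypes)))
  stopifnot(length(alleles) == 2L)
  ref <- if (!is.null(ref_hint) && ref_hint %in% alleles) ref_hint
         else {
           counts <- table(factor(unlist(genotypes), levels = alleles))
           if (counts[1] >= counts[2]) alleles[1] else alleles[2]
         }
  alt <- setdiff(alleles, ref)
  called <- !vapply(genotypes, is.null, TRUE)
  gsum <- vapply(genotypes[called], function(g) sum(g == alt), 0L)
  hom_ref <- sum(gsum == 0L); het <- sum(gsum == 1L); hom_alt <- sum(gsum == 2L)
  ref_count <- 2L * hom_ref + het
  alt_count <- 2L * hom_alt + het
  minor <- if (alt_count <= ref_count) "alt" else "ref"   # tie: alt is minor
  carriers <- if (minor == "alt") het + hom_alt else het + hom_ref
  gt <- rep("./.", length(genotypes))
  gt[called] <- c("0/0", "0/1", "1/1")[gsum + 1L]
  names(gt) <- individuals
  structure(
    list(amplicon_id = amplicon_id, position = as.integer(position),
         ref_allele = ref, alt_allele = alt,
         site_class = if ("-" %in% alleles) "DIP" else "SNP",
         genotype_counts = c(hom_ref = hom_ref, het = het, hom_alt = hom_alt),
         n_called = sum(called), carriers_of_rare = carriers,
         minor = minor, genotypes = gt, status = "unassessed"),
    class = "variant_site"
  )
}

#' @export
print.variant_site <- function(x, ...) {
  cat("<variant_site> ", x$amplicon_id, " pos ", x$position + 1L, " ",
      x$ref_allele, ">", x$alt_allele, " [", x$site_class, "] counts (",
      paste(x$genotype_counts, collapse = ","), ") carriers ",
      x$carriers_of_rare, " status ", x$status, "\n", sep = "")
  invisible(x)
}

#' Call variant sites from panel consensus sequences
#'
#' Decodes each individual's IUPAC call per aligned column and emits a
#' `variant_site` for every column where at least two distinct alleles
#' segregate in the panel. N calls are missing data, not alleles. Columns
#' with more than two alleles are flagged and excluded from the bi-allelic
#' pipeline (attribute `multi_allelic`, 0-based positions).
#'
#' @param panel a [panel_genotypes()].
#' @return list of `variant_site` objects with attribute `multi_allelic`.
#' @export
call_sites <- function(panel) {
  stopifnot(inherits(panel, "panel_genotypes"))
  mat <- do.call(rbind, strsplit(unname(panel$calls), "", fixed = TRUE))
  ref_chars <- if (!is.null(panel$ref)) chars(panel$ref) else NULL
  sites <- list()
  multi <- integer(0)
  for (j in seq_len(panel$width)) {
    col <- decode_column(mat[, j])
    n_all <- length(col$alleles)
    if (n_all < 2L) next
    if (n_all > 2L) { multi <- c(multi, j - 1L); next }
    sites[[length(sites) + 1L]] <- site_from_genotypes(
      panel$amplicon_id, j - 1L, col$genotypes, panel$individuals,
      ref_hint = if (!is.null(ref_chars)) ref_chars[j] else NULL)
  }
  attr(sites, "multi_allelic") <- multi
  sites
}

#' Exact heterozygote-excess probability (Levene conditional)
#'
#' Probability, conditional on the observed allele counts, of drawing a
#' genotype table with at least the observed number of heterozygotes when
#' the 2n allele copies are paired at random (Hardy-Weinberg null). This
#' generalizes the all-heterozygote PSV rule to partial excess.
#'
#' @param hom_ref,het,hom_alt observed genotype counts.
#' @return upper-tail probability `P(het' >= het | allele counts)`.
#' @export
het_excess_exact <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  if (n == 0L) stop("no called individuals")
  nA <- 2L * hom_ref + het
  na <- 2L * hom_alt + het
  log_p <- function(h) {
    d <- (nA - h) / 2; r <- (na - h) / 2
    if (d < 0 || r < 0 || d != floor(d) || r != floor(r)) return(-Inf)
    lfactorial(n) - lfactorial(d) - lfactorial(h) - lfactorial(r) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }
  hs <- seq(het, min(nA, na))
  sum(exp(vapply(hs, log_p, 0)))
}

#' Paralogous-sequence-variant check
#'
#' A site is flagged as a PSV if and only if every called individual is
#' heterozygous. Under Hardy-Weinberg equilibrium the probability of an
#' all-heterozygote panel is (2pq)^n, maximized at p = q = 0.5; with
#' n = 10 that maximum is 0.5^10 = 0.000977, the significance of the
#' exclusion rule. The exact heterozygote-excess probability
#' ([het_excess_exact()]) is reported alongside for non-total excess but
#' does not auto-exclude.
#'
#' @param site a `variant_site`.
#' @param n number of called individuals (defaults to the site's).
#' @return list: `is_psv`, `all_het_probability` ((2pq)^n at the
#'   maximizing p = 0.5), `all_het_probability_observed` (at observed
#'   allele frequencies), `het_excess_p`, `n`, `low_power` (TRUE when
#'   fewer than 6 called individuals).
#' @export
psv_check <- function(site, n = site$n_called) {
  stopifnot(inherits(site, "variant_site"))
  if (n == 0L) stop("no called individuals")
  if (n < 2L) stop("PSV check requires at least 2 called individuals")
  gc <- site$genotype_counts
  p_hat <- (2 * gc[["hom_ref"]] + gc[["het"]]) / (2 * n)
  list(is_psv = gc[["het"]] == n,
       all_het_probability = 0.5^n * 2^n * 0.5^n,    # (2*0.5*0.5)^n
       all_het_probability_observed = (2 * p_hat * (1 - p_hat))^n,
       het_excess_p = het_excess_exact(gc[["hom_ref"]], gc[["het"]],
                                       gc[["hom_alt"]]),
       n = n, low_power = n < 6L)
}

#' Validate a variant site against the carrier and PSV rules
#'
#' Approval requires the rare variant in at least two individuals and a
#' non-PSV genotype pattern. A single carrier requests extended typing;
#' when extension calls are supplied (consensus characters at this column
#' for the extra individuals, or a [panel_genotypes()] whose
#' `extension_calls` cover the column) the rules are re-tested on the
#' pooled panel.
#'
#' @param site a `variant_site` from [call_sites()].
#' @param extension optional: character vector of consensus characters for
#'   extension individuals at this column, or the `panel_genotypes` the
#'   site came from.
#' @return object of class `validated_variant`: the site plus allele
#'   frequencies `p`/`q`, `all_het_probability`, `het_excess_p`, `status`
#'   (`validated`, `unconfirmed_single_carrier`, `psv_excluded`,
#'   `monomorphic`), and `extension_requested`/`extension_used`.
#' @export
validate_variant <- function(site, extension = NULL) {
  stopifnot(inherits(site, "variant_site"))
  ext_chars <- NULL
  if (inherits(extension, "panel_genotypes")) {
    if (!is.null(extension$extension_calls))
      ext_chars <- vapply(extension$extension_calls, substr,
                          "", site$position + 1L, site$position + 1L)
  } else if (!is.null(extension)) {
    ext_chars <- as.character(extension)
  }

  evaluate <- function(s, used_ext) {
    chk <- psv_check(s)
    status <-
      if (chk$is_psv) "psv_excluded"
      else if (s$carriers_of_rare >= 2L) "validated"
      else if (s$carriers_of_rare == 1L) "unconfirmed_single_carrier"
      else "monomorphic"
    gc <- s$genotype_counts
    p <- (2 * gc[["hom_ref"]] + gc[["het"]]) / (2 * s$n_called)
    out <- structure(
      c(unclass(s),
        list(p = p, q = 1 - p,
             all_het_probability = chk$all_het_probability,
             all_het_probability_observed = chk$all_het_probability_observed,
             het_excess_p = chk$het_excess_p,
             low_power = chk$low_power,
             extension_used = used_ext,
             extension_requested = FALSE)),
      class = c("validated_variant", "variant_site"))
    out$status <- status
    out
  }

  v <- evaluate(site, used_ext = FALSE)
  if (v$status == "unconfirmed_single_carrier") {
    if (is.null(ext_chars)) {
      v$extension_requested <- TRUE
    } else {
      # pool the extension individuals and re-test every rule on the pooled set
      base_g <- lapply(unname(site$genotypes), function(s)
        switch(s, `0/0` = c(site$ref_allele, site$ref_allele),
               `0/1` = c(site$ref_allele, site$alt_allele),
               `1/1` = c(site$alt_allele, site$alt_allele), NULL))
      ext_g <- lapply(ext_chars, decode_genotype)
      pooled_alleles <- sort(unique(unlist(c(base_g, ext_g))))
      if (!all(pooled_alleles %in% c(site$ref_allele, site$alt_allele)))
        stop("extension calls introduce a third allele at position ",
             site$position + 1L)
      ids <- c(names(site$genotypes),
               names(ext_chars) %||% paste0("ext", seq_along(ext_g)))
      pooled <- site_from_genotypes(site$amplicon_id, site$position,
                                    c(base_g, ext_g), ids,
                                    ref_hint = site$ref_allele)
      v <- evaluate(pooled, used_ext = TRUE)
    }
  }
  v
}

#' Annotate a variant's region and coding effect
#'
#' @param position 0-based transcript position of the variant.
#' @param ref_allele,alt_allele the two alleles (`-` for a deletion).
#' @param record the [flic_record()] the variant lies in.
#' @return list with `region` (`CDS`, `UTR3`, `unknown`) and `cds_effect`
#'   (`synonymous`, `missense`, `nonsense`, `frameshift`,
#'   `not_applicable`). CDS SNPs are classified by translating the codon
#'   with each allele under the standard genetic code; CDS DIPs are
#'   frameshifts.
#' @export
annotate_region <- function(position, ref_allele, alt_allele, record) {
  stopifnot(inherits(record, "flic_record"))
  if (position < 0L || position >= nchar(record$sequence))
    stop("position ", position, " outside record ", record$accession)
  in_cds <- !is.null(record$cds) && interval_contains(record$cds, position)
  region <- if (in_cds) "CDS"
            else if (interval_contains(record$utr3, position)) "UTR3"
            else "unknown"
  if (region != "CDS")
    return(list(region = region, cds_effect = "not_applicable"))
  if (ref_allele == "-" || alt_allele == "-")
    return(list(region = "CDS", cds_effect = "frameshift"))
  off <- position - record$cds[["start"]]
  codon_start <- record$cds[["start"]] + (off %/% 3L) * 3L
  if (codon_start + 3L > record$cds[["end"]])
    return(list(region = "CDS", cds_effect = "not_applicable"))  # partial codon
  codon <- substr(record$sequence, codon_start + 1L, codon_start + 3L)
  frame <- off %% 3L
  ref_codon <- codon
  substr(ref_codon, frame + 1L, frame + 1L) <- ref_allele
  alt_codon <- codon
  substr(alt_codon, frame + 1L, frame + 1L) <- alt_allele
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[ref_codon]); aa_alt <- unname(code[alt_codon])
  effect <- if (aa_ref == aa_alt) "synonymous"
            else if (aa_alt == "*") "nonsense"
            else "missense"
  list(region = "CDS", cds_effect = effect)
}

#' Genotype one amplicon end to end
#'
#' Runs QC, site calling, validation (using the panel's extension calls
#' automatically for single-carrier sites), and optional region/effect
#' annotation against the source transcript.
#'
#' @param panel a [panel_genotypes()].
#' @param flic optional [flic_record()] for annotation.
#' @param offset 0-based transcript position of panel column 0 (e.g. the
#'   3'UTR start when the amplicon is the 3'UTR).
#' @param qc_threshold multi-heterozygote QC threshold (default 5).
#' @param run_qc logical; skip QC with `FALSE`.
#' @return list with `qc` and `variants` (list of `validated_variant`,
#'   each annotated with `region`/`cds_effect` when `flic` is supplied);
#'   `variants` is empty when QC fails.
#' @export
genotype_amplicon <- function(panel, flic = NULL, offset = 0L,
                              qc_threshold = 5L, run_qc = TRUE) {
  qc <- if (run_qc) qc_amplicon(panel, threshold = qc_threshold) else NULL
  if (!is.null(qc) && qc$verdict != "pass")
    return(list(qc = qc, variants = list()))
  sites <- call_sites(panel)
  variants <- lapply(sites, validate_variant, extension = panel)
  if (!is.null(flic)) {
    variants <- lapply(variants, function(v) {
      ann <- annotate_region(v$position + offset, v$ref_allele, v$alt_allele,
                             flic)
      v$region <- ann$region; v$cds_effect <- ann$cds_effect
      v
    })
  }
  list(qc = qc, variants = variants)
}
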