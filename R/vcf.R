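# Variant output: VCF 4.2 and TSV.
#
# CHROM is the FLIc accession and POS the 1-based transcript position.
# Deletion DIPs are left-anchored in the usual VCF way: REF carries the
# anchor base plus the deleted base, ALT the anchor base, and POS moves to
# the anchor.

vcf_info <- function(v) {
  sprintf("REGION=%s;EFFECT=%s;CARRIERS=%d;ALLHET_P=%.6g",
          v$region %||% "unknown", v$cds_effect %||% "not_applicable",
          v$carriers_of_rare, v$all_het_probability_observed)
}

# (pos0, ref, alt, template) -> list(pos0, ref, alt) in VCF representation
vcf_alleles <- function(pos0, ref, alt, template) {
  if (ref != "-" && alt != "-") return(list(pos0 = pos0, ref = ref, alt = alt))
  if (alt == "-") {           # deletion of the ref base
    if (pos0 > 0L) {
      anchor <- substr(template, pos0, pos0)
      list(pos0 = pos0 - 1L, ref = paste0(anchor, ref), alt = anchor)
    } else {                  # first base: right-anchor instead
      anchor <- substr(template, pos0 + 2L, pos0 + 2L)
      list(pos0 = pos0, ref = paste0(ref, anchor), alt = anchor)
    }
  } else {                    # insertion relative to the reference
    anchor <- if (pos0 > 0L) substr(template, pos0, pos0)
              else substr(template, 1L, 1L)
    list(pos0 = max(pos0 - 1L, 0L), ref = anchor, alt = paste0(anchor, ref))
  }
}

#' Write validated variants as VCF 4.2
#'
#' @param variants list of `validated_variant` objects (one amplicon or
#'   several; each needs `amplicon_id`, `position`, alleles, genotypes).
#' @param path output path.
#' @param templates named character vector of amplicon reference
#'   sequences (needed to anchor DIPs; plain SNPs work without).
#' @param offsets named integer vector: 0-based transcript position of
#'   each amplicon's column 0 (default 0).
#' @param chrom_ids optional named character vector mapping amplicon id to
#'   the CHROM value (default: the amplicon id itself).
#' @return invisibly, `path`.
#' @export
write_vcf <- function(variants, path, templates = NULL, offsets = NULL,
                      chrom_ids = NULL) {
  if (inherits(variants, "validated_variant")) variants <- list(variants)
  individuals <- if (length(variants)) names(variants[[1]]$genotypes) else character(0)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=utrsnp",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Transcript region (CDS/UTR3/unknown)\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect of the variant\">",
    "##INFO=<ID=CARRIERS,Number=1,Type=Integer,Description=\"Individuals carrying the rare allele\">",
    "##INFO=<ID=ALLHET_P,Number=1,Type=Float,Description=\"Hardy-Weinberg probability of the all-heterozygote pattern at observed allele frequencies\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individuals), collapse = "\t"))
  rows <- vapply(variants, function(v) {
    amp <- v$amplicon_id
    off <- if (!is.null(offsets) && amp %in% names(offsets)) offsets[[amp]] else 0L
    tpl <- if (!is.null(templates) && amp %in% names(templates)) templates[[amp]] else NULL
    pos0 <- v$position
    ref <- v$ref_allele; alt <- v$alt_allele
    if (ref == "-" || alt == "-") {
      if (is.null(tpl))
        stop("DIP at position ", pos0 + 1L, " needs a template to anchor")
      a <- vcf_alleles(pos0, ref, alt, tpl)
      pos0 <- a$pos0; ref <- a$ref; alt <- a$alt
    }
    chrom <- if (!is.null(chrom_ids) && amp %in% names(chrom_ids))
      chrom_ids[[amp]] else amp
    filter <- switch(v$status, validated = "PASS", psv_excluded = "PSV",
                     unconfirmed_single_carrier = "SINGLE_CARRIER",
                     monomorphic = "MONOMORPHIC", ".")
    paste(c(chrom, pos0 + off + 1L, ".", ref, alt, ".", filter, vcf_info(v),
            "GT", unname(v$genotypes)), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Tabulate validated variants as a data frame / TSV
#'
#' @param variants list of `validated_variant` objects.
#' @param path optional output TSV path.
#' @return data frame (1-based positions).
#' @export
variants_table <- function(variants, path = NULL) {
  if (inherits(variants, "validated_variant")) variants <- list(variants)
  df <- do.call(rbind, lapply(variants, function(v) {
    data.frame(amplicon_id = v$amplicon_id, position = v$position + 1L,
               ref = v$ref_allele, alt = v$alt_allele,
               class = v$site_class, status = v$status,
               hom_ref = v$genotype_counts[["hom_ref"]],
               het = v$genotype_counts[["het"]],
               hom_alt = v$genotype_counts[["hom_alt"]],
               carriers = v$carriers_of_rare,
               p = v$p, q = v$q,
               all_het_p = v$all_het_probability_observed,
               het_excess_p = v$het_excess_p,
               region = v$region %||% "unknown",
               cds_effect = v$cds_effect %||% "not_applicable")
  }))
  if (!is.null(df)) rownames(df) <- NULL
  if (!is.null(path) && !is.null(df))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
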