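# Diploid panel genotypes: one consensus sequence per individual per
# amplicon, pre-aligned to the amplicon reference. Heterozygous positions
# carry IUPAC ambiguity codes; '-' is a homozygous single-base deletion and
# a lowercase base a base/deletion heterozygote (artifact convention).

#' Construct panel genotypes for one amplicon
#'
#' @param amplicon_id character identifier of the amplicon (usually the
#'   FLIc accession).
#' @param individuals character vector of unique individual ids (panel size
#'   `n >= 2`; the discovery panel default in this pipeline is 10).
#' @param calls character vector (one consensus string per individual), all
#'   of identical length, aligned to the amplicon reference.
#' @param extension_calls optional named character vector of additional
#'   individuals (default 5 in the simulator) used when a rare variant seen
#'   in a single panel individual triggers extended typing.
#' @param ref optional amplicon reference sequence (same length as the
#'   calls); used for reference-allele assignment and VCF output.
#' @return an object of class `panel_genotypes`.
#' @export
panel_genotypes <- function(amplicon_id, individuals, calls,
                            extension_calls = NULL, ref = NULL) {
  stopifnot(is.character(amplicon_id), length(amplicon_id) == 1L)
  individuals <- as.character(individuals)
  calls <- as.character(calls)
  if (length(individuals) != length(calls))
    stop("one consensus string per individual required")
  if (length(individuals) < 2L) stop("panel size must be at least 2")
  if (anyDuplicated(individuals)) stop("individual ids must be unique")
  w <- unique(nchar(calls))
  if (length(w) != 1L)
    stop("amplicon ", amplicon_id,
         ": consensus strings have unequal lengths (", paste(w, collapse = ","), ")")
  if (!is.null(extension_calls)) {
    extension_calls <- stats::setNames(as.character(extension_calls),
                                       names(extension_calls))
    if (is.null(names(extension_calls)) || any(!nzchar(names(extension_calls))))
      stop("extension_calls must be named by individual id")
    if (any(nchar(extension_calls) != w))
      stop("extension calls must match the amplicon alignment width")
    if (any(names(extension_calls) %in% individuals))
      stop("extension individuals overlap the panel")
  }
  if (!is.null(ref) && nchar(ref) != w)
    stop("reference length does not match alignment width")
  names(calls) <- individuals
  structure(
    list(amplicon_id = amplicon_id, individuals = individuals, calls = calls,
         extension_calls = extension_calls, ref = ref, width = w),
    class = "panel_genotypes"
  )
}

#' @export
print.panel_genotypes <- function(x, ...) {
  cat("<panel_genotypes> ", x$amplicon_id, ": ", length(x$individuals),
      " individuals x ", x$width, " aligned columns",
      if (!is.null(x$extension_calls))
        paste0(" (+", length(x$extension_calls), " extension)"),
      "\n", sep = "")
  invisible(x)
}

#' Read panel consensus sequences from FASTA
#'
#' FASTA ids follow the dialect `<amplicon_id>|<individual_id>`. The file is
#' read case-sensitively (lowercase bases are base/deletion heterozygotes).
#' Individuals whose id starts with `ext:` are treated as extension-panel
#' individuals.
#'
#' @param path path to the panel FASTA.
#' @param refs optional named character vector of amplicon reference
#'   sequences.
#' @return named list of [panel_genotypes()], one per amplicon.
#' @export
read_panel <- function(path, refs = NULL) {
  seqs <- Biostrings::readBStringSet(path)   # BStringSet: preserves case
  ids <- sub("\\s.*$", "", names(seqs))
  parts <- strsplit(ids, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("panel FASTA ids must be '<amplicon_id>|<individual_id>'")
  amp <- vapply(parts, `[`, "", 1L)
  ind <- vapply(parts, `[`, "", 2L)
  out <- list()
  for (a in unique(amp)) {
    sel <- amp == a
    calls <- as.character(seqs[sel])
    names(calls) <- ind[sel]
    is_ext <- startsWith(names(calls), "ext:")
    ext <- NULL
    if (any(is_ext)) {
      ext <- calls[is_ext]
      names(ext) <- sub("^ext:", "", names(ext))
    }
    core <- calls[!is_ext]
    out[[a]] <- panel_genotypes(a, names(core), unname(core),
                                extension_calls = ext,
                                ref = if (!is.null(refs)) unname(refs[a]) else NULL)
  }
  out
}

#' Write panel genotypes to FASTA
#'
#' @param panels list of [panel_genotypes()] (or a single one).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_panel <- function(panels, path) {
  if (inherits(panels, "panel_genotypes")) panels <- list(panels)
  lines <- character(0)
  for (p in panels) {
    lines <- c(lines, rbind(paste0(">", p$amplicon_id, "|", p$individuals),
                            unname(p$calls)))
    if (!is.null(p$extension_calls))
      lines <- c(lines,
                 rbind(paste0(">", p$amplicon_id, "|ext:", names(p$extension_calls)),
                       unname(p$extension_calls)))
  }
  writeLines(lines, path)
  invisible(path)
}
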