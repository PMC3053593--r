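# Full-length cDNA (FLIc) records: the SNP-discovery targets.
#
# A FLIc is a transcript sequenced end-to-end, annotated with its coding
# sequence (CDS) and complete 3' untranslated region (3'UTR). The 3'UTR is
# the discovery target of the UTR-primed method: weak conservation gives it
# both a higher polymorphism density and stronger divergence between
# paralogs than the CDS.

#' Construct an annotated full-length cDNA record
#'
#' @param accession character identifier (e.g. a GenBank accession).
#' @param sequence nucleotide string; normalized to uppercase; only
#'   `A C G T N` permitted.
#' @param utr3 [interval()] of the 3'UTR on the transcript (0-based
#'   half-open).
#' @param cds [interval()] of the coding sequence, or `NULL` if the CDS is
#'   not annotated.
#' @param complete_cds logical; whether the CDS annotation covers the
#'   complete coding sequence.
#' @return an object of class `flic_record`.
#' @export
flic_record <- function(accession, sequence, utr3, cds = NULL,
                        complete_cds = !is.null(cds)) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  sequence <- toupper(as.character(sequence))
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad))
    stop("record ", accession, ": sequence contains non-ACGTN characters: ",
         paste(unique(chars(bad)), collapse = ""))
  L <- nchar(sequence)
  if (!inherits(utr3, "interval")) utr3 <- interval(utr3[1], utr3[2])
  if (interval_len(utr3) == 0L)
    stop("record ", accession, ": empty 3'UTR interval")
  if (utr3[["start"]] < 0L || utr3[["end"]] > L)
    stop("record ", accession, ": 3'UTR interval [", utr3[["start"]], ", ",
         utr3[["end"]], ") outside sequence of length ", L)
  if (!is.null(cds)) {
    if (!inherits(cds, "interval")) cds <- interval(cds[1], cds[2])
    if (cds[["start"]] < 0L || cds[["end"]] > L)
      stop("record ", accession, ": CDS interval outside sequence")
    if (interval_overlaps(cds, utr3))
      stop("record ", accession, ": CDS and 3'UTR overlap")
    if (cds[["end"]] > utr3[["start"]])
      stop("record ", accession, ": 3'UTR must follow the CDS on the transcript")
  }
  structure(
    list(accession = accession, sequence = sequence, cds = cds, utr3 = utr3,
         complete_cds = isTRUE(complete_cds)),
    class = "flic_record"
  )
}

#' @export
print.flic_record <- function(x, ...) {
  cat("<flic_record> ", x$accession, ": ", nchar(x$sequence), " nt",
      if (!is.null(x$cds))
        sprintf("; CDS [%d,%d)%s", x$cds[["start"]], x$cds[["end"]],
                if (x$complete_cds) " (complete)" else ""),
      sprintf("; 3'UTR [%d,%d)", x$utr3[["start"]], x$utr3[["end"]]),
      "\n", sep = "")
  invisible(x)
}

#' Read annotated FLIc records from FASTA plus an annotation table
#'
#' The annotation table is TSV with header columns `accession`,
#' `cds_start`, `cds_end`, `utr3_start`, `utr3_end`, all coordinates
#' 1-based inclusive (GenBank convention); empty/NA CDS fields mean the CDS
#' is not annotated. Coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' Records failing validation are reported in the `failures` attribute
#' (a data frame of accession + message), never silently dropped.
#'
#' @param fasta_path path to a multi-record FASTA of transcript sequences.
#' @param annotation_path path to the TSV annotation table.
#' @param reverse_complement logical; reverse-complement sequences on input
#'   (off by default: FLIcs are sense-strand by construction).
#' @return named list of [flic_record()] objects, with attribute
#'   `failures`.
#' @export
read_flics <- function(fasta_path, annotation_path, reverse_complement = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (reverse_complement) seqs <- Biostrings::reverseComplement(seqs)
  # FASTA ids may carry descriptions after whitespace
  ids <- sub("\\s.*$", "", names(seqs))
  annot <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("accession", "cds_start", "cds_end", "utr3_start", "utr3_end")
  if (!all(need %in% names(annot)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))

  records <- list()
  failures <- data.frame(accession = character(0), message = character(0))
  for (i in seq_along(seqs)) {
    acc <- ids[i]
    row <- annot[annot$accession == acc, , drop = FALSE]
    res <- tryCatch({
      if (nrow(row) == 0L) stop("no annotation row for accession ", acc)
      if (nrow(row) > 1L) stop("duplicate annotation rows for accession ", acc)
      cds <- NULL
      if (!is.na(row$cds_start) && !is.na(row$cds_end))
        cds <- interval(row$cds_start - 1L, row$cds_end)
      flic_record(acc, as.character(seqs[[i]]),
                  utr3 = interval(row$utr3_start - 1L, row$utr3_end),
                  cds = cds)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(accession = acc, message = conditionMessage(res)))
    } else {
      records[[acc]] <- res
    }
  }
  if (nrow(failures) > 0L)
    warning(nrow(failures), " record(s) failed validation: ",
            paste(failures$accession, collapse = ", "))
  attr(records, "failures") <- failures
  records
}

#' Write FLIc records back to FASTA plus annotation TSV
#'
#' Inverse of [read_flics()]: coordinates are emitted 1-based inclusive.
#'
#' @param records list of [flic_record()] objects.
#' @param fasta_path,annotation_path output paths.
#' @return invisibly, the annotation data frame written.
#' @export
write_flics <- function(records, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "accession")
  Biostrings::writeXStringSet(seqs, fasta_path)
  annot <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      accession = r$accession,
      cds_start = if (is.null(r$cds)) NA_integer_ else r$cds[["start"]] + 1L,
      cds_end   = if (is.null(r$cds)) NA_integer_ else r$cds[["end"]],
      utr3_start = r$utr3[["start"]] + 1L,
      utr3_end   = r$utr3[["end"]]
    )
  }))
  utils::write.table(annot, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(annot)
}

#' Extract the 3'UTR subsequence with a transcript-coordinate map
#'
#' @param record a [flic_record()].
#' @return list with `sequence` (the 3'UTR subsequence), `offset` (transcript
#'   coordinate of subsequence position 0), and two exact coordinate-mapping
#'   functions `to_transcript(pos)` / `from_transcript(pos)` (0-based).
#' @export
extract_utr3 <- function(record) {
  stopifnot(inherits(record, "flic_record"))
  iv <- record$utr3
  if (is.null(iv) || interval_len(iv) == 0L)
    stop("record ", record$accession, ": absent or empty 3'UTR")
  off <- iv[["start"]]
  n <- interval_len(iv)
  list(
    sequence = subseq0(record$sequence, iv),
    offset = off,
    to_transcript = function(pos) {
      stopifnot(all(pos >= 0L & pos < n))
      pos + off
    },
    from_transcript = function(pos) {
      stopifnot(all(interval_contains(iv, pos)))
      pos - off
    }
  )
}
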