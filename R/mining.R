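# In silico candidate-SNP mining: align ESTs to their full-length cDNA and
# emit candidate variant sites under the filter chain
#   (1) whole-EST filters: minimum identity (96%), minimum aligned length
#       (the self-contained surrogate for a BLAST E-value cutoff), and the
#       paralog rule (> 4 differences within any 100-column window means
#       the EST comes from a paralog, not an allele);
#   (2) per-column filters: differences within the first/last 50 bases of
#       the EST read (low-quality read ends) and differences inside simple
#       repeats of the target (homopolymer or short tandem runs).

#' Mining filter parameters
#'
#' @param identity_min minimum fraction of identical aligned columns
#'   (default 0.96).
#' @param max_diffs_per_100bp an EST with more than this many differences
#'   inside any 100-column window is treated as paralog-derived
#'   (default 4).
#' @param min_aln_len minimum aligned columns for an EST to be usable;
#'   replaces a database E-value cutoff with a self-contained criterion
#'   (default 100).
#' @param end_trim differences within this many bases of either end of the
#'   EST read are not considered (default 50).
#' @param min_supporting_ests clean supporting ESTs required for candidate
#'   status (default 1).
#' @param match,mismatch,gap_open,gap_extend alignment scoring (defaults
#'   +1/-2; first gapped base costs `gap_open`, each further base
#'   `gap_extend`).
#' @param homopolymer_min,repeat_min_units simple-repeat mask thresholds:
#'   homopolymer runs of at least `homopolymer_min` nt, and di-/tri-
#'   nucleotide tandem repeats of at least `repeat_min_units` units.
#' @return list of class `mining_params`.
#' @export
mining_params <- function(identity_min = 0.96, max_diffs_per_100bp = 4L,
                          min_aln_len = 100L, end_trim = 50L,
                          min_supporting_ests = 1L,
                          match = 1, mismatch = -2,
                          gap_open = 5, gap_extend = 2,
                          homopolymer_min = 5L, repeat_min_units = 3L) {
  structure(as.list(environment()), class = "mining_params")
}

#' Mask simple repeats in a sequence
#'
#' Operationalizes the "poly G or C sequences or other simple repeats"
#' exclusion: homopolymer runs of length >= `homopolymer_min` (any base)
#' and tandem di-/tri-nucleotide repeats of >= `min_units` units.
#'
#' @param seq nucleotide string.
#' @param homopolymer_min minimum homopolymer run length (default 5).
#' @param min_units minimum tandem unit count for di-/tri-nucleotide
#'   repeats (default 3).
#' @return logical vector, one element per base, `TRUE` where masked.
#' @export
mask_repeats <- function(seq, homopolymer_min = 5L, min_units = 3L) {
  n <- nchar(seq)
  mask <- logical(n)
  r <- rle(chars(seq))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$lengths >= homopolymer_min))
    mask[starts[i]:ends[i]] <- TRUE
  for (unit in 2:3) {
    # zero-width lookahead so overlapping phases of a periodic run all match
    pat <- sprintf("(?=(([ACGTN]{%d})\\2{%d,}))", unit, min_units - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      cs <- attr(m, "capture.start")[, 1L]
      cl <- attr(m, "capture.length")[, 1L]
      for (j in seq_along(cs))
        mask[cs[j]:(cs[j] + cl[j] - 1L)] <- TRUE
    }
  }
  mask
}

#' Align an EST read to a full-length cDNA
#'
#' Global alignment with free end gaps (the EST is a fragment of the
#' transcript), deterministic under the fixed scoring parameters. With
#' `search_revcomp`, the reverse complement of the read is also tried and
#' the better-scoring orientation kept.
#'
#' @param est EST read (character).
#' @param flic a [flic_record()] or a plain sequence string.
#' @param est_id,accession identifiers carried into the result.
#' @param params [mining_params()].
#' @param search_revcomp also try the reverse-complemented read.
#' @return object of class `est_alignment`: gapped `aligned_est` /
#'   `aligned_flic` strings, `identity` (fraction of identical aligned
#'   columns), `score`, `est_span` and `flic_span` (0-based half-open),
#'   `est_len`, `strand`, and `usable` (FALSE when no positive-score
#'   alignment exists).
#' @export
align_est <- function(est, flic, est_id = "EST", accession = NULL,
                      params = mining_params(), search_revcomp = FALSE) {
  seq <- if (inherits(flic, "flic_record")) flic$sequence else as.character(flic)
  if (is.null(accession) && inherits(flic, "flic_record"))
    accession <- flic$accession
  stopifnot(nzchar(est), nzchar(seq))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  do_align <- function(read) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(read), subject = Biostrings::DNAString(seq),
      type = "overlap", substitutionMatrix = mat,
      gapOpening = params$gap_open - params$gap_extend,
      gapExtension = params$gap_extend)
  }
  aln <- do_align(est)
  strand <- "+"
  read <- est
  if (search_revcomp) {
    rc <- revcomp(est)
    aln_rc <- do_align(rc)
    if (Biostrings::score(aln_rc) > Biostrings::score(aln)) {
      aln <- aln_rc; strand <- "-"; read <- rc
    }
  }
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  pb <- chars(ap); sb <- chars(as_)
  ncols <- length(pb)
  ident <- if (ncols) mean(pb == sb & pb != "-") else 0
  structure(
    list(est_id = est_id, flic_accession = accession,
         aligned_est = ap, aligned_flic = as_,
         identity = ident, score = Biostrings::score(aln),
         est_span = c(Biostrings::start(Biostrings::pattern(aln)) - 1L,
                      Biostrings::end(Biostrings::pattern(aln))),
         flic_span = c(Biostrings::start(Biostrings::subject(aln)) - 1L,
                       Biostrings::end(Biostrings::subject(aln))),
         est_len = nchar(read), strand = strand,
         usable = Biostrings::score(aln) > 0),
    class = "est_alignment"
  )
}

#' @export
print.est_alignment <- function(x, ...) {
  cat("<est_alignment> ", x$est_id, " vs ", x$flic_accession %||% "?",
      sprintf(": %d cols, identity %.4f, score %.0f, strand %s%s",
              nchar(x$aligned_est), x$identity, x$score, x$strand,
              if (!x$usable) " (unusable)" else ""), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# indicator of difference columns (mismatch or gap) of an alignment
diff_columns <- function(alignment) {
  pb <- chars(alignment$aligned_est)
  sb <- chars(alignment$aligned_flic)
  pb != sb | pb == "-" | sb == "-"
}

#' Whole-EST filters: identity, aligned length, paralog rule
#'
#' @param alignment an [align_est()] result.
#' @param params [mining_params()].
#' @return list with `keep` (logical) and `reason`: `"pass"`,
#'   `"unusable"`, `"identity"` (below the identity floor), `"short"`
#'   (aligned length below `min_aln_len`), or `"paralog"` (a 100-column
#'   window with more than `max_diffs_per_100bp` differences).
#' @export
filter_est <- function(alignment, params = mining_params()) {
  stopifnot(inherits(alignment, "est_alignment"))
  if (!alignment$usable) return(list(keep = FALSE, reason = "unusable"))
  if (alignment$identity < params$identity_min)
    return(list(keep = FALSE, reason = "identity"))
  d <- diff_columns(alignment)
  ncols <- length(d)
  if (ncols < params$min_aln_len)
    return(list(keep = FALSE, reason = "short"))
  w <- min(100L, ncols)
  cs <- cumsum(d)
  win <- cs[w:ncols] - c(0, cs)[seq_len(ncols - w + 1L)]
  if (any(win > params$max_diffs_per_100bp))
    return(list(keep = FALSE, reason = "paralog"))
  list(keep = TRUE, reason = "pass")
}

# Enumerate the difference columns of one alignment with both coordinate
# systems. Returns a data frame with 0-based flic_pos, est_pos (position in
# the read; for a read gap, the index of the next read base), alleles, and
# per-column filter flags.
alignment_differences <- function(alignment, repeat_mask, params) {
  pb <- chars(alignment$aligned_est)
  sb <- chars(alignment$aligned_flic)
  est_pos <- alignment$est_span[1]
  flic_pos <- alignment$flic_span[1]
  out <- list()
  for (k in seq_along(pb)) {
    p <- pb[k]; s <- sb[k]
    if (p != s || p == "-" || s == "-") {
      fp <- if (s != "-") flic_pos else max(flic_pos - 1L, 0L)
      end_trim <- est_pos < params$end_trim ||
        est_pos >= alignment$est_len - params$end_trim
      in_repeat <- fp + 1L <= length(repeat_mask) && repeat_mask[fp + 1L]
      out[[length(out) + 1L]] <- data.frame(
        flic_pos = fp, est_pos = est_pos,
        flic_allele = s, est_allele = p,
        end_trim = end_trim, in_repeat = in_repeat
      )
    }
    if (p != "-") est_pos <- est_pos + 1L
    if (s != "-") flic_pos <- flic_pos + 1L
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Mine candidate SNPs from EST alignments against one target
#'
#' Every difference column of every alignment becomes a putative site;
#' whole-EST rejections (identity / short alignment / paralog rule) and
#' per-column rejections (EST end-trim, simple-repeat mask) are applied,
#' and evidence is merged across ESTs: a site rejected through one EST but
#' supported cleanly by another remains a candidate (per-EST filters are
#' evidence filters, not site vetoes).
#'
#' @param alignments list of [align_est()] results against `flic`.
#' @param flic the target [flic_record()] (or sequence string).
#' @param params [mining_params()].
#' @return data frame of class `candidate_set`: `accession`, `pos`
#'   (0-based transcript position), `flic_allele`, `est_allele`, `status`
#'   (`candidate`, `rejected_end_trim`, `rejected_repeat`,
#'   `rejected_paralog_est`, `rejected_identity`), `supporters`
#'   (comma-separated clean supporting EST ids), `n_support`.
#' @export
mine_candidates <- function(alignments, flic, params = mining_params()) {
  if (inherits(alignments, "est_alignment")) alignments <- list(alignments)
  seq <- if (inherits(flic, "flic_record")) flic$sequence else as.character(flic)
  acc <- if (inherits(flic, "flic_record")) flic$accession else "target"
  mask <- mask_repeats(seq, params$homopolymer_min, params$repeat_min_units)

  rows <- list()
  for (aln in alignments) {
    verdict <- filter_est(aln, params)
    diffs <- alignment_differences(aln, mask, params)
    if (is.null(diffs)) next
    if (!verdict$keep) {
      status <- switch(verdict$reason,
                       paralog = "rejected_paralog_est",
                       "rejected_identity")
      if (verdict$reason == "unusable") next
      diffs$status <- status
    } else {
      diffs$status <- ifelse(diffs$end_trim, "rejected_end_trim",
                             ifelse(diffs$in_repeat, "rejected_repeat",
                                    "candidate"))
    }
    diffs$est_id <- aln$est_id
    rows[[length(rows) + 1L]] <- diffs
  }
  empty <- data.frame(accession = character(0), pos = integer(0),
                      flic_allele = character(0), est_allele = character(0),
                      status = character(0), supporters = character(0),
                      n_support = integer(0))
  class(empty) <- c("candidate_set", "data.frame")
  if (!length(rows)) return(empty)
  all_d <- do.call(rbind, rows)

  status_rank <- c(candidate = 1, rejected_end_trim = 2, rejected_repeat = 3,
                   rejected_paralog_est = 4, rejected_identity = 5)
  key <- paste(all_d$flic_pos, all_d$flic_allele, all_d$est_allele, sep = "\r")
  merged <- lapply(split(all_d, key), function(g) {
    clean <- g$est_id[g$status == "candidate"]
    status <- if (length(clean) >= params$min_supporting_ests &&
                  length(clean) > 0L) "candidate"
              else names(status_rank)[min(status_rank[g$status])]
    data.frame(accession = acc, pos = g$flic_pos[1],
               flic_allele = g$flic_allele[1], est_allele = g$est_allele[1],
               status = status,
               supporters = paste(clean, collapse = ","),
               n_support = length(clean))
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$pos, out$est_allele), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Mine candidates across a set of targets
#'
#' Each EST is aligned to its assigned target; when `est_to_flic` is not
#' given, every EST is aligned against every target and assigned to the
#' best-scoring one (a local surrogate for the database homology search
#' that selects candidate ESTs).
#'
#' @param flics named list of [flic_record()] objects.
#' @param ests named character vector of EST reads.
#' @param params [mining_params()].
#' @param est_to_flic optional named character vector mapping EST id to
#'   accession.
#' @param search_revcomp also try reverse-complemented reads.
#' @return list with `candidates` (one `candidate_set` per accession) and
#'   `est_report` (data frame: est id, accession, identity, score, keep,
#'   reason).
#' @export
mine_snps <- function(flics, ests, params = mining_params(),
                      est_to_flic = NULL, search_revcomp = FALSE) {
  stopifnot(length(ests) > 0L, !is.null(names(ests)))
  if (is.null(est_to_flic)) {
    est_to_flic <- vapply(names(ests), function(id) {
      scores <- vapply(flics, function(f)
        align_est(ests[[id]], f, est_id = id, params = params,
                  search_revcomp = search_revcomp)$score, 0)
      names(flics)[which.max(scores)]
    }, "")
  }
  report <- list()
  candidates <- list()
  for (acc in names(flics)) {
    ids <- names(est_to_flic)[est_to_flic == acc]
    alns <- lapply(ids, function(id)
      align_est(ests[[id]], flics[[acc]], est_id = id,
                params = params, search_revcomp = search_revcomp))
    for (a in alns) {
      v <- filter_est(a, params)
      report[[length(report) + 1L]] <- data.frame(
        est_id = a$est_id, accession = acc, identity = a$identity,
        score = a$score, keep = v$keep, reason = v$reason)
    }
    candidates[[acc]] <- mine_candidates(alns, flics[[acc]], params)
  }
  list(candidates = candidates,
       est_report = if (length(report)) do.call(rbind, report) else NULL)
}

#' Write a candidate set as TSV (1-based positions)
#'
#' @param candidates a `candidate_set` or list of them.
#' @param path output path.
#' @return invisibly, the data frame written.
#' @export
write_candidates <- function(candidates, path) {
  if (inherits(candidates, "candidate_set")) candidates <- list(candidates)
  df <- do.call(rbind, lapply(candidates, as.data.frame))
  df$position <- df$pos + 1L
  df <- df[, c("accession", "position", "flic_allele", "est_allele",
               "status", "supporters", "n_support")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
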