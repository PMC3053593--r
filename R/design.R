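# Amplicon selection and primer design.
#
# Three method profiles share one scorer and differ in product-size range
# and permitted region:
#   utr_primed : 350-450 bp, both primers inside the 3'UTR (amplicons
#                sequenceable end-to-end in one direction);
#   insilico   : 130-170 bp spanning a mined candidate site (short, to
#                limit co-amplified intron length from genomic DNA);
#   epic       : 200-250 bp on transcript coordinates (experimental; true
#                intron crossing needs genomic sequence).
# Primer melting temperatures use nearest-neighbor thermodynamics
# (SantaLucia 1998 unified parameters); universal M13 sequencing tails are
# appended to the returned tailed primers.

.M13_FWD <- "TGTAAAACGACGGCCAGT"
.M13_REV <- "CAGGAAACAGCTATGACC"

# SantaLucia (1998) unified NN parameters: dH kcal/mol, dS cal/(mol K)
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# initiation terms by terminal base
.INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)

#' Primer melting temperature
#'
#' Nearest-neighbor thermodynamic Tm (SantaLucia 1998 unified parameters)
#' at fixed standard conditions: 50 mM monovalent salt (entropic salt
#' correction 0.368 (N-1) ln\[Na+\]) and 0.25 uM oligo with the CT/4
#' approximation for non-self-complementary duplexes. The Wallace rule
#' 2(A+T) + 4(G+C) is available as a documented alternative for quick
#' hand checks.
#'
#' @param primer primer sequence, ACGT only (sequencing tails are excluded
#'   from Tm by the design layer), length >= 8.
#' @param method `"nn"` (default) or `"wallace"`.
#' @param Na monovalent cation concentration, mol/L (default 0.05).
#' @param conc oligo concentration, mol/L (default 2.5e-7).
#' @return melting temperature in degrees Celsius.
#' @export
melting_temp <- function(primer, method = c("nn", "wallace"),
                         Na = 0.05, conc = 2.5e-7) {
  method <- match.arg(method)
  primer <- toupper(primer)
  b <- chars(primer)
  if (!all(b %in% c("A", "C", "G", "T")))
    stop("primer must contain only A/C/G/T")
  if (method == "wallace")
    return(2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C")))
  n <- length(b)
  if (n < 8L) stop("nearest-neighbor Tm requires primer length >= 8")
  nn <- paste0(b[-n], b[-1L])
  dH <- sum(.NN_DH[nn]) + .INIT_DH[[b[1L]]] + .INIT_DH[[b[n]]]
  dS <- sum(.NN_DS[nn]) + .INIT_DS[[b[1L]]] + .INIT_DS[[b[n]]]
  dS <- dS + 0.368 * (n - 1) * log(Na)
  dH * 1000 / (dS + 1.987 * log(conc / 4)) - 273.15
}

#' Design parameters for one amplification method
#'
#' @param method `"utr_primed"`, `"insilico"` or `"epic"`.
#' @param product_size_range nt interval; defaults are method-specific:
#'   utr_primed (350, 450), insilico (130, 170), epic (200, 250).
#' @param tm_optimum primer Tm optimum, degrees C (default 60).
#' @param primer_len_range primer core length range (default 18-24 nt).
#' @param gc_range acceptable primer GC fraction (default 0.35-0.65).
#' @param candidate_margin for `insilico`: minimum distance (nt) from the
#'   candidate site to either primer's inner edge (default 20).
#' @param m13_forward_tail,m13_reverse_tail universal sequencing tails
#'   appended to the 5' ends of the tailed primers.
#' @return list of class `design_params`.
#' @export
design_params <- function(method = c("utr_primed", "insilico", "epic"),
                          product_size_range = NULL,
                          tm_optimum = 60,
                          primer_len_range = c(18L, 24L),
                          gc_range = c(0.35, 0.65),
                          candidate_margin = 20L,
                          m13_forward_tail = .M13_FWD,
                          m13_reverse_tail = .M13_REV) {
  method <- match.arg(method)
  if (is.null(product_size_range))
    product_size_range <- switch(method,
                                 utr_primed = c(350L, 450L),
                                 insilico = c(130L, 170L),
                                 epic = c(200L, 250L))
  structure(list(method = method,
                 product_size_range = as.integer(product_size_range),
                 tm_optimum = tm_optimum,
                 primer_len_range = as.integer(primer_len_range),
                 gc_range = gc_range,
                 candidate_margin = as.integer(candidate_margin),
                 m13_forward_tail = m13_forward_tail,
                 m13_reverse_tail = m13_reverse_tail),
            class = "design_params")
}

design_failure <- function(reason, accession = NULL) {
  structure(list(reason = reason, accession = accession),
            class = "design_failure")
}

#' @export
print.design_failure <- function(x, ...) {
  cat("<design_failure> ", if (!is.null(x$accession)) paste0(x$accession, ": "),
      x$reason, "\n", sep = "")
  invisible(x)
}

#' Test whether a design attempt failed
#' @param x result of [design_amplicon()].
#' @return logical.
#' @export
is_design_failure <- function(x) inherits(x, "design_failure")

# vectorized NN Tm for all (start, len) windows of `seq`; returns a
# function tm(start0, len) over 0-based starts
make_tm_lookup <- function(seq) {
  b <- chars(seq)
  n <- length(b)
  nn <- paste0(b[-n], b[-1L])
  dHc <- c(0, cumsum(.NN_DH[nn]))
  dSc <- c(0, cumsum(.NN_DS[nn]))
  gcc <- c(0, cumsum(b %in% c("G", "C")))
  function(start0, len, Na = 0.05, conc = 2.5e-7) {
    i <- start0 + 1L          # 1-based first base
    j <- start0 + len         # 1-based last base
    dH <- dHc[j] - dHc[i] + .INIT_DH[b[i]] + .INIT_DH[b[j]]
    dS <- dSc[j] - dSc[i] + .INIT_DS[b[i]] + .INIT_DS[b[j]] +
      0.368 * (len - 1) * log(Na)
    tm <- dH * 1000 / (dS + 1.987 * log(conc / 4)) - 273.15
    gc <- (gcc[j + 1L] - gcc[i]) / len
    list(tm = unname(tm), gc = unname(gc))
  }
}

# 3'-end complementarity between two primers: longest perfect duplex formed
# by the 3' terminal bases of each (primer-dimer proxy)
three_prime_complementarity <- function(p1, p2, max_check = 8L) {
  k <- min(nchar(p1), nchar(p2), max_check)
  e1 <- substr(p1, nchar(p1) - k + 1L, nchar(p1))
  e2 <- substr(p2, nchar(p2) - k + 1L, nchar(p2))
  rc2 <- revcomp(e2)
  best <- 0L
  for (len in seq_len(k)) {
    tail1 <- substr(e1, k - len + 1L, k)
    head2 <- substr(rc2, 1L, len)
    if (tail1 == head2) best <- len
  }
  best
}

# per-primer candidates in region [r0, r1) (0-based half-open): one row per
# (start, len) meeting a soft Tm window, keeping the best-scoring length per
# position to make pairing tractable
primer_candidates <- function(tmfun, r0, r1, params, anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  lens <- seq(params$primer_len_range[1], params$primer_len_range[2])
  pos <- if (anchor == "start") seq(r0, r1 - 1L) else seq(r0 + 1L, r1)
  grid <- expand.grid(pos = pos, len = lens)
  if (anchor == "start") {
    grid <- grid[grid$pos + grid$len <= r1, , drop = FALSE]
    grid$start <- grid$pos
  } else {
    # pos is the (exclusive) end coordinate of the primer on the top strand
    grid <- grid[grid$pos - grid$len >= r0, , drop = FALSE]
    grid$start <- grid$pos - grid$len
  }
  if (nrow(grid) == 0L) return(grid)
  th <- tmfun(grid$start, grid$len)
  grid$tm <- th$tm
  grid$gc <- th$gc
  gc_pen <- ifelse(grid$gc < params$gc_range[1] | grid$gc > params$gc_range[2],
                   10 + 100 * pmax(params$gc_range[1] - grid$gc,
                                   grid$gc - params$gc_range[2]), 0)
  grid$score <- abs(grid$tm - params$tm_optimum) + gc_pen
  # best length per anchored position; deterministic tie-break on length
  grid <- grid[order(grid$pos, grid$score, grid$len), , drop = FALSE]
  grid[!duplicated(grid$pos), , drop = FALSE]
}

#' Design a PCR amplicon and primer pair for a target
#'
#' Exhaustively scores primer pairs inside the permitted region (the
#' 3'UTR for `utr_primed`; a window spanning the candidate for
#' `insilico`), subject to the method's hard product-size range. The
#' score penalizes Tm deviation from the optimum for each primer, product
#' length deviation from the range midpoint, GC content outside
#' `gc_range`, and 3'-end complementarity of >= 4 nt between the primers
#' (primer-dimer proxy). Ties are broken leftmost-then-shortest, so the
#' design is deterministic. M13 tails are prepended to the returned tailed
#' primers (and excluded from Tm).
#'
#' @param record a [flic_record()].
#' @param params a [design_params()].
#' @param candidate_position 0-based transcript position of the mined
#'   candidate site (required for `insilico`).
#' @return an `amplicon_design` (list with accession, `target` interval of
#'   the product on the transcript, primer cores and tailed primers, Tm
#'   pair, product length, score), or a `design_failure` with reason
#'   `"utr_too_short"` or `"no_valid_pair"`.
#' @export
design_amplicon <- function(record, params = design_params(),
                            candidate_position = NULL) {
  stopifnot(inherits(record, "flic_record"), inherits(params, "design_params"))
  seq <- record$sequence
  L <- nchar(seq)
  psz <- params$product_size_range
  if (params$method == "utr_primed") {
    region <- record$utr3
    if (interval_len(region) < psz[1])
      return(design_failure("utr_too_short", record$accession))
  } else {
    if (params$method == "insilico" && is.null(candidate_position))
      stop("insilico design requires candidate_position")
    region <- interval(0L, L)
  }
  r0 <- region[["start"]]; r1 <- region[["end"]]
  if (grepl("N", subseq0(seq, region), fixed = TRUE))
    return(design_failure("no_valid_pair", record$accession))

  tmfun <- make_tm_lookup(seq)
  fwd <- primer_candidates(tmfun, r0, r1, params, anchor = "start")
  rev <- primer_candidates(tmfun, r0, r1, params, anchor = "end")
  if (nrow(fwd) == 0L || nrow(rev) == 0L)
    return(design_failure("no_valid_pair", record$accession))

  # pair forwards with reverse candidates at each feasible product length
  pairs <- merge(
    data.frame(fs = fwd$pos, flen = fwd$len, ftm = fwd$tm, fscore = fwd$score,
               key = 1L),
    data.frame(L = seq(psz[1], psz[2]), key = 1L), by = "key")
  pairs$key <- NULL
  pairs$re <- pairs$fs + pairs$L          # product end (exclusive)
  rev_idx <- match(pairs$re, rev$pos)
  ok <- !is.na(rev_idx)
  pairs <- pairs[ok, , drop = FALSE]
  rev_m <- rev[rev_idx[ok], , drop = FALSE]
  pairs$rlen <- rev_m$len
  pairs$rtm <- rev_m$tm
  pairs$rscore <- rev_m$score
  # primers must not overlap
  pairs <- pairs[pairs$fs + pairs$flen <= pairs$re - pairs$rlen, , drop = FALSE]
  if (params$method == "insilico") {
    cp <- candidate_position
    m <- params$candidate_margin
    pairs <- pairs[pairs$fs + pairs$flen + m <= cp &
                   cp < pairs$re - pairs$rlen - m + 1L, , drop = FALSE]
  }
  if (nrow(pairs) == 0L)
    return(design_failure("no_valid_pair", record$accession))

  mid <- mean(psz)
  pairs$score <- pairs$fscore + pairs$rscore + 0.05 * abs(pairs$L - mid)
  pairs <- pairs[order(pairs$score, pairs$fs, pairs$L, pairs$flen, pairs$rlen), ,
                 drop = FALSE]
  # 3'-end complementarity penalty on a shortlist only (string work is slow)
  top <- utils::head(pairs, 50L)
  dimer <- vapply(seq_len(nrow(top)), function(i) {
    fp <- substr(seq, top$fs[i] + 1L, top$fs[i] + top$flen[i])
    rp <- revcomp(substr(seq, top$re[i] - top$rlen[i] + 1L, top$re[i]))
    three_prime_complementarity(fp, rp)
  }, 0L)
  top$score <- top$score + ifelse(dimer >= 4L, 5 * (dimer - 3L), 0)
  top <- top[order(top$score, top$fs, top$L, top$flen, top$rlen), , drop = FALSE]
  best <- top[1L, ]

  fwd_core <- substr(seq, best$fs + 1L, best$fs + best$flen)
  rev_core <- revcomp(substr(seq, best$re - best$rlen + 1L, best$re))
  structure(
    list(flic_accession = record$accession,
         method = params$method,
         target = interval(best$fs, best$re),
         forward_primer = fwd_core,
         reverse_primer = rev_core,
         forward_tailed = paste0(params$m13_forward_tail, fwd_core),
         reverse_tailed = paste0(params$m13_reverse_tail, rev_core),
         product_length = best$L,
         tm = c(forward = best$ftm, reverse = best$rtm),
         score = best$score),
    class = "amplicon_design"
  )
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat("<amplicon_design> ", x$flic_accession, " [", x$method, "]: product ",
      x$product_length, " bp at [", x$target[["start"]], ",",
      x$target[["end"]], "); Tm ", sprintf("%.1f/%.1f", x$tm[1], x$tm[2]),
      " C; score ", sprintf("%.2f", x$score), "\n", sep = "")
  invisible(x)
}

#' Extract the predicted PCR product for a design
#'
#' String extraction between the primer sites of the template; with no
#' intron simulated, its length equals the designed product length.
#'
#' @param design an `amplicon_design`.
#' @param template template sequence (defaults senseless here, so pass the
#'   record's sequence).
#' @return character product sequence.
#' @export
amplify_product <- function(design, template) {
  stopifnot(inherits(design, "amplicon_design"))
  subseq0(template, design$target)
}

#' Design amplicons for many targets and tabulate results
#'
#' @param records named list of [flic_record()] objects.
#' @param params a [design_params()].
#' @param candidate_positions optional named integer vector (0-based) of
#'   candidate sites for `insilico` designs.
#' @return list with `designs` (data frame, 1-based coordinates) and
#'   `failures` (data frame of accession + reason).
#' @export
design_all <- function(records, params = design_params(),
                       candidate_positions = NULL) {
  designs <- list(); failures <- list()
  for (acc in names(records)) {
    cp <- if (!is.null(candidate_positions)) candidate_positions[[acc]] else NULL
    d <- design_amplicon(records[[acc]], params, candidate_position = cp)
    if (is_design_failure(d)) {
      failures[[length(failures) + 1L]] <-
        data.frame(accession = acc, reason = d$reason)
    } else {
      designs[[length(designs) + 1L]] <- data.frame(
        accession = acc, method = d$method,
        start = d$target[["start"]] + 1L, end = d$target[["end"]],
        forward_primer = d$forward_primer, reverse_primer = d$reverse_primer,
        forward_tailed = d$forward_tailed, reverse_tailed = d$reverse_tailed,
        product_length = d$product_length,
        tm_forward = unname(d$tm[1]), tm_reverse = unname(d$tm[2]),
        score = d$score)
    }
  }
  list(designs = if (length(designs)) do.call(rbind, designs) else NULL,
       failures = if (length(failures)) do.call(rbind, failures) else NULL)
}
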