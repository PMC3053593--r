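# Synthetic duplicated-genome data generator.
#
# Emulates the study system end-to-end: annotated full-length cDNA targets
# with a recent-duplication paralog for a configurable fraction of genes
# (paralogs diverge faster in the 3'UTR than in the CDS), bi-allelic SNPs
# and single-base deletion-insertion polymorphisms (DIPs) planted at chosen
# minor-allele frequencies, a small diploid validation panel sampled under
# Hardy-Weinberg equilibrium, and single-pass EST reads with per-base
# substitution errors. Ground truth is retained so every pipeline stage can
# be tested for parameter recovery.

#' Simulation configuration
#'
#' Defaults encode the study conditions: a 10-individual diploid panel, a
#' 5-individual extension panel, 3'UTRs of 200-800 nt, and a DIP fraction
#' of 16/79 (the observed split of 63 SNPs vs 16 DIPs among discovered
#' polymorphisms). Paralog divergence (0.03/bp in the 3'UTR, x0.3 in the
#' CDS) is a free parameter of the simulator, not an estimate.
#'
#' @param seed integer RNG seed; a fixed config yields byte-identical output.
#' @param n_genes number of target genes.
#' @param utr3_len_range,cds_len_range nt length ranges (CDS rounded down
#'   to a codon multiple).
#' @param paralog_fraction proportion of genes given a duplicated copy.
#' @param paralog_divergence per-base substitution probability between a
#'   gene and its paralog in the 3'UTR.
#' @param cds_divergence_factor multiplier (< 1) on `paralog_divergence`
#'   inside the CDS, reflecting stronger purifying selection there.
#' @param panel_size diploid panel size `n`.
#' @param n_extension extension-panel size for single-carrier re-typing.
#' @param planted_snps_per_gene variants planted per gene (in the 3'UTR).
#' @param maf_distribution minor-allele frequencies sampled uniformly for
#'   planted variants.
#' @param dip_fraction proportion of planted variants that are single-base
#'   DIPs rather than SNPs.
#' @param est_per_gene,est_error_rate,est_len_range EST read count per
#'   gene, per-base substitution error rate, and read-length range.
#' @param est_paralog_fraction probability an EST originates from the
#'   paralog (when one exists) rather than an allelic transcript.
#' @param psv_mode logical; simulate paralog co-amplification, so paralog
#'   fixed differences appear heterozygous in every panel individual.
#' @param plant_repeats logical; insert a poly-G/C run (6-10 nt) into each
#'   3'UTR to exercise the simple-repeat filter.
#' @param indel_est_errors logical; also make EST errors single-base
#'   indels (off by default so alignment columns stay well defined).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 10L,
                       utr3_len_range = c(200L, 800L),
                       cds_len_range = c(300L, 1500L),
                       paralog_fraction = 0.5,
                       paralog_divergence = 0.03,
                       cds_divergence_factor = 0.3,
                       panel_size = 10L,
                       n_extension = 5L,
                       planted_snps_per_gene = 2L,
                       maf_distribution = c(0.05, 0.1, 0.25, 0.5),
                       dip_fraction = 16 / 79,
                       est_per_gene = 5L,
                       est_error_rate = 0.01,
                       est_len_range = c(300L, 600L),
                       est_paralog_fraction = 0.25,
                       psv_mode = FALSE,
                       plant_repeats = FALSE,
                       indel_est_errors = FALSE) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              utr3_len_range = as.integer(utr3_len_range),
              cds_len_range = as.integer(cds_len_range),
              paralog_fraction = paralog_fraction,
              paralog_divergence = paralog_divergence,
              cds_divergence_factor = cds_divergence_factor,
              panel_size = as.integer(panel_size),
              n_extension = as.integer(n_extension),
              planted_snps_per_gene = as.integer(planted_snps_per_gene),
              maf_distribution = maf_distribution,
              dip_fraction = dip_fraction,
              est_per_gene = as.integer(est_per_gene),
              est_error_rate = est_error_rate,
              est_len_range = as.integer(est_len_range),
              est_paralog_fraction = est_paralog_fraction,
              psv_mode = isTRUE(psv_mode),
              plant_repeats = isTRUE(plant_repeats),
              indel_est_errors = isTRUE(indel_est_errors))
  probs <- c(cfg$paralog_fraction, cfg$paralog_divergence,
             cfg$cds_divergence_factor, cfg$dip_fraction,
             cfg$est_error_rate, cfg$est_paralog_fraction,
             cfg$maf_distribution)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities and frequencies must lie in [0, 1]")
  for (rng in list(cfg$utr3_len_range, cfg$cds_len_range, cfg$est_len_range))
    if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 1L)
      stop("length ranges must be nonempty positive intervals")
  if (cfg$n_genes < 1L || cfg$panel_size < 2L)
    stop("need at least 1 gene and a panel of at least 2")
  if (cfg$maf_distribution[1] < 0 || length(cfg$maf_distribution) < 1L)
    stop("maf_distribution must be nonempty")
  if (cfg$paralog_divergence > 0.25)
    warning("paralog divergence > 0.25: alignment-based mining assumptions break")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes, panel n=", x$panel_size,
      " (+", x$n_extension, "), paralog fraction ", x$paralog_fraction,
      " at divergence ", x$paralog_divergence, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# draw one integer from [a, b] (robust to a == b, unlike sample(seq(a, b)))
sample_range <- function(rng) {
  if (rng[1] == rng[2]) return(rng[1])
  sample(seq(rng[1], rng[2]), 1L)
}

# substitute each position independently with prob `rate`; returns
# list(seq, positions) with 0-based substituted positions
mutate_seq <- function(seq, rate) {
  b <- chars(seq)
  hit <- which(stats::runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  list(seq = paste(b, collapse = ""), positions = hit - 1L)
}

#' Simulate annotated targets with paralogs and planted variants
#'
#' Each gene gets a random CDS and 3'UTR; a fraction of genes receive a
#' paralogous copy whose per-base divergence is `paralog_divergence` in the
#' 3'UTR and `paralog_divergence * cds_divergence_factor` in the CDS.
#' `planted_snps_per_gene` variants (SNP or single-base-deletion DIP) are
#' planted at 3'UTR positions outside simple repeats, each with a minor
#' allele frequency drawn from `maf_distribution`.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_targets`: list with `flics` (named list
#'   of [flic_record()]), `paralogs` (named character vector of paralog
#'   sequences), and `truth` (per-gene planted variants and paralog fixed
#'   differences, 0-based transcript coordinates).
#' @export
simulate_targets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    flics <- list()
    paralogs <- character(0)
    truth <- list()
    for (g in seq_len(config$n_genes)) {
      acc <- sprintf("SIMG%03d", g)
      cds_len <- sample_range(config$cds_len_range)
      cds_len <- (cds_len %/% 3L) * 3L
      utr_len <- sample_range(config$utr3_len_range)
      seq <- random_seq(cds_len + utr_len)
      if (config$plant_repeats) {
        run_len <- sample(6:10, 1L)
        run_base <- sample(c("G", "C"), 1L)
        at <- sample.int(utr_len - run_len + 1L, 1L) - 1L      # UTR-relative
        substr(seq, cds_len + at + 1L, cds_len + at + run_len) <-
          strrep(run_base, run_len)
      }
      cds <- interval(0L, cds_len)
      utr3 <- interval(cds_len, cds_len + utr_len)

      has_paralog <- stats::runif(1) < config$paralog_fraction
      paralog_diffs <- NULL
      if (has_paralog) {
        cds_mut <- mutate_seq(subseq0(seq, cds),
                              config$paralog_divergence * config$cds_divergence_factor)
        utr_mut <- mutate_seq(subseq0(seq, utr3), config$paralog_divergence)
        paralogs[[acc]] <- paste0(cds_mut$seq, utr_mut$seq)
        pos <- c(cds_mut$positions, utr_mut$positions + cds_len)
        paralog_diffs <- data.frame(
          pos = pos,
          gene_base = vapply(pos, function(p) substr(seq, p + 1L, p + 1L), ""),
          paralog_base = vapply(pos, function(p)
            substr(paralogs[[acc]], p + 1L, p + 1L), "")
        )
      }

      # plant variants in the 3'UTR, outside simple repeats so the planted
      # truth is recoverable by the mining filters
      mask <- mask_repeats(seq)
      avail <- setdiff(seq(cds_len, cds_len + utr_len - 1L), which(mask) - 1L)
      n_var <- min(config$planted_snps_per_gene, length(avail))
      pos <- sort(sample(avail, n_var))
      variants <- NULL
      if (n_var > 0L) {
        is_dip <- stats::runif(n_var) < config$dip_fraction
        ref <- vapply(pos, function(p) substr(seq, p + 1L, p + 1L), "")
        alt <- ifelse(is_dip, "-",
                      vapply(ref, function(b)
                        sample(setdiff(c("A", "C", "G", "T"), b), 1L), ""))
        variants <- data.frame(
          pos = pos, pos_utr = pos - cds_len, ref = ref, alt = unname(alt),
          class = ifelse(is_dip, "DIP", "SNP"),
          maf = sample(config$maf_distribution, n_var, replace = TRUE)
        )
      }
      flics[[acc]] <- flic_record(acc, seq, utr3 = utr3, cds = cds,
                                  complete_cds = TRUE)
      truth[[acc]] <- list(accession = acc, has_paralog = has_paralog,
                           paralog_diffs = paralog_diffs, variants = variants)
    }
    structure(list(flics = flics, paralogs = paralogs, truth = truth,
                   config = config),
              class = "sim_targets")
  })
}

#' Simulate the diploid validation panel
#'
#' For each gene the amplicon is its full 3'UTR. Each individual's genotype
#' at a planted site is two independent allele draws at the site's minor
#' allele frequency (Hardy-Weinberg sampling); the per-individual consensus
#' is emitted with IUPAC heterozygote codes. In `psv_mode`, paralog
#' co-amplification makes every individual heterozygous at each paralog
#' fixed-difference column.
#'
#' @param targets a [simulate_targets()] result.
#' @param config the same [sim_config()] (defaults to the one in `targets`).
#' @return named list of [panel_genotypes()], one per gene, each carrying
#'   the amplicon reference; per-individual diplotypes are attached as the
#'   `diplotypes` attribute (ground truth).
#' @export
simulate_panel <- function(targets, config = targets$config) {
  stopifnot(inherits(targets, "sim_targets"))
  with_seed(config$seed + 101L, {
    panels <- list()
    diplo_truth <- list()
    inds <- sprintf("ind%02d", seq_len(config$panel_size))
    ext_inds <- sprintf("ext%02d", seq_len(config$n_extension))
    for (acc in names(targets$flics)) {
      rec <- targets$flics[[acc]]
      utr <- extract_utr3(rec)
      ref_chars <- chars(utr$sequence)
      tr <- targets$truth[[acc]]
      n_all <- length(inds) + length(ext_inds)
      mat <- matrix(rep(ref_chars, n_all), ncol = n_all)
      diplo <- list()
      if (!is.null(tr$variants)) {
        for (v in seq_len(nrow(tr$variants))) {
          row <- tr$variants[v, ]
          a <- matrix(stats::runif(2L * n_all) < row$maf, nrow = 2L)
          g <- apply(a, 2L, function(z) {
            al <- ifelse(z, row$alt, row$ref)
            encode_genotype(al[1], al[2])
          })
          mat[row$pos_utr + 1L, ] <- g
          diplo[[length(diplo) + 1L]] <- data.frame(
            pos_utr = row$pos_utr,
            individual = c(inds, ext_inds),
            n_alt = colSums(a)
          )
        }
      }
      if (config$psv_mode && tr$has_paralog && !is.null(tr$paralog_diffs)) {
        in_utr <- tr$paralog_diffs[interval_contains(rec$utr3, tr$paralog_diffs$pos), ,
                                   drop = FALSE]
        for (d in seq_len(nrow(in_utr))) {
          col <- in_utr$pos[d] - rec$utr3[["start"]] + 1L
          mat[col, ] <- encode_genotype(in_utr$gene_base[d], in_utr$paralog_base[d])
        }
      }
      calls <- apply(mat, 2L, paste, collapse = "")
      ext <- NULL
      if (length(ext_inds) > 0L) {
        ext <- calls[length(inds) + seq_along(ext_inds)]
        names(ext) <- ext_inds
      }
      panels[[acc]] <- panel_genotypes(acc, inds, calls[seq_along(inds)],
                                       extension_calls = ext,
                                       ref = utr$sequence)
      diplo_truth[[acc]] <- if (length(diplo)) do.call(rbind, diplo) else NULL
    }
    attr(panels, "diplotypes") <- diplo_truth
    panels
  })
}

#' Simulate EST reads from allelic and paralogous transcripts
#'
#' Each EST is a random window (length in `est_len_range`) of either an
#' allelic haplotype of the gene (planted variant alleles drawn at their
#' MAF) or, with probability `est_paralog_fraction`, of the paralogous
#' transcript; per-base substitution errors are applied at
#' `est_error_rate`. Source labels are recorded for every read.
#'
#' @param targets a [simulate_targets()] result.
#' @param config the same [sim_config()].
#' @return list with `ests` (named character vector of reads) and `sources`
#'   (data frame: est id, gene, source `allelic`/`paralog`, window start on
#'   the source transcript (0-based), error count).
#' @export
simulate_ests <- function(targets, config = targets$config) {
  stopifnot(inherits(targets, "sim_targets"))
  with_seed(config$seed + 202L, {
    ests <- character(0)
    src <- list()
    for (acc in names(targets$flics)) {
      rec <- targets$flics[[acc]]
      tr <- targets$truth[[acc]]
      for (e in seq_len(config$est_per_gene)) {
        use_paralog <- tr$has_paralog &&
          stats::runif(1) < config$est_paralog_fraction
        if (use_paralog) {
          hap <- targets$paralogs[[acc]]
        } else {
          b <- chars(rec$sequence)
          if (!is.null(tr$variants)) {
            carry <- stats::runif(nrow(tr$variants)) < tr$variants$maf
            for (v in which(carry)) b[tr$variants$pos[v] + 1L] <- tr$variants$alt[v]
          }
          hap <- paste(b[b != "-"], collapse = "")
        }
        len <- sample_range(config$est_len_range)
        if (len > nchar(hap)) {
          warning("EST length clipped to transcript length for ", acc)
          len <- nchar(hap)
        }
        start <- sample.int(nchar(hap) - len + 1L, 1L) - 1L
        read <- substr(hap, start + 1L, start + len)
        if (config$est_error_rate > 0) {
          if (config$indel_est_errors) {
            b <- chars(read)
            hit <- which(stats::runif(length(b)) < config$est_error_rate)
            for (i in hit) {
              kind <- sample(c("sub", "del", "ins"), 1L)
              b[i] <- switch(kind,
                sub = sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L),
                del = "",
                ins = paste0(b[i], sample(c("A", "C", "G", "T"), 1L)))
            }
            read <- paste(b, collapse = "")
            nerr <- length(hit)
          } else {
            m <- mutate_seq(read, config$est_error_rate)
            read <- m$seq
            nerr <- length(m$positions)
          }
        } else nerr <- 0L
        id <- sprintf("%s_EST%02d", acc, e)
        ests[[id]] <- read
        src[[length(src) + 1L]] <- data.frame(
          est_id = id, gene = acc,
          source = if (use_paralog) "paralog" else "allelic",
          window_start = start, n_errors = nerr
        )
      }
    }
    list(ests = ests, sources = do.call(rbind, src))
  })
}

#' Run the full simulator and optionally write a dataset to disk
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `targets.fa`,
#'   `paralogs.fa`, `annot.tsv`, `ests.fa`, `panel.fa`, `truth.json` and
#'   `config.yaml`.
#' @return list with `targets`, `panels`, `ests`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  targets <- simulate_targets(config)
  panels <- simulate_panel(targets, config)
  ests <- simulate_ests(targets, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_flics(targets$flics, file.path(out_dir, "targets.fa"),
                file.path(out_dir, "annot.tsv"))
    if (length(targets$paralogs)) {
      ps <- Biostrings::DNAStringSet(targets$paralogs)
      names(ps) <- paste0(names(targets$paralogs), "_paralog")
      Biostrings::writeXStringSet(ps, file.path(out_dir, "paralogs.fa"))
    }
    es <- Biostrings::DNAStringSet(ests$ests)
    Biostrings::writeXStringSet(es, file.path(out_dir, "ests.fa"))
    write_panel(panels, file.path(out_dir, "panel.fa"))
    jsonlite::write_json(targets$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  list(targets = targets, panels = panels, ests = ests)
}
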