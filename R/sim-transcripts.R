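STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

#' Default alternative-start-codon set
#'
#' AUG, its nine single-base mutants (CUG, GUG, UUG, AAG, ACG, AGG, AUA,
#' AUC, AUU) and GCG -- GCG is included because alanine-initiated N-termini
#' are observed among confirmed alternative starts. Returned in RNA
#' spelling.
#'
#' @return character vector of codons.
#' @export
default_atis_codons <- function() {
  mut <- character(0)
  aug <- c("A", "U", "G")
  for (i in 1:3) for (b in c("A", "C", "G", "U")) {
    cod <- aug; cod[i] <- b
    mut <- c(mut, paste(cod, collapse = ""))
  }
  unique(c("AUG", mut, "GCG"))
}

sample_codons <- function(n, exclude_stops = TRUE) {
  pool <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)),
                          BASES, paste0))
  if (exclude_stops) pool <- setdiff(pool, STOP_CODONS)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# positions p (0-based) in 0..(limit-1) whose trinucleotide is in `set`
codon_hits <- function(seq, set, limit) {
  if (limit < 1L) return(integer(0))
  p <- 0:(limit - 1L)
  cod <- substring(seq, p + 1L, p + 3L)
  p[cod %in% set & nchar(cod) == 3L]
}

# Rewrite UTR bases so that (a) no codon-set hit exists at UTR offsets other
# than `planted`, and (b) for in-frame plants no stop codon sits between the
# planted start and the CDS. Positions inside the planted codon are frozen.
repair_utr <- function(seq, utr5_end, set_dna, planted = integer(0),
                       inframe_from = NA_integer_, max_iter = 400L) {
  frozen <- integer(0)
  if (length(planted)) frozen <- as.vector(outer(planted, 0:2, `+`))
  bad_windows <- function(s) {
    hits <- setdiff(codon_hits(s, set_dna, utr5_end), planted)
    stops <- integer(0)
    if (!is.na(inframe_from) && utr5_end - inframe_from >= 3L) {
      p <- seq.int(inframe_from, utr5_end - 3L, by = 3L)
      cod <- substring(s, p + 1L, p + 3L)
      stops <- p[cod %in% STOP_CODONS]
    }
    sort(unique(c(hits, stops)))
  }
  n_bad_near <- function(s, pos) {
    # recount problems in the windows a single-base edit can affect
    length(bad_windows(s))
  }
  for (iter in seq_len(max_iter)) {
    bad <- bad_windows(seq)
    if (!length(bad)) return(seq)
    n_before <- length(bad)
    b <- bad[1]
    cand_pos <- setdiff(b + 0:2, frozen)
    cand_pos <- cand_pos[cand_pos >= 0L & cand_pos < utr5_end]
    fixed <- FALSE
    for (pos in sample_vec(cand_pos)) {
      old <- substr(seq, pos + 1L, pos + 1L)
      for (base in sample_vec(setdiff(BASES, old))) {
        trial <- seq
        substr(trial, pos + 1L, pos + 1L) <- base
        if (n_bad_near(trial, pos) < n_before) {
          seq <- trial
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) {
      # strictly-improving edit not available at this window: random restart
      pos <- sample_vec(setdiff(seq_len(utr5_end) - 1L, frozen), 1L)
      old <- substr(seq, pos + 1L, pos + 1L)
      substr(seq, pos + 1L, pos + 1L) <-
        sample_vec(setdiff(BASES, old), 1L)
    }
  }
  stop("could not repair UTR after ", max_iter, " iterations")
}

#' Generate synthetic transcript models with planted alternative starts
#'
#' Each coding model carries a 5'UTR, a CDS (AUG...stop, no internal stop)
#' and a 3'UTR on a single synthetic chromosome. A configurable fraction of
#' models carries one planted upstream near-cognate start codon, in-frame
#' (an N-terminal extension of known length) or out-of-frame; the planted
#' ground truth is recorded. UTRs are rewritten so that no *unplanted*
#' codon-set hit survives upstream of the CDS, making the planted truth the
#' exact expected output of [scan_atis_sites()]. Optionally appends
#' non-coding (lncRNA) transcripts.
#'
#' @param config a [sim_config()].
#' @param codon_set start-codon set used for planting/scanning (RNA
#'   spelling); default [default_atis_codons()].
#' @return list with `models` (data.frame: transcript_id, gene_id, biotype,
#'   sequence, utr5_end, cds_end, chrom, chrom_start), `atis_truth`
#'   (planted sites with expected event and product), `genome` (named
#'   character: chromosome sequence) and `codon_set`.
#' @export
gen_transcript_models <- function(config, codon_set = default_atis_codons()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 101L))
  set_dna <- rna_to_dna(codon_set)
  n <- config$n_genes
  n_atis <- round(config$frac_atis * n)
  atis_genes <- if (n_atis > 0) sort(sample.int(n, n_atis)) else integer(0)

  rows <- vector("list", n + config$n_lncrna)
  truth <- list()
  for (i in seq_len(n)) {
    utr5 <- sample_vec(config$utr5_range[1]:config$utr5_range[2], 1L)
    n_cod <- sample_vec(max(2L, config$cds_range[1] %/% 3L):
                      (config$cds_range[2] %/% 3L), 1L)
    utr3 <- sample_vec(config$utr3_range[1]:config$utr3_range[2], 1L)
    cds <- paste0("ATG", sample_codons(n_cod - 2L),
                  sample(STOP_CODONS, 1L))
    utr5_seq <- paste(sample(BASES, utr5, replace = TRUE), collapse = "")
    utr3_seq <- paste(sample(BASES, utr3, replace = TRUE), collapse = "")
    seq <- paste0(utr5_seq, cds, utr3_seq)
    utr5_end <- utr5
    cds_end <- utr5 + nchar(cds)

    planted <- integer(0); inframe_from <- NA_integer_
    plant <- NULL
    if (i %in% atis_genes && utr5 >= 24L) {
      in_frame <- runif(1) < 0.5
      if (in_frame) {
        kmax <- min(utr5 %/% 3L, 12L)
        k <- sample_vec(7L:max(7L, kmax), 1L)
        p0 <- utr5_end - 3L * k
        inframe_from <- p0
      } else {
        kmax <- min((utr5 - 2L) %/% 3L, 12L)
        k <- sample_vec(7L:max(7L, kmax), 1L)
        p0 <- utr5_end - 3L * k - sample(1:2, 1L)
      }
      codon <- sample(setdiff(set_dna, "ATG"), 1L)
      substr(seq, p0 + 1L, p0 + 3L) <- codon
      planted <- p0
      plant <- list(p0 = p0, codon = codon, in_frame = in_frame, k = k)
    }
    seq <- repair_utr(seq, utr5_end, set_dna, planted, inframe_from)

    tid <- sprintf("TX%05d", i)
    rows[[i]] <- data.frame(
      transcript_id = tid, gene_id = sprintf("GENE%05d", i),
      biotype = "protein_coding", sequence = seq,
      utr5_end = utr5_end, cds_end = cds_end, stringsAsFactors = FALSE)

    if (!is.null(plant)) {
      product <- translate_nt(substr(seq, plant$p0 + 1L, nchar(seq)),
                              initiator = TRUE)
      frame <- if (plant$in_frame) "in_frame" else "out_of_frame"
      prod_nt_end <- plant$p0 + 3L * (nchar(product) + 1L)  # incl. stop
      event <- if (plant$in_frame) {
        if (prod_nt_end <= utr5_end) "uorf" else "extension"
      } else {
        if (prod_nt_end <= utr5_end) "uorf" else "frameshift"
      }
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = tid, offset = plant$p0,
        codon = dna_to_rna(plant$codon), frame = frame, event = event,
        extra_aa = if (plant$in_frame && event == "extension")
          plant$k else NA_integer_,
        product_len = nchar(product), kept = nchar(product) > 6L,
        stringsAsFactors = FALSE)
    }
  }

  for (j in seq_len(config$n_lncrna)) {
    len <- sample_vec(200:400, 1L)
    rows[[n + j]] <- data.frame(
      transcript_id = sprintf("LNC%03d", j),
      gene_id = sprintf("LNCG%03d", j), biotype = "lncRNA",
      sequence = paste(sample(BASES, len, replace = TRUE), collapse = ""),
      utr5_end = NA_integer_, cds_end = NA_integer_,
      stringsAsFactors = FALSE)
  }

  models <- do.call(rbind, rows)
  spacer <- strrep("N", 100L)
  starts <- cumsum(c(1L, utils::head(nchar(models$sequence) + 100L, -1L)))
  models$chrom <- "chrS"
  models$chrom_start <- starts
  genome <- paste(models$sequence, collapse = spacer)

  atis_truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(transcript_id = character(), offset = integer(),
               codon = character(), frame = character(),
               event = character(), extra_aa = integer(),
               product_len = integer(), kept = logical(),
               stringsAsFactors = FALSE)

  list(models = models, atis_truth = atis_truth,
       genome = c(chrS = genome), codon_set = codon_set)
}
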