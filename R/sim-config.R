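#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' statistical structure of the study inputs at desk scale: transcript
#' abundance spanning four orders of magnitude, protein abundance derived
#' from a log-log slope of 2.6 with bivariate log10 noise, a small fraction
#' of tissue-enriched genes, heterozygous/homozygous missense plus nonsense
#' variants (het:hom proportions echoing the exome data), and
#' two search engines with distinct score distributions.
#'
#' @param n_genes number of protein-coding genes.
#' @param n_tissues number of tissues (29 in the atlas).
#' @param seed integer seed; fully determines every generator output.
#' @param mrna_log10_range orders of magnitude spanned by mRNA abundance.
#' @param protein_log10_range orders spanned by protein intensity; `NULL`
#'   (default) derives it as `true_slope * mrna_log10_range`, the value the
#'   slope model implies.
#' @param true_slope log10-protein per log10-mRNA slope planted in the
#'   generator (brain tissue: 2.6; all tissues: 1.8-2.7).
#' @param noise_sd Gaussian noise SD, log10 units, added independently to
#'   both the mRNA and the protein axis.
#' @param dropout_rate overall scale of protein non-detection; 0 disables
#'   dropout entirely.
#' @param dropout_floor abundance-independent ("flat") component of the
#'   dropout probability, as a fraction of `dropout_rate`.
#' @param frac_tissue_enriched fraction of genes planted as tissue-enriched.
#' @param enriched_fold planted fold-change of the enriched tissue over all
#'   others (must exceed the classifier's fivefold rule).
#' @param mrna_log10_min lower edge of the log10 FPKM window.
#' @param protein_log10_min lower edge of the log10 intensity window.
#' @param variant_counts named list: `missense_het`, `missense_hom`,
#'   `nonsense` counts to simulate.
#' @param frac_atis fraction of transcript models carrying one planted
#'   upstream near-cognate start codon (ground truth recorded).
#' @param n_lncrna number of non-coding transcripts emitted alongside the
#'   coding models.
#' @param utr5_range,cds_range,utr3_range nucleotide length windows for the
#'   transcript regions (CDS length is rounded to a codon multiple).
#' @param score_distributions per-engine location/scale of the background
#'   (non-planted) PSM score distributions.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_tissues = 29L,
                       seed = 1L,
                       mrna_log10_range = 4,
                       protein_log10_range = NULL,
                       true_slope = 2.6,
                       noise_sd = 0.3,
                       dropout_rate = 0.1,
                       dropout_floor = 0.05,
                       frac_tissue_enriched = 0.05,
                       enriched_fold = 8,
                       mrna_log10_min = -1,
                       protein_log10_min = 3,
                       variant_counts = list(missense_het = 60L,
                                             missense_hom = 37L,
                                             nonsense = 10L),
                       frac_atis = 0.3,
                       n_lncrna = 5L,
                       utr5_range = c(30L, 90L),
                       cds_range = c(60L, 300L),
                       utr3_range = c(20L, 60L),
                       score_distributions = list(
                         engine_a_ion = c(mean = 15, sd = 6),
                         engine_a_delta = c(mean = 5, sd = 3),
                         engine_b = c(mean = 40, sd = 20))) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_tissues = as.integer(n_tissues),
              seed = as.integer(seed),
              mrna_log10_range = mrna_log10_range,
              protein_log10_range =
                protein_log10_range %||% (true_slope * mrna_log10_range),
              true_slope = true_slope,
              noise_sd = noise_sd,
              dropout_rate = dropout_rate,
              dropout_floor = dropout_floor,
              frac_tissue_enriched = frac_tissue_enriched,
              enriched_fold = enriched_fold,
              mrna_log10_min = mrna_log10_min,
              protein_log10_min = protein_log10_min,
              variant_counts = lapply(variant_counts, as.integer),
              frac_atis = frac_atis,
              n_lncrna = as.integer(n_lncrna),
              utr5_range = as.integer(utr5_range),
              cds_range = as.integer(cds_range),
              utr3_range = as.integer(utr3_range),
              score_distributions = score_distributions)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L, cfg$n_tissues >= 1L)
  if (cfg$mrna_log10_range <= 0 || cfg$protein_log10_range <= 0)
    stop("abundance ranges must be > 0")
  probs <- c(cfg$dropout_rate, cfg$dropout_floor,
             cfg$frac_tissue_enriched, cfg$frac_atis)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$enriched_fold <= 1) stop("enriched_fold must exceed 1")
  if (cfg$cds_range[1] < 6L) stop("CDS shorter than 6 nt is impossible")
  if (any(diff(rbind(cfg$utr5_range, cfg$cds_range, cfg$utr3_range)[, 1:2,
                                                                    drop = FALSE]) < 0))
    invisible(NULL)
  if (cfg$utr5_range[1] > cfg$utr5_range[2] ||
      cfg$cds_range[1] > cfg$cds_range[2] ||
      cfg$utr3_range[1] > cfg$utr3_range[2])
    stop("length ranges must be nondecreasing")
  cnt <- unlist(cfg$variant_counts)
  if (any(cnt < 0L)) stop("variant counts must be nonnegative")
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("synthetic-atlas configuration\n")
  cat(sprintf("  genes: %d  tissues: %d  seed: %d\n",
              x$n_genes, x$n_tissues, x$seed))
  cat(sprintf("  mRNA range: %g log10  slope: %g  noise SD: %g\n",
              x$mrna_log10_range, x$true_slope, x$noise_sd))
  cat(sprintf("  tissue-enriched: %.1f%% (fold %g)  dropout: %g\n",
              100 * x$frac_tissue_enriched, x$enriched_fold,
              x$dropout_rate))
  invisible(x)
}
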