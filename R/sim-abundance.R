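#' Expression matrix container
#'
#' A plain numeric matrix (genes x tissues) plus a unit tag and a detection
#' threshold. Values are on the natural scale; zeros denote non-detection
#' for intensity data.
#'
#' @param values nonnegative numeric matrix with row (gene) and column
#'   (tissue) names.
#' @param unit `"fpkm"` or `"intensity"`.
#' @param detect_threshold abundance at or above which a value counts as
#'   detected (default: 1 for FPKM; anything > 0 for intensity).
#' @return an `expr_matrix` object.
#' @export
expression_matrix <- function(values, unit = c("fpkm", "intensity"),
                              detect_threshold = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("abundance values must be >= 0")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("tissue%d", seq_len(ncol(values)))
  thr <- detect_threshold %||% if (unit == "fpkm") 1 else
    .Machine$double.xmin
  structure(list(values = values, unit = unit, detect_threshold = thr),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d tissues [%s, detect >= %g]\n",
              nrow(x$values), ncol(x$values), x$unit, x$detect_threshold))
  invisible(x)
}

as_values <- function(m) if (inherits(m, "expr_matrix")) m$values else
  as.matrix(m)

detected <- function(m) {
  if (inherits(m, "expr_matrix")) m$values >= m$detect_threshold & m$values > 0
  else as.matrix(m) > 0
}

# log10 abundance drawn from a wide normal truncated to the configured
# window: log-normal in shape but nearly flat across the window, so the
# realized range matches the configured orders of magnitude and the
# bivariate-noise slope model stays identifiable.
rtrunc_log10 <- function(n, lo, range) {
  out <- numeric(0)
  while (length(out) < n) {
    z <- rnorm(2L * n, lo + range / 2, range)
    out <- c(out, z[z >= lo & z <= lo + range])
  }
  out[seq_len(n)]
}

#' Generate a paired mRNA/protein abundance atlas
#'
#' Implements the generative model the analytics assume: per gene a true
#' log10 mRNA abundance spanning `mrna_log10_range` orders of magnitude;
#' log10 protein = `true_slope` * log10 mRNA + intercept; independent
#' Gaussian noise (SD `noise_sd`) on both log10 axes; a planted fraction of
#' tissue-enriched genes (one tissue `enriched_fold` above all others, in
#' both layers); and protein dropout whose probability is a logistic
#' function of the mRNA abundance rank plus a flat floor, scaled by
#' `dropout_rate`.
#'
#' @param models transcript models from [gen_transcript_models()], or
#'   `NULL` to synthesize gene ids from `config$n_genes` alone (the
#'   abundance model needs only gene identities). lncRNA transcripts, when
#'   present, receive mRNA abundance but no protein row.
#' @param config a [sim_config()].
#' @return list with `mrna` and `protein` ([expression_matrix()]s), `truth`
#'   (per-gene intended class, base abundance, enriched tissue, slope) and
#'   `dropout` (logical genes x tissues matrix of planted protein dropout).
#' @export
gen_abundance_atlas <- function(models, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 202L))
  if (is.null(models)) {
    gene_ids <- sprintf("GENE%05d", seq_len(config$n_genes))
    lnc_ids <- character(0)
  } else {
    m <- models$models %||% models
    gene_ids <- m$gene_id[m$biotype == "protein_coding"]
    lnc_ids <- m$gene_id[m$biotype != "protein_coding"]
  }
  ng <- length(gene_ids)
  nt <- config$n_tissues
  tissues <- sprintf("tissue%02d", seq_len(nt))
  lo <- config$mrna_log10_min

  base <- rtrunc_log10(ng, lo, config$mrna_log10_range)

  # planted tissue-enriched genes, drawn from genes detected everywhere so
  # the fivefold call is recoverable at zero noise
  eligible <- which(base >= log10(1))
  n_enr <- min(round(config$frac_tissue_enriched * ng), length(eligible))
  enr_idx <- if (n_enr > 0) sort(sample_vec(eligible, n_enr)) else integer(0)
  enr_tissue <- rep(NA_integer_, ng)
  enr_tissue[enr_idx] <- sample.int(nt, length(enr_idx), replace = TRUE)

  true_mrna <- matrix(base, ng, nt)
  boost <- log10(config$enriched_fold)
  for (i in enr_idx) true_mrna[i, enr_tissue[i]] <-
      true_mrna[i, enr_tissue[i]] + boost

  noise <- function() matrix(rnorm(ng * nt, 0, config$noise_sd), ng, nt)
  obs_mrna <- true_mrna + noise()

  intercept <- config$protein_log10_min - config$true_slope * lo
  true_prot <- config$true_slope * true_mrna + intercept
  obs_prot <- true_prot + noise()

  # dropout: logistic in the (descending-abundance) rank percentile
  drop <- matrix(FALSE, ng, nt)
  if (config$dropout_rate > 0) {
    rank_pct <- rank(-base, ties.method = "first") / ng
    p <- config$dropout_rate *
      (config$dropout_floor + (1 - config$dropout_floor) *
         plogis((rank_pct - 0.75) / 0.06))
    drop <- matrix(runif(ng * nt) < rep(p, nt), ng, nt)
  }

  prot_vals <- 10^obs_prot
  prot_vals[drop] <- 0
  mrna_vals <- 10^obs_mrna
  dimnames(mrna_vals) <- dimnames(prot_vals) <- list(gene_ids, tissues)
  dimnames(drop) <- list(gene_ids, tissues)

  if (length(lnc_ids)) {
    lnc_base <- rtrunc_log10(length(lnc_ids), lo, config$mrna_log10_range)
    lnc_vals <- 10^(matrix(lnc_base, length(lnc_ids), nt) +
                      matrix(rnorm(length(lnc_ids) * nt, 0,
                                   config$noise_sd),
                             length(lnc_ids), nt))
    rownames(lnc_vals) <- lnc_ids
    mrna_vals <- rbind(mrna_vals, lnc_vals)
  }

  truth <- data.frame(
    gene_id = gene_ids,
    log10_mrna_true = base,
    enriched = seq_len(ng) %in% enr_idx,
    enriched_tissue = ifelse(is.na(enr_tissue), NA_character_,
                             tissues[pmax(enr_tissue, 1L)]),
    class_intended = ifelse(seq_len(ng) %in% enr_idx, "tissue_enriched",
                            ifelse(base >= 0, "expressed_in_all",
                                   "below_detection")),
    slope = config$true_slope,
    dropout_any = rowSums(drop) > 0,
    stringsAsFactors = FALSE)
  truth$enriched_tissue[!truth$enriched] <- NA_character_

  list(mrna = expression_matrix(mrna_vals, "fpkm", 1),
       protein = expression_matrix(prot_vals, "intensity"),
       truth = truth, dropout = drop)
}
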