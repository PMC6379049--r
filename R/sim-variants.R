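#' Generate single-nucleotide protein-affecting variants
#'
#' Emits missense and nonsense point mutations in the CDS of the supplied
#' transcript models with zygosity labels. I<->L exchanges are never emitted
#' (indistinguishable by mass spectrometry). Protein-level annotation
#' (1-based residue index, reference and alternate amino acid) is consistent
#' with the transcript translation by construction and is re-checked before
#' returning.
#'
#' @param models output of [gen_transcript_models()] (or its `models`
#'   data.frame).
#' @param config a [sim_config()]; `config$variant_counts` gives the number
#'   of heterozygous missense, homozygous missense and nonsense variants.
#' @return data.frame with gene/transcript ids, genomic coordinates (1-based
#'   on the synthetic chromosome), ref/alt bases, `protein_pos`, `ref_aa`,
#'   `alt_aa` (`"*"` for nonsense), `zygosity` and `effect`.
#' @export
gen_variant_set <- function(models, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- models$models %||% models
  set.seed(child_seed(config$seed, 303L))
  coding <- m[m$biotype == "protein_coding", , drop = FALSE]
  if (!nrow(coding)) stop("no coding transcripts to mutate")
  counts <- config$variant_counts
  want <- c(rep("missense_het", counts$missense_het),
            rep("missense_hom", counts$missense_hom),
            rep("nonsense", counts$nonsense))
  if (!length(want)) return(empty_variants())

  code <- Biostrings::GENETIC_CODE
  out <- vector("list", length(want))
  used <- character(0)  # transcript:codon slots already mutated
  guard <- 0L
  i <- 1L
  while (i <= length(want)) {
    guard <- guard + 1L
    if (guard > 200L * length(want))
      stop("requested variant counts exceed available codon positions")
    r <- coding[sample.int(nrow(coding), 1L), ]
    n_cod <- (r$cds_end - r$utr5_end) %/% 3L
    if (n_cod < 4L) next
    ci <- sample(2:(n_cod - 1L), 1L)      # spare initiator and last codon
    slot <- paste(r$transcript_id, ci)
    if (slot %in% used) next
    cds_off <- r$utr5_end + 3L * (ci - 1L)
    codon <- substr(r$sequence, cds_off + 1L, cds_off + 3L)
    ref_aa <- unname(code[codon])
    nonsense <- grepl("nonsense", want[i])
    # enumerate single-base substitutions of this codon
    subs <- list()
    for (pos in 1:3) for (b in setdiff(BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      aa <- unname(code[alt])
      ok <- if (nonsense) aa == "*" else
        (aa != "*" && aa != ref_aa &&
           !(ref_aa %in% c("I", "L") && aa %in% c("I", "L")))
      if (ok) subs[[length(subs) + 1L]] <- list(pos = pos, base = b, aa = aa)
    }
    if (!length(subs)) next
    s <- subs[[sample.int(length(subs), 1L)]]
    used <- c(used, slot)
    zyg <- if (want[i] == "missense_hom") "hom" else
      if (want[i] == "missense_het") "het" else sample(c("het", "hom"), 1L)
    tx_pos0 <- cds_off + s$pos - 1L       # 0-based within transcript
    out[[i]] <- data.frame(
      gene_id = r$gene_id, transcript_id = r$transcript_id,
      chrom = r$chrom, pos = r$chrom_start + tx_pos0,
      ref = substr(codon, s$pos, s$pos), alt = s$base,
      protein_pos = ci, ref_aa = ref_aa, alt_aa = s$aa,
      zygosity = zyg,
      effect = if (nonsense) "nonsense" else "missense",
      stringsAsFactors = FALSE)
    i <- i + 1L
  }
  v <- do.call(rbind, out)
  v$variant_id <- sprintf("%s:%s%d%s", v$transcript_id, v$ref_aa,
                          v$protein_pos, v$alt_aa)
  # consistency check: the mutated CDS must translate to the annotated alt
  for (j in seq_len(nrow(v))) {
    r <- m[m$transcript_id == v$transcript_id[j], ]
    seq <- r$sequence
    tx0 <- v$pos[j] - r$chrom_start
    substr(seq, tx0 + 1L, tx0 + 1L) <- v$alt[j]
    aa <- translate_nt(substr(seq, r$utr5_end + 1L, r$cds_end),
                       initiator = TRUE, stop_at_first = FALSE)
    got <- substr(aa, v$protein_pos[j], v$protein_pos[j])
    if (got != v$alt_aa[j])
      stop("internal error: planted variant does not translate to alt aa")
  }
  rownames(v) <- NULL
  v
}

empty_variants <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             chrom = character(), pos = integer(), ref = character(),
             alt = character(), protein_pos = integer(),
             ref_aa = character(), alt_aa = character(),
             zygosity = character(), effect = character(),
             variant_id = character(), stringsAsFactors = FALSE)
}
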