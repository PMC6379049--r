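# small fixtures shared across test files; everything is built in code

small_config <- function(seed = 7, ...) {
  sim_config(n_genes = 40L, n_tissues = 6L, seed = seed, frac_atis = 0.5,
             variant_counts = list(missense_het = 8L, missense_hom = 5L,
                                   nonsense = 3L), n_lncrna = 3L, ...)
}

# one-row transcript model with explicit regions (DNA spelling)
toy_model <- function(utr5, cds, utr3 = "", transcript_id = "TXT1",
                      gene_id = "GT1") {
  seq <- paste0(utr5, cds, utr3)
  data.frame(transcript_id = transcript_id, gene_id = gene_id,
             biotype = "protein_coding", sequence = seq,
             utr5_end = nchar(utr5), cds_end = nchar(utr5) + nchar(cds),
             chrom = "chrS", chrom_start = 1L, stringsAsFactors = FALSE)
}

# tiny hand-built protein database with one canonical + variant entries
toy_entry <- function(accession, sequence, source_db, gene_id = "G1",
                      transcript_id = "T1", locus_id = gene_id,
                      var_pos = NA, var_ref = NA, var_alt = NA,
                      var_effect = NA, var_zygosity = NA) {
  df <- data.frame(accession = accession, sequence = sequence,
                   source_db = source_db, gene_id = gene_id,
                   transcript_id = transcript_id, locus_id = locus_id,
                   var_pos = var_pos, var_ref = var_ref,
                   var_alt = var_alt, var_effect = var_effect,
                   var_zygosity = var_zygosity,
                   atis_offset = NA_integer_, atis_codon = NA_character_,
                   atis_frame = NA_character_, atis_event = NA_character_,
                   stringsAsFactors = FALSE)
  df
}

# minimal passing candidate_set wrapping one PSM (for the homology oracle)
new_cand_for_test <- function(pep) {
  rec <- cbind(toy_psm(pep), c1 = TRUE, c2 = TRUE, c3 = TRUE, c4 = TRUE,
               c5 = TRUE, c6 = TRUE, pass = TRUE, first_fail = "",
               stringsAsFactors = FALSE)
  structure(list(role = "variant", records = rec, thresholds = list()),
            class = "candidate_set")
}

sample_random_cds <- function(n_cod) {
  pool <- setdiff(as.vector(outer(as.vector(outer(
    c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0)), c("TAA", "TAG", "TGA"))
  paste(sample(pool, n_cod, replace = TRUE), collapse = "")
}

toy_psm <- function(peptide, ion = 40, delta = 20, mods = "",
                    file = "f.mgf", scan = 1L) {
  data.frame(spectrum_file = file, scan = scan, peptide = peptide,
             mods = mods, charge = 2L, ion_score = ion,
             delta_score = delta, proteins = "", stringsAsFactors = FALSE)
}
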