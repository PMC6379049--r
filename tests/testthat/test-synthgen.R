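test_that("transcript models are deterministic and structurally valid", {
  cfg <- small_config()
  tx1 <- gen_transcript_models(cfg)
  tx2 <- gen_transcript_models(cfg)
  expect_identical(tx1, tx2)

  d1 <- tempfile(); d2 <- tempfile()
  write_transcript_bundle(tx1, d1)
  write_transcript_bundle(tx2, d2)
  for (f in c("genome.fa", "transcripts.fa", "transcripts.gtf")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }

  m <- tx1$models[tx1$models$biotype == "protein_coding", ]
  for (i in seq_len(nrow(m))) {
    cds <- substr(m$sequence[i], m$utr5_end[i] + 1L, m$cds_end[i])
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_equal(nchar(cds) %% 3L, 0L)
    aa <- translate_nt(cds, initiator = TRUE, stop_at_first = FALSE)
    # exactly one stop, at the very end
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1L), fixed = TRUE))
  }
})

test_that("impossible length constraints are rejected", {
  expect_error(sim_config(cds_range = c(3L, 5L)), "CDS")
  expect_error(sim_config(dropout_rate = 1.5), "probabilities")
  expect_error(sim_config(mrna_log10_range = 0), "ranges")
})

test_that("planted aTIS ground truth is exactly recovered by the scanner", {
  cfg <- small_config(seed = 11)
  tx <- gen_transcript_models(cfg)
  truth <- tx$atis_truth
  expect_gt(nrow(truth), 0)
  canon <- build_canonical_db(tx)
  for (i in seq_len(nrow(truth))) {
    m <- tx$models[tx$models$transcript_id == truth$transcript_id[i], ]
    found <- scan_atis_sites(m)
    if (truth$kept[i]) {
      # the scan output equals the planted truth: same single site
      expect_equal(nrow(found), 1L)
      expect_equal(found$start_offset, truth$offset[i])
      expect_identical(found$start_codon, truth$codon[i])
      expect_identical(found$frame, truth$frame[i])
      expect_identical(found$event, truth$event[i])
      if (found$event == "extension") {
        parent <- canon$sequence[canon$transcript_id == m$transcript_id]
        expect_equal(nchar(found$sequence) - nchar(parent),
                     truth$extra_aa[i])
      }
    } else {
      expect_equal(nrow(found), 0L)
    }
  }
  # unplanted models yield no aTIS hits (UTRs were scrubbed)
  clean <- setdiff(tx$models$transcript_id[tx$models$biotype ==
                                             "protein_coding"],
                   truth$transcript_id)
  for (tid in head(clean, 5)) {
    m <- tx$models[tx$models$transcript_id == tid, ]
    expect_equal(nrow(scan_atis_sites(m)), 0L)
  }
})

test_that("abundance atlas matches its generative model", {
  cfg <- sim_config(n_genes = 2000L, n_tissues = 4L, seed = 3,
                    true_slope = 2, mrna_log10_range = 4,
                    noise_sd = 0.25, frac_tissue_enriched = 0,
                    dropout_rate = 0)
  at <- gen_abundance_atlas(NULL, cfg)
  lm_ <- log10(at$mrna$values[, 1])
  lp <- log10(at$protein$values[, 1])
  span99 <- function(x) diff(quantile(x, c(0.005, 0.995), names = FALSE))
  # realized dynamic ranges match the configured orders of magnitude
  expect_lt(abs(span99(lm_) - 4), 0.5)
  expect_lt(abs(span99(lp) - cfg$protein_log10_range), 0.5)
  # no dropout configured by default here
  cfg0 <- sim_config(n_genes = 500L, n_tissues = 3L, seed = 5,
                     dropout_rate = 0)
  at0 <- gen_abundance_atlas(NULL, cfg0)
  det_m <- at0$mrna$values[rownames(at0$protein$values), ] >= 1
  expect_true(all(at0$protein$values[det_m] > 0))
})

test_that("planted tissue-enriched genes are exactly recovered at zero noise", {
  cfg <- sim_config(n_genes = 1000L, n_tissues = 8L, seed = 21,
                    noise_sd = 0, frac_tissue_enriched = 0.05,
                    dropout_rate = 0)
  at <- gen_abundance_atlas(NULL, cfg)
  calls <- classify_specificity(at$mrna)
  called <- calls$gene_id[calls$category == "tissue_enriched"]
  planted <- at$truth$gene_id[at$truth$enriched]
  expect_equal(length(planted), 50L)
  expect_setequal(called, planted)
  # and the supporting tissue is the planted one
  sup <- calls$supporting_tissues[match(planted, calls$gene_id)]
  expect_identical(sup, at$truth$enriched_tissue[at$truth$enriched])
})

test_that("variant generator honours counts, labels and the I/L exclusion", {
  cfg <- small_config(seed = 13)
  tx <- gen_transcript_models(cfg)
  v <- gen_variant_set(tx, cfg)
  expect_equal(nrow(v), 16L)
  expect_equal(sum(v$effect == "missense" & v$zygosity == "het"), 8L)
  expect_equal(sum(v$effect == "missense" & v$zygosity == "hom"), 5L)
  expect_equal(sum(v$effect == "nonsense"), 3L)
  expect_true(all(v$alt_aa[v$effect == "nonsense"] == "*"))
  expect_true(all(v$ref_aa != v$alt_aa))

  # missense consistency: mutated CDS translates to the alt residue
  for (i in which(v$effect == "missense")) {
    m <- tx$models[tx$models$transcript_id == v$transcript_id[i], ]
    seq <- m$sequence
    substr(seq, v$pos[i] - m$chrom_start + 1L,
           v$pos[i] - m$chrom_start + 1L) <- v$alt[i]
    aa <- translate_nt(substr(seq, m$utr5_end + 1L, m$cds_end),
                       initiator = TRUE)
    expect_identical(substr(aa, v$protein_pos[i], v$protein_pos[i]),
                     v$alt_aa[i])
  }

  # I/L exchanges never emitted, across many draws
  big_cfg <- sim_config(n_genes = 150L, n_tissues = 3L, seed = 17,
                        frac_atis = 0,
                        variant_counts = list(missense_het = 500L,
                                              missense_hom = 400L,
                                              nonsense = 50L))
  big_tx <- gen_transcript_models(big_cfg)
  big_v <- gen_variant_set(big_tx, big_cfg)
  expect_equal(nrow(big_v), 950L)
  expect_false(any(big_v$ref_aa %in% c("I", "L") &
                     big_v$alt_aa %in% c("I", "L")))
})

test_that("planted PSM flags land on the right side of the thresholds", {
  cfg <- small_config(seed = 19)
  tx <- gen_transcript_models(cfg)
  v <- gen_variant_set(tx, cfg)
  canon <- build_canonical_db(tx)
  db <- rbind(canon, suppressWarnings(build_variant_db(canon, v)))
  planted <- plant_candidate_peptides(
    db, c(pass = 4L, fail_ion = 3L, fail_delta = 3L, fail_map = 2L),
    seed = 19)
  psms <- gen_psm_tables(db, planted, cfg, n_background = 40L)
  a <- psms$engine_a
  pl <- a[a$planted_flag != "", ]
  expect_true(all(pl$ion_score[pl$planted_flag == "pass"] >= 25 &
                    pl$delta_score[pl$planted_flag == "pass"] >= 10))
  expect_true(all(pl$ion_score[pl$planted_flag == "fail_ion"] < 25))
  expect_true(all(pl$delta_score[pl$planted_flag == "fail_ion"] >= 10))
  expect_true(all(pl$delta_score[pl$planted_flag == "fail_delta"] < 10))
  expect_true(all(pl$ion_score[pl$planted_flag == "fail_delta"] >= 25))
  # deterministic
  psms2 <- gen_psm_tables(db, planted, cfg, n_background = 40L)
  expect_identical(psms, psms2)
})

test_that("spectrum pairs hit their SA target and rerun byte-identically", {
  pair0 <- gen_spectrum_pair("ELVISLIVESK", distortion = 0, seed = 4)
  frags <- theoretical_fragments("ELVISLIVESK")
  v_e <- match_peaks(pair0$endogenous, frags)$intensity
  v_r <- match_peaks(pair0$reference, frags)$intensity
  expect_equal(spectral_contrast_angle(v_e, v_r), 1.0, tolerance = 1e-9)

  pair <- gen_spectrum_pair("ELVISLIVESK", distortion = 0.3, seed = 4)
  v_e <- match_peaks(pair$endogenous, frags)$intensity
  sa <- spectral_contrast_angle(v_e, v_r0 <- match_peaks(pair$reference,
                                                         frags)$intensity)
  expect_equal(sa, 0.7, tolerance = 1e-4)
  # SA 0.7 corresponds to cosine ~0.89 on the matched vectors
  cosine <- sum(v_e * v_r0) / sqrt(sum(v_e^2) * sum(v_r0^2))
  expect_equal(cosine, cos(0.15 * pi), tolerance = 1e-4)

  f1 <- tempfile(fileext = ".mgf"); f2 <- tempfile(fileext = ".mgf")
  write_mgf(list(pair$endogenous, pair$reference), f1)
  pairb <- gen_spectrum_pair("ELVISLIVESK", distortion = 0.3, seed = 4)
  write_mgf(list(pairb$endogenous, pairb$reference), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(gen_spectrum_pair("ELVISLIVESK", mods = "3|phospho"),
               "phospho")
  expect_error(gen_spectrum_pair("AGK"), "at least 5")
})
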