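# toy search space: canonical M K T A Y R A G K D D W K (1..13)
toy_db <- function() {
  canon <- toy_entry("T1:canon", "MKTAYRAGKDDWK", "canonical",
                     gene_id = "G1", transcript_id = "T1")
  v_mis <- toy_entry("T1:A4V", "MKTVYRAGKDDWK", "variant",
                     gene_id = "G1", transcript_id = "T1",
                     var_pos = 4L, var_ref = "A", var_alt = "V",
                     var_effect = "missense", var_zygosity = "het")
  v_clv <- toy_entry("T1:D10K", "MKTAYRAGKKDWK", "variant",
                     gene_id = "G1", transcript_id = "T1",
                     var_pos = 10L, var_ref = "D", var_alt = "K",
                     var_effect = "missense", var_zygosity = "hom")
  v_non <- toy_entry("T1:W12*", "MKTAYRAGKDD", "variant",
                     gene_id = "G1", transcript_id = "T1",
                     var_pos = 12L, var_ref = "W", var_alt = "*",
                     var_effect = "nonsense", var_zygosity = "het")
  rbind(canon, v_mis, v_clv, v_non)
}

toy_variants <- function() {
  data.frame(gene_id = "G1", transcript_id = "T1",
             protein_pos = c(4L, 10L, 12L),
             ref_aa = c("A", "D", "W"), alt_aa = c("V", "K", "*"),
             zygosity = c("het", "hom", "het"),
             effect = c("missense", "missense", "nonsense"),
             variant_id = c("T1:A4V", "T1:D10K", "T1:W12*"),
             stringsAsFactors = FALSE)
}

test_that("peptide mapping collapses I/L and deduplicates loci", {
  db <- rbind(toy_entry("E1", "MAGAILKDDR", "canonical", gene_id = "GA"),
              toy_entry("E2", "MQQALLKWWR", "canonical", gene_id = "GB"),
              toy_entry("E3", "MAGAILKDDR", "sample_rna", gene_id = "GA"))
  mp <- map_peptides("AILK", db)
  expect_setequal(mp$matches$accession, c("E1", "E2", "E3"))
  s <- mp$summary
  expect_equal(s$n_loci, 2L)  # GA (twice) and GB
  expect_identical(s$source_dbs, "canonical,sample_rna")
  expect_error(map_peptides("AILK", db[0, ]), "empty database")

  # digestion-aware mapping requires enzymatic termini
  mp_t <- map_peptides("AGAILK", db, enzyme = "trypsin")
  expect_equal(nrow(mp_t$matches), 0L)   # starts mid-sequence, no K/R before
  mp_t2 <- map_peptides("MAGAILK", db, enzyme = "trypsin")
  expect_setequal(mp_t2$matches$accession, c("E1", "E3"))
})

test_that("variant criteria (i)-(vi) pass and fail as printed", {
  db <- toy_db()
  run1 <- function(psm) filter_variant_candidates(psm, db)$records

  # clean pass through (i)-(v): shows the variant residue
  r <- run1(toy_psm("TVYR"))
  expect_true(r$pass)
  expect_identical(r$first_fail, "")

  # (i) ion score 24.9 fails first
  r <- run1(toy_psm("TVYR", ion = 24.9))
  expect_false(r$pass); expect_identical(r$first_fail, "c1")
  # (ii) delta 9.9
  r <- run1(toy_psm("TVYR", delta = 9.9))
  expect_identical(r$first_fail, "c2")
  # (iii) peptide also in the canonical database
  r <- run1(toy_psm("AGK"))
  expect_identical(r$first_fail, "c3")
  # (v) cleavage branch: N-terminus created by the novel K
  r <- run1(toy_psm("DWK"))
  expect_true(r$pass)
  # (vi) nonsense: ends at the novel C-terminus
  r <- run1(toy_psm("DD"))
  expect_true(r$pass)
  # (vi) with a missed cleavage still ends at the novel C-terminus
  r <- run1(toy_psm("AGKDD"))
  expect_true(r$pass)

  # (iv) two variant entries at different loci
  db2 <- rbind(db, toy_entry("T9:X", "MRTVYR", "variant",
                             gene_id = "G9", transcript_id = "T9",
                             var_pos = 4L, var_ref = "A", var_alt = "V",
                             var_effect = "missense",
                             var_zygosity = "het"))
  r <- filter_variant_candidates(toy_psm("TVYR"), db2)$records
  expect_identical(r$first_fail, "c4")
  expect_error(filter_variant_candidates(toy_psm("TVYR"), db,
                                         enzyme = "nope"), "unknown")
})

test_that("canonical counterparts require the wild-type residue", {
  db <- toy_db(); v <- toy_variants()
  run1 <- function(psm)
    filter_canonical_counterparts(psm, db, v)$records

  # wild-type residue shown, canonical mapping, scores fine
  r <- run1(toy_psm("TAYR"))
  expect_true(r$pass)
  expect_identical(r$variant_ids, "T1:A4V")

  # peptide mapping only to the variant database fails (iii)
  r <- run1(toy_psm("TVYR"))
  expect_identical(r$first_fail, "c3")

  # nonsense counterpart: must extend past the novel C-terminus
  r <- run1(toy_psm("DDWK"))
  expect_true(r$pass)
  expect_true(grepl("T1:W12", r$variant_ids))
  r <- run1(toy_psm("MKTAYR"))  # covers A4 with ref: pass via missense
  expect_true(r$pass)
})

test_that("novel-candidate criteria follow the printed order", {
  db <- rbind(
    toy_entry("T1:canon", "MKTAYRAGKDDWK", "canonical",
              transcript_id = "T1"),
    toy_entry("TA:atis:0", "MWWPPQQKMKTAYR", "atis",
              gene_id = "GA", transcript_id = "TA"),
    toy_entry("TL:f0:1", "MEEPPTTK", "lncrna", gene_id = "GL",
              transcript_id = "TL"))
  db$atis_offset[2] <- 0L; db$atis_codon[2] <- "GUG"
  fpkm <- matrix(c(5, 0.5), 2, 1, dimnames = list(c("TA", "TL"), "t1"))

  res <- filter_novel_candidates(toy_psm("MWWPPQQK"), db, fpkm, "atis")
  expect_true(res$records$pass)

  # (i): peptide matching another database too
  res <- filter_novel_candidates(toy_psm("MKTAYR"), db, fpkm, "atis")
  expect_identical(res$records$first_fail, "c1")
  # (ii)/(iii): scores
  res <- filter_novel_candidates(toy_psm("MWWPPQQK", ion = 20), db, fpkm,
                                 "atis")
  expect_identical(res$records$first_fail, "c2")
  # (iv): FPKM exactly 1 fails the strict cutoff
  fpkm1 <- fpkm; fpkm1["TA", 1] <- 1.0
  res <- filter_novel_candidates(toy_psm("MWWPPQQK"), db, fpkm1, "atis")
  expect_identical(res$records$first_fail, "c4")
  # lncRNA role with unexpressed parent
  res <- filter_novel_candidates(toy_psm("MEEPPTTK"), db, fpkm, "lncrna")
  expect_identical(res$records$first_fail, "c4")
})

test_that("engine intersection keys on the modified peptide", {
  db <- toy_db()
  psms_a <- rbind(toy_psm("TVYR", scan = 1L), toy_psm("TVYR", scan = 2L),
                  toy_psm("DWK", scan = 3L))
  set_a <- filter_variant_candidates(psms_a, db)
  b <- data.frame(spectrum_file = "b.mgf", scan = 9L, peptide = "TVYR",
                  mods = "", charge = 2L, score = 150, proteins = "",
                  stringsAsFactors = FALSE)
  both <- intersect_engines(set_a, b)
  expect_equal(nrow(both$records), 1L)  # DWK absent from B; TVYR deduped
  expect_identical(both$records$peptide, "TVYR")
  expect_true(grepl("f.mgf:1;f.mgf:2", both$records$spectra_a))

  # engine-B score floor (missing-protein profile)
  b_low <- b; b_low$score <- 80
  expect_equal(nrow(intersect_engines(set_a, b_low,
                                      b_score_min = 100)$records), 0L)
  empty <- filter_variant_candidates(toy_psm("TVYR", ion = 1), db)
  expect_equal(nrow(intersect_engines(empty, b)$records), 0L)
})

test_that("homology exclusion drops near-canonical candidates", {
  db <- toy_db()
  canon <- db[db$source_db == "canonical", ]
  set_a <- filter_variant_candidates(toy_psm("TVYR"), db)
  kept <- homology_exclude(set_a, canon, max_mismatches = 0L)
  expect_true(kept$records$pass)  # TVYR differs from TAYR
  dropped <- homology_exclude(set_a, canon, max_mismatches = 1L)
  expect_false(dropped$records$pass)
  expect_identical(dropped$records$first_fail, "homology")
  expect_identical(dropped$records$homology_hit, "T1:canon")

  # brute-force minimum-Hamming oracle on random windows
  set.seed(11)
  aa <- c("A", "C", "D", "E", "G", "K", "R", "S", "T", "V")
  ch <- function(x) strsplit(x, "")[[1]]
  for (rep in 1:10) {
    seqs <- replicate(3, paste(sample(aa, 30, TRUE), collapse = ""))
    cdb <- do.call(rbind, lapply(1:3, function(i)
      toy_entry(paste0("C", i), seqs[i], "canonical")))
    pep <- paste(sample(aa, 6, TRUE), collapse = "")
    mind <- min(vapply(seqs, function(s) {
      w <- vapply(1:(nchar(s) - 5L), function(i)
        sum(ch(substr(s, i, i + 5L)) != ch(pep)), 0L)
      min(w)
    }, 0L))
    fake <- new_cand_for_test(pep)
    out <- homology_exclude(fake, cdb, max_mismatches = 1L)
    expect_identical(out$records$pass, mind > 1L)
  }
})

test_that("HPP guideline needs two distinct peptides of nine residues", {
  df <- data.frame(protein = c("P1", "P1", "P2", "P2", "P3", "P3"),
                   peptide = c("AAAAAAAAA", "CCCCCCCCCCCC",  # 9, 12
                               "DDDDDDDD", "EEEEEEEEEEEEEEE", # 8, 15
                               "GGGGGGGGG", "GGGGGGGGG"),     # dup
                   stringsAsFactors = FALSE)
  out <- hpp_guideline_check(df)
  expect_true(out$hpp_pass[out$protein == "P1"])
  expect_false(out$hpp_pass[out$protein == "P2"])
  expect_false(out$hpp_pass[out$protein == "P3"])
})

test_that("start codons are inferred exactly only from acetylated N-termini", {
  entry <- list(sequence = "MATTQISKDELDELK", start_codon = "GUG")
  # acetyl peptide at position 1: exact
  out <- infer_start_codon("MATTQISK", entry, acetylated = TRUE)
  expect_identical(out$codon, "GUG"); expect_true(out$exact)
  # acetyl peptide at position 2 with Met start: exact via Met excision
  out <- infer_start_codon("ATTQISK", entry, acetylated = TRUE)
  expect_true(out$exact)
  # internal non-acetylated peptide: tentative
  out <- infer_start_codon("DELDELK", entry, acetylated = FALSE)
  expect_false(out$exact)
  expect_identical(out$codon, "GUG")
  expect_error(infer_start_codon("WWWWW", entry, TRUE), "not contained")
})

test_that("filters are monotone and recover the planted truth table", {
  cfg <- small_config(seed = 23)
  tx <- gen_transcript_models(cfg)
  v <- gen_variant_set(tx, cfg)
  canon <- build_canonical_db(tx)
  db <- rbind(canon, suppressWarnings(build_variant_db(canon, v)))
  planted <- plant_candidate_peptides(
    db, c(pass = 5L, fail_ion = 3L, fail_delta = 3L, fail_map = 3L),
    seed = 23)
  psms <- gen_psm_tables(db, planted, cfg, n_background = 60L)

  cand <- filter_variant_candidates(psms$engine_a, db)
  rec <- cand$records

  # 100% truth-table recovery with the recorded first failure
  pl <- rec[rec$planted_flag != "", ]
  expect_true(all(pl$pass[pl$planted_flag == "pass"]))
  expect_true(all(pl$first_fail[pl$planted_flag == "fail_ion"] == "c1"))
  expect_true(all(pl$first_fail[pl$planted_flag == "fail_delta"] == "c2"))
  expect_true(all(pl$first_fail[pl$planted_flag == "fail_map"] == "c3"))
  expect_equal(sum(pl$pass), 5L)

  # audit conservation: input = pass + sum of first failures
  expect_equal(nrow(rec), sum(rec$pass) + sum(rec$first_fail != ""))

  # monotone in the thresholds: relaxing never shrinks the passing set
  loose <- filter_variant_candidates(psms$engine_a, db, score_min = 15,
                                     delta_min = 5)$records
  expect_true(all(rec$peptide[rec$pass] %in%
                    loose$peptide[loose$pass]))
})
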