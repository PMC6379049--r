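test_that("translation follows the standard code with initiator-Met", {
  m <- toy_model("", "ATGGCTTAA")
  expect_identical(translate_cds(m), "MA")
  # RNA spelling accepted
  expect_identical(translate_nt("AUGGCUUAA"), "MA")
  # near-cognate initiator rendered as Met
  m2 <- toy_model("", "GTGGCTAAATAA")
  expect_identical(translate_cds(m2), "MAK")
  expect_error(translate_cds(toy_model("CCC", "")), "empty CDS")

  # oracle: Biostrings translation on random coding sequences
  set.seed(8)
  for (i in 1:5) {
    n_cod <- sample(10:40, 1)
    s <- paste0("ATG", sample_random_cds(n_cod), "TGA")
    expect_identical(
      translate_nt(s, stop_at_first = FALSE),
      as.character(Biostrings::translate(Biostrings::DNAString(s))))
  }
})

test_that("sample database applies the strict FPKM cutoff and collapses duplicates", {
  models <- rbind(toy_model("", "ATGGCTTAA", transcript_id = "T1",
                            gene_id = "G1"),
                  toy_model("CCC", "ATGGCTTAA", transcript_id = "T2",
                            gene_id = "G2"),
                  toy_model("", "ATGAAGTAA", transcript_id = "T3",
                            gene_id = "G3"))
  fpkm <- matrix(c(0.5, 1.0, 2.0), 3, 1,
                 dimnames = list(c("T1", "T2", "T3"), "t1"))
  db <- build_sample_db(models, fpkm, fpkm_cutoff = 1)
  expect_equal(nrow(db), 1L)        # strict >: only FPKM 2.0
  expect_identical(db$transcript_id, "T3")

  db0 <- build_sample_db(models, fpkm, fpkm_cutoff = 0)
  # T1 and T2 translate identically -> collapsed with merged header
  expect_equal(nrow(db0), 2L)
  merged <- db0[grepl("\\|", db0$accession), ]
  expect_identical(merged$transcript_id, "T1|T2")
})

test_that("variant database substitutes, truncates and rejects I/L", {
  canon <- toy_entry("P1:canon", "MKTAYR", "canonical",
                     transcript_id = "P1")
  mk_var <- function(pos, ref, alt, effect, id) {
    data.frame(gene_id = "G1", transcript_id = "P1", protein_pos = pos,
               ref_aa = ref, alt_aa = alt, zygosity = "het",
               effect = effect, variant_id = id, stringsAsFactors = FALSE)
  }
  v <- rbind(mk_var(4L, "A", "V", "missense", "P1:A4V"),
             mk_var(5L, "Y", "*", "nonsense", "P1:Y5*"),
             mk_var(3L, "T", "I", "missense", "P1:T3I"))
  db <- suppressWarnings(build_variant_db(canon, v))
  expect_identical(db$sequence[db$accession == "P1:A4V"], "MKTVYR")
  expect_identical(db$sequence[db$accession == "P1:Y5*"], "MKTA")

  # I -> L rejected with explicit reason
  vil <- mk_var(2L, "I", "L", "missense", "PX:I2L")
  canon2 <- toy_entry("PX:canon", "MIKA", "canonical",
                      transcript_id = "PX")
  expect_warning(out <- build_variant_db(canon2, vil),
                 "I/L.*rejected|rejected.*I/L")
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(attr(out, "rejected")), 1L)

  expect_error(suppressWarnings(
    build_variant_db(canon, mk_var(99L, "A", "V", "missense", "P1:A99V"))),
    "out of range")
})

test_that("aTIS scanning finds planted starts with correct events", {
  # in-frame GTG planted 21 nt upstream: extension of exactly 7 residues
  utr <- paste0("GTG", strrep("C", 18))
  m <- toy_model(utr, "ATGGCTGAATAA")
  hits <- scan_atis_sites(m)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start_offset, 0L)
  expect_identical(hits$start_codon, "GUG")
  expect_identical(hits$frame, "in_frame")
  expect_identical(hits$event, "extension")
  canonical <- translate_cds(m)
  expect_equal(nchar(hits$sequence) - nchar(canonical), 7L)
  expect_identical(hits$sequence, paste0("MPPPPPP", canonical))

  # product of exactly 6 aa excluded, 7 aa included
  utr6 <- paste0("ATG", strrep("AAA", 4), "TAA", "CCC")  # M + 4K = 5 aa
  utr7 <- paste0("ATG", strrep("AAA", 6), "TAA", "CCC")  # M + 6K = 7 aa
  m6 <- toy_model(utr6, "ATGGCTGAATAA")
  m7 <- toy_model(utr7, "ATGGCTGAATAA")
  expect_equal(nrow(scan_atis_sites(m6)), 0L)
  h7 <- scan_atis_sites(m7)
  expect_equal(nrow(h7), 1L)
  expect_identical(h7$event, "uorf")
  expect_equal(nchar(h7$sequence), 7L)

  # no AUG in the UTR, AUG-only codon set: empty result
  m_empty <- toy_model(strrep("C", 12), "ATGGCTGAATAA")
  expect_equal(nrow(scan_atis_sites(m_empty, codon_set = "AUG")), 0L)

  # out-of-frame start running into the CDS: frameshift
  utr_fs <- paste0("C", "GTG", strrep("C", 17))  # offset 1, 21-nt UTR
  m_fs <- toy_model(utr_fs, "ATGGCTGAATAA", "TAACCC")
  h_fs <- scan_atis_sites(m_fs)
  expect_equal(nrow(h_fs), 1L)
  expect_identical(h_fs$frame, "out_of_frame")
  expect_identical(h_fs$event, "frameshift")
})

test_that("aTIS event classification covers downstream and mixed labels", {
  m <- toy_model(strrep("C", 12), "ATGGCTAAAGCTGAATAA")
  entry <- data.frame(transcript_id = m$transcript_id,
                      start_offset = m$utr5_end + 9L,
                      sequence = "ME", stringsAsFactors = FALSE)
  expect_identical(classify_atis_event(entry, m), "downstream_n_terminus")
  expect_error(classify_atis_event(
    data.frame(transcript_id = "OTHER", start_offset = 0L, sequence = "M"),
    m), "mismatch")
  ev <- atis_gene_events(data.frame(
    gene_id = c("g1", "g1", "g2"),
    event = c("extension", "uorf", "extension")))
  expect_identical(ev$event[ev$gene_id == "g1"], "mixed")
  expect_identical(ev$event[ev$gene_id == "g2"], "extension")
})

test_that("three-frame translation round-trips its fragments", {
  fr <- three_frame_translate("ATGAAATAG", min_length_aa = 2L)
  expect_true("MK" %in% fr$sequence)
  expect_equal(fr$frame[fr$sequence == "MK"], 0L)

  # length-3 sequence: at most one fragment, frames 1-2 empty
  fr3 <- three_frame_translate("ATG", min_length_aa = 1L)
  expect_true(all(fr3$frame == 0L))
  expect_lte(nrow(fr3), 1L)

  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  fr <- three_frame_translate(s, min_length_aa = 5L)
  for (i in seq_len(nrow(fr))) {
    nt <- substr(s, fr$nt_start[i], fr$nt_end[i])
    expect_identical(translate_nt(nt, stop_at_first = FALSE),
                     fr$sequence[i])
  }
})

test_that("digestion obeys hand-enumerated oracles and concatenation", {
  d0 <- digest("MKAGRS", "trypsin", max_missed = 0L)
  expect_identical(d0$peptide, c("MK", "AGR", "S"))
  expect_true(all(d0$missed == 0L))

  d1 <- digest("MKAGRS", "trypsin", max_missed = 1L)
  expect_setequal(d1$peptide, c("MK", "AGR", "S", "MKAGR", "AGRS"))
  expect_equal(sort(d1$missed[d1$peptide %in% c("MKAGR", "AGRS")]),
               c(1L, 1L))

  # no cleavage sites: the whole protein at 0 missed
  dn <- digest("MAGAGA", "trypsin")
  expect_identical(dn$peptide, "MAGAGA")
  expect_equal(dn$missed, 0L)

  # N-terminal cutter
  da <- digest("MKDAD", "aspn", max_missed = 0L)
  expect_identical(da$peptide, c("MK", "DA", "D"))

  # chymotrypsin C-terminal of F/Y/L/W/M
  dc <- digest("MAFAYA", "chymotrypsin", max_missed = 0L)
  expect_identical(dc$peptide, c("M", "AF", "AY", "A"))

  # concatenation property across enzymes on random proteins
  set.seed(10)
  for (enz in names(enzyme_rules())) {
    prot <- paste(sample(c("A", "C", "D", "E", "F", "G", "K", "L", "M",
                           "R", "S", "W", "Y"), 80, replace = TRUE),
                  collapse = "")
    d <- digest(prot, enz, max_missed = 0L)
    expect_identical(paste(d$peptide, collapse = ""), prot)
    # start/end bookkeeping
    expect_true(all(substring(prot, d$start, d$end) == d$peptide))
  }
  expect_error(digest("MK", "pepsinX"), "unknown enzyme")
})
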