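#' Standard genetic code translation of a nucleotide string
#'
#' Low-level translator used by all database-construction steps. Translation
#' proceeds codon by codon from the first base of `seq` and, by default,
#' stops at (and excludes) the first stop codon. Any codon from the
#' configured start-codon set is translated as methionine when
#' `initiator = TRUE`, reflecting initiator-tRNA behaviour at near-cognate
#' starts (GUG/UUG/CUG/GCG initiation yields an N-terminal Met).
#'
#' @param seq a single DNA or RNA string (U and T are equivalent).
#' @param initiator translate the first codon as `M` regardless of identity.
#' @param stop_at_first truncate at the first stop codon (default) rather
#'   than encoding it as `*`.
#' @return amino acid string (possibly empty).
#' @export
translate_nt <- function(seq, initiator = FALSE, stop_at_first = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- rna_to_dna(toupper(seq))
  n <- nchar(s)
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  if (anyNA(aa)) {
    stop("sequence contains non-ACGTU characters or an incomplete codon: ",
         codons[which(is.na(aa))[1]])
  }
  if (initiator && length(aa)) aa[1] <- "M"
  if (stop_at_first) {
    stop_i <- which(aa == "*")
    if (length(stop_i)) aa <- aa[seq_len(stop_i[1] - 1L)]
  }
  paste(aa, collapse = "")
}

#' Translate the annotated CDS of a transcript model
#'
#' @param model one row of a transcript-model table (or a list) carrying
#'   `sequence`, `utr5_end` (0-based CDS start) and `cds_end` (0-based
#'   exclusive).
#' @return the protein sequence; translation stops at the first stop codon
#'   and the initiator codon is rendered as `M`.
#' @export
translate_cds <- function(model) {
  utr5_end <- as.integer(model$utr5_end)
  cds_end <- as.integer(model$cds_end)
  seq <- as.character(model$sequence)
  if (is.na(utr5_end) || is.na(cds_end)) stop("model has no annotated CDS")
  if (utr5_end < 0L || cds_end > nchar(seq) || utr5_end > cds_end)
    stop("invalid CDS bounds")
  cds <- substr(seq, utr5_end + 1L, cds_end)
  if (nchar(cds) == 0L) stop("empty CDS")
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  translate_nt(cds, initiator = TRUE, stop_at_first = TRUE)
}

#' Three-frame translation of a (non-coding) RNA sequence
#'
#' Translates frames 0, 1 and 2, splits each translation at stop codons and
#' keeps fragments of at least `min_length_aa` residues -- the standard
#' construction of a lncRNA peptide search space.
#'
#' @param rna_sequence a single RNA/DNA string (length >= 3).
#' @param min_length_aa minimal fragment length kept.
#' @param id identifier prefix used for fragment accessions.
#' @return data.frame with columns `accession`, `sequence`, `frame`
#'   (0-based), `nt_start`, `nt_end` (1-based inclusive coordinates in the
#'   input), `source_db = "lncrna"`.
#' @export
three_frame_translate <- function(rna_sequence, min_length_aa = 7L,
                                  id = "seq") {
  s <- rna_to_dna(toupper(rna_sequence))
  if (nchar(s) < 3L) stop("sequence shorter than one codon")
  out <- list()
  for (frame in 0:2) {
    sub <- substr(s, frame + 1L, nchar(s))
    if (nchar(sub) < 3L) next
    aa <- translate_nt(sub, initiator = FALSE, stop_at_first = FALSE)
    if (nchar(aa) == 0L) next
    pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
    pos <- 1L  # aa index within this frame's translation
    for (p in pieces) {
      len <- nchar(p)
      if (len >= min_length_aa) {
        nt_start <- frame + 3L * (pos - 1L) + 1L
        out[[length(out) + 1L]] <- data.frame(
          accession = sprintf("%s:f%d:%d", id, frame, nt_start),
          sequence = p, frame = frame,
          nt_start = nt_start, nt_end = nt_start + 3L * len - 1L,
          source_db = "lncrna", stringsAsFactors = FALSE)
      }
      pos <- pos + len + 1L  # skip the stop
    }
  }
  if (!length(out)) {
    return(data.frame(accession = character(), sequence = character(),
                      frame = integer(), nt_start = integer(),
                      nt_end = integer(), source_db = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
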