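protein_entry_cols <- function() {
  c("accession", "sequence", "source_db", "gene_id", "transcript_id",
    "locus_id", "var_pos", "var_ref", "var_alt", "var_effect",
    "var_zygosity", "atis_offset", "atis_codon", "atis_frame",
    "atis_event")
}

protein_entries <- function(df) {
  for (col in setdiff(protein_entry_cols(), names(df)))
    df[[col]] <- rep(NA, nrow(df))
  df <- df[, protein_entry_cols()]
  if (nrow(df)) assert_aa(df$sequence, "protein entry")
  df
}

#' Translate the canonical proteome of a model set
#'
#' One protein entry per coding transcript (source `canonical`); the gene
#' id serves as the genomic locus.
#'
#' @param models output of [gen_transcript_models()] or its `models` table.
#' @return protein-entry data.frame.
#' @export
build_canonical_db <- function(models) {
  m <- models$models %||% models
  m <- m[m$biotype == "protein_coding", , drop = FALSE]
  protein_entries(data.frame(
    accession = paste0(m$transcript_id, ":canon"),
    sequence = vapply(seq_len(nrow(m)),
                      function(i) translate_cds(m[i, ]), ""),
    source_db = "canonical", gene_id = m$gene_id,
    transcript_id = m$transcript_id, locus_id = m$gene_id,
    stringsAsFactors = FALSE))
}

#' Sample-specific protein database from expressed transcripts
#'
#' Translates every coding transcript whose FPKM exceeds the cutoff
#' (strictly) in the selected tissue. Duplicate protein sequences are
#' collapsed into one entry whose accession concatenates the merged ids.
#'
#' @param models transcript models.
#' @param fpkm matrix (or [expression_matrix()]) of FPKM with transcript or
#'   gene ids as rownames.
#' @param tissue tissue column used for the cutoff (default: first).
#' @param fpkm_cutoff detection cutoff; inclusion requires FPKM strictly
#'   greater than this (default 1).
#' @return protein-entry data.frame (source `sample_rna`).
#' @export
build_sample_db <- function(models, fpkm, tissue = 1L, fpkm_cutoff = 1) {
  m <- models$models %||% models
  m <- m[m$biotype == "protein_coding", , drop = FALSE]
  fv <- as_values(fpkm)
  ids <- ifelse(m$transcript_id %in% rownames(fv), m$transcript_id,
                m$gene_id)
  expr <- fv[ids, tissue]
  keep <- which(expr > fpkm_cutoff)
  if (!length(keep)) {
    return(protein_entries(data.frame(
      accession = character(), sequence = character(),
      source_db = character(), gene_id = character(),
      transcript_id = character(), locus_id = character(),
      stringsAsFactors = FALSE)))
  }
  m <- m[keep, , drop = FALSE]
  seqs <- vapply(seq_len(nrow(m)), function(i) translate_cds(m[i, ]), "")
  # collapse identical protein sequences, merged header keeps all ids
  grp <- split(seq_along(seqs), seqs)
  rows <- lapply(grp, function(ix) {
    data.frame(
      accession = paste(paste0(m$transcript_id[ix], ":rna"),
                        collapse = "|"),
      sequence = seqs[ix[1]], source_db = "sample_rna",
      gene_id = paste(unique(m$gene_id[ix]), collapse = "|"),
      transcript_id = paste(m$transcript_id[ix], collapse = "|"),
      locus_id = m$gene_id[ix[1]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$accession), , drop = FALSE]
  rownames(out) <- NULL
  protein_entries(out)
}

#' Variant protein database
#'
#' One entry per variant: missense entries carry a single-residue
#' substitution; nonsense entries are truncated immediately before the
#' novel stop. I<->L variants are rejected at input (dropped with a
#' warning and recorded in the `"rejected"` attribute). Each entry records
#' the variant site so downstream criteria can be enforced without
#' external lookups.
#'
#' @param canonical_db entries from [build_canonical_db()].
#' @param variants data.frame from [gen_variant_set()] (needs
#'   transcript_id, gene_id, protein_pos, ref_aa, alt_aa, zygosity,
#'   effect, variant_id).
#' @return protein-entry data.frame (source `variant`).
#' @export
build_variant_db <- function(canonical_db, variants) {
  il <- (variants$ref_aa %in% c("I", "L")) &
    (variants$alt_aa %in% c("I", "L"))
  rejected <- variants[il, , drop = FALSE]
  if (nrow(rejected)) {
    warning(sprintf(
      "%d I/L variant(s) rejected (indistinguishable by MS): %s",
      nrow(rejected), paste(rejected$variant_id, collapse = ", ")))
  }
  variants <- variants[!il, , drop = FALSE]
  canon <- setNames(canonical_db$sequence, canonical_db$transcript_id)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    parent <- canon[[v$transcript_id]]
    if (is.null(parent)) {
      warning("variant ", v$variant_id, " skipped: gene with no CDS")
      return(NULL)
    }
    if (v$protein_pos < 1L || v$protein_pos > nchar(parent))
      stop("variant position out of range for record ", v$variant_id)
    if (substr(parent, v$protein_pos, v$protein_pos) != v$ref_aa)
      stop("reference residue mismatch for record ", v$variant_id)
    seq <- if (v$effect == "nonsense") {
      substr(parent, 1L, v$protein_pos - 1L)
    } else {
      s <- parent
      substr(s, v$protein_pos, v$protein_pos) <- v$alt_aa
      s
    }
    data.frame(accession = v$variant_id, sequence = seq,
               source_db = "variant", gene_id = v$gene_id,
               transcript_id = v$transcript_id, locus_id = v$gene_id,
               var_pos = v$protein_pos, var_ref = v$ref_aa,
               var_alt = v$alt_aa, var_effect = v$effect,
               var_zygosity = v$zygosity, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), sequence = character(),
               source_db = character(), gene_id = character(),
               transcript_id = character(), locus_id = character(),
               var_pos = integer(), var_ref = character(),
               var_alt = character(), var_effect = character(),
               var_zygosity = character(), stringsAsFactors = FALSE)
  out <- protein_entries(out)
  attr(out, "rejected") <- rejected
  out
}

#' Scan a 5'UTR for alternative translation initiation sites
#'
#' Every occurrence of a codon from `codon_set` at a UTR offset p (0-based,
#' strictly upstream of the CDS) is translated from p to the first stop
#' codon (or transcript end), uncapped through the canonical CDS. Products
#' longer than `min_length_aa - 1` residues are kept. The initiator codon
#' is rendered as Met.
#'
#' @param model one transcript-model row.
#' @param codon_set candidate start codons, RNA or DNA spelling
#'   (default [default_atis_codons()]).
#' @param min_length_aa minimum product length kept (default 7, i.e.
#'   strictly more than 6 residues).
#' @return data.frame of aTIS entries: accession, transcript_id, gene_id,
#'   start_offset, start_codon, frame, event, sequence.
#' @export
scan_atis_sites <- function(model, codon_set = default_atis_codons(),
                            min_length_aa = 7L) {
  if (!length(codon_set)) stop("codon_set must be nonempty")
  utr5_end <- as.integer(model$utr5_end)
  if (is.na(utr5_end)) stop("model has no 5'UTR/CDS annotation")
  set_dna <- rna_to_dna(toupper(codon_set))
  seq <- as.character(model$sequence)
  hits <- codon_hits(seq, set_dna, utr5_end)
  rows <- lapply(hits, function(p) {
    product <- translate_nt(substr(seq, p + 1L, nchar(seq)),
                            initiator = TRUE)
    if (nchar(product) < min_length_aa) return(NULL)
    frame <- if ((utr5_end - p) %% 3L == 0L) "in_frame" else "out_of_frame"
    entry <- data.frame(
      accession = sprintf("%s:atis:%d", model$transcript_id, p),
      transcript_id = model$transcript_id,
      gene_id = model$gene_id,
      start_offset = p,
      start_codon = dna_to_rna(substr(seq, p + 1L, p + 3L)),
      frame = frame, event = NA_character_,
      sequence = product, stringsAsFactors = FALSE)
    entry$event <- classify_atis_event(entry, model)
    entry
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(accession = character(), transcript_id = character(),
                      gene_id = character(), start_offset = integer(),
                      start_codon = character(), frame = character(),
                      event = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify an alternative-initiation event
#'
#' Upstream in-frame starts reading through the canonical start are
#' `extension`; upstream starts whose stop precedes the canonical start are
#' `uorf`; out-of-frame upstream starts overlapping the CDS are
#' `frameshift`; in-frame starts downstream of the canonical start are
#' `downstream_n_terminus`. Gene-level `mixed` labels arise when entries of
#' the same gene disagree (see [atis_gene_events()]).
#'
#' @param entry one aTIS entry (needs transcript_id, start_offset,
#'   sequence).
#' @param model the transcript model the entry derives from.
#' @return event label.
#' @export
classify_atis_event <- function(entry, model) {
  if (!identical(as.character(entry$transcript_id),
                 as.character(model$transcript_id)))
    stop("entry/model mismatch: ", entry$transcript_id, " vs ",
         model$transcript_id)
  p <- as.integer(entry$start_offset)
  utr5_end <- as.integer(model$utr5_end)
  in_frame <- (utr5_end - p) %% 3L == 0L
  if (p >= utr5_end) {
    return(if (in_frame) "downstream_n_terminus" else "frameshift")
  }
  # nt coordinate just past the product's stop codon
  prod_nt_end <- p + 3L * (nchar(entry$sequence) + 1L)
  ran_off_end <- p + 3L * nchar(entry$sequence) >= nchar(model$sequence) - 2L
  terminated_in_utr <- !ran_off_end && prod_nt_end <= utr5_end
  if (terminated_in_utr) return("uorf")
  if (in_frame) "extension" else "frameshift"
}

#' Aggregate aTIS event labels to gene level
#'
#' Genes whose entries (across transcripts) carry more than one distinct
#' event label are `mixed`.
#'
#' @param entries aTIS entry data.frame with `gene_id` and `event`.
#' @return data.frame `gene_id`, `event`.
#' @export
atis_gene_events <- function(entries) {
  ev <- tapply(entries$event, entries$gene_id, function(x) {
    u <- unique(x)
    if (length(u) == 1L) u else "mixed"
  })
  data.frame(gene_id = names(ev), event = unname(ev),
             stringsAsFactors = FALSE)
}

#' Build the full aTIS search space for a model set
#'
#' @param models transcript models.
#' @param codon_set,min_length_aa passed to [scan_atis_sites()].
#' @return protein-entry data.frame (source `atis`).
#' @export
build_atis_db <- function(models, codon_set = default_atis_codons(),
                          min_length_aa = 7L) {
  m <- models$models %||% models
  m <- m[m$biotype == "protein_coding", , drop = FALSE]
  entries <- do.call(rbind, lapply(seq_len(nrow(m)), function(i)
    scan_atis_sites(m[i, ], codon_set, min_length_aa)))
  if (is.null(entries) || !nrow(entries)) {
    return(protein_entries(data.frame(accession = character(),
                                      sequence = character(),
                                      source_db = character(),
                                      stringsAsFactors = FALSE)))
  }
  protein_entries(data.frame(
    accession = entries$accession, sequence = entries$sequence,
    source_db = "atis", gene_id = entries$gene_id,
    transcript_id = entries$transcript_id, locus_id = entries$gene_id,
    atis_offset = entries$start_offset, atis_codon = entries$start_codon,
    atis_frame = entries$frame, atis_event = entries$event,
    stringsAsFactors = FALSE))
}

#' Build the lncRNA (three-frame) search space
#'
#' @param models transcript models (non-coding biotypes are used).
#' @param min_length_aa minimal fragment length (default 7).
#' @return protein-entry data.frame (source `lncrna`).
#' @export
build_lncrna_db <- function(models, min_length_aa = 7L) {
  m <- models$models %||% models
  m <- m[m$biotype != "protein_coding", , drop = FALSE]
  rows <- lapply(seq_len(nrow(m)), function(i) {
    fr <- three_frame_translate(m$sequence[i], min_length_aa,
                                id = m$transcript_id[i])
    if (!nrow(fr)) return(NULL)
    data.frame(accession = fr$accession, sequence = fr$sequence,
               source_db = "lncrna", gene_id = m$gene_id[i],
               transcript_id = m$transcript_id[i],
               locus_id = m$gene_id[i], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), sequence = character(),
               source_db = character(), stringsAsFactors = FALSE)
  protein_entries(out)
}
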