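#' Required columns of the tabular exchange formats
#'
#' Named list of schemas (column name -> type) used by [load_tables()]:
#' `psm_a` (engine A), `psm_b` (engine B) and `variants`. Expression
#' matrices have their own reader, [read_expression_tsv()], since their
#' tissue columns are data-dependent.
#'
#' @return named list of schemas.
#' @export
table_schemas <- function() {
  list(
    psm_a = c(spectrum_file = "character", scan = "integer",
              peptide = "character", mods = "character",
              charge = "integer", ion_score = "numeric",
              delta_score = "numeric", proteins = "character"),
    psm_b = c(spectrum_file = "character", scan = "integer",
              peptide = "character", mods = "character",
              charge = "integer", score = "numeric",
              proteins = "character"),
    variants = c(gene_id = "character", transcript_id = "character",
                 protein_pos = "integer", ref_aa = "character",
                 alt_aa = "character", zygosity = "character",
                 effect = "character")
  )
}

#' Read and validate a tab-separated table against a schema
#'
#' UTF-8 TSV with a header row; DOS and UNIX line endings parse
#' identically. Missing columns raise an error naming them; values that
#' fail type coercion are reported with their line numbers.
#'
#' @param path file path.
#' @param schema named character vector (column -> type), e.g. an element
#'   of [table_schemas()].
#' @return data.frame with typed columns.
#' @export
load_tables <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop("schema mismatch in ", basename(path), ": missing columns: ",
         paste(missing, collapse = ", "))
  for (col in names(schema)) {
    raw <- df[[col]]
    cast <- switch(schema[[col]],
                   character = as.character(raw),
                   integer = suppressWarnings(as.integer(raw)),
                   numeric = suppressWarnings(as.numeric(raw)))
    bad <- which(is.na(cast) & !is.na(raw) & raw != "")
    if (length(bad))
      message(sprintf("%s: %d malformed value(s) in '%s' at line(s) %s",
                      basename(path), length(bad), col,
                      paste(utils::head(bad + 1L, 5), collapse = ", ")))
    df[[col]] <- cast
  }
  df
}

#' Write / read an expression matrix as TSV
#'
#' Genes in rows (first column `gene_id`), tissues in the header.
#'
#' @param matrix an [expression_matrix()] or plain matrix.
#' @param path file path.
#' @export
write_expression_tsv <- function(matrix, path) {
  v <- as_values(matrix)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param unit,detect_threshold passed to [expression_matrix()].
#' @export
read_expression_tsv <- function(path, unit = "fpkm",
                                detect_threshold = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  expression_matrix(v, unit, detect_threshold)
}

wrap60 <- function(s) {
  n <- nchar(s)
  starts <- seq.int(1L, n, by = 60L)
  paste(substring(s, starts, pmin(starts + 59L, n)), collapse = "\n")
}

#' Write protein entries as FASTA with a key=value header grammar
#'
#' Headers encode `src=`, `gene=`, `tx=`, `locus=` and any variant/aTIS
#' feature coordinates (1-based), so downstream filters can enforce
#' database-origin criteria without external lookups. Sequences wrap at 60
#' columns; entries are written in accession order for byte-identical
#' reruns.
#'
#' @param db protein-entry data.frame.
#' @param path output path.
#' @export
write_protein_fasta <- function(db, path) {
  db <- db[order(db$accession), , drop = FALSE]
  hdr <- sprintf(">%s src=%s gene=%s tx=%s locus=%s", db$accession,
                 db$source_db, db$gene_id, db$transcript_id, db$locus_id)
  extra <- ifelse(!is.na(db$var_pos),
                  sprintf(" pos=%d ref=%s alt=%s effect=%s zyg=%s",
                          db$var_pos, db$var_ref, db$var_alt,
                          db$var_effect, db$var_zygosity),
                  ifelse(!is.na(db$atis_offset),
                         sprintf(" atis_offset=%d codon=%s frame=%s event=%s",
                                 db$atis_offset, db$atis_codon,
                                 db$atis_frame, db$atis_event), ""))
  lines <- as.vector(rbind(paste0(hdr, extra),
                           vapply(db$sequence, wrap60, "")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a key=value protein FASTA back into an entry table
#'
#' @param path FASTA path written by [write_protein_fasta()].
#' @return protein-entry data.frame.
#' @export
read_protein_fasta <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^>", lines)
  ends <- c(hdr_i[-1] - 1L, length(lines))
  rows <- lapply(seq_along(hdr_i), function(k) {
    h <- sub("^>", "", lines[hdr_i[k]])
    toks <- strsplit(h, " ", fixed = TRUE)[[1]]
    kv <- toks[-1]
    kvs <- strsplit(kv, "=", fixed = TRUE)
    vals <- setNames(vapply(kvs, `[`, "", 2L), vapply(kvs, `[`, "", 1L))
    seq <- paste(lines[(hdr_i[k] + 1L):ends[k]], collapse = "")
    data.frame(accession = toks[1], sequence = seq,
               source_db = vals[["src"]],
               gene_id = vals["gene"] %0na% NA,
               transcript_id = vals["tx"] %0na% NA,
               locus_id = vals["locus"] %0na% NA,
               var_pos = as.integer(vals["pos"] %0na% NA),
               var_ref = vals["ref"] %0na% NA,
               var_alt = vals["alt"] %0na% NA,
               var_effect = vals["effect"] %0na% NA,
               var_zygosity = vals["zyg"] %0na% NA,
               atis_offset = as.integer(vals["atis_offset"] %0na% NA),
               atis_codon = vals["codon"] %0na% NA,
               atis_frame = vals["frame"] %0na% NA,
               atis_event = vals["event"] %0na% NA,
               stringsAsFactors = FALSE)
  })
  protein_entries(do.call(rbind, rows))
}

`%0na%` <- function(x, default) {
  if (length(x) == 0L || is.na(x)) default else unname(x)
}

#' Write transcript models as genome FASTA, transcript FASTA and GTF
#'
#' Coordinates are 1-based in the GTF (format law); each transcript is a
#' single exon on the synthetic chromosome. Deterministic output.
#'
#' @param tx output of [gen_transcript_models()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_transcript_bundle <- function(tx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- tx$models
  genome_path <- file.path(dir, "genome.fa")
  writeLines(c(">chrS", wrap60(unname(tx$genome["chrS"]))), genome_path)
  tfa <- file.path(dir, "transcripts.fa")
  writeLines(as.vector(rbind(paste0(">", m$transcript_id),
                             vapply(m$sequence, wrap60, ""))), tfa)
  gtf <- file.path(dir, "transcripts.gtf")
  rows <- lapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    end <- r$chrom_start + nchar(r$sequence) - 1L
    attr_ <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                     r$gene_id, r$transcript_id, r$biotype)
    feats <- c(sprintf("chrS\tsim\ttranscript\t%d\t%d\t.\t+\t.\t%s",
                       r$chrom_start, end, attr_),
               sprintf("chrS\tsim\texon\t%d\t%d\t.\t+\t.\t%s",
                       r$chrom_start, end, attr_))
    if (!is.na(r$utr5_end)) {
      feats <- c(feats, sprintf(
        "chrS\tsim\tCDS\t%d\t%d\t.\t+\t0\t%s",
        r$chrom_start + r$utr5_end, r$chrom_start + r$cds_end - 1L,
        attr_))
    }
    feats
  })
  writeLines(unlist(rows), gtf)
  invisible(c(genome = genome_path, transcripts = tfa, gtf = gtf))
}

#' Write variants as a minimal VCF
#'
#' VCF 4.2, 1-based positions on the synthetic chromosome, genotype column
#' encoding zygosity (0/1 het, 1/1 hom).
#'
#' @param variants data.frame from [gen_variant_set()].
#' @param path output path.
#' @export
write_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrS>",
           '##INFO=<ID=EFF,Number=1,Type=String,Description="Protein effect">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample1")
  v <- variants[order(variants$pos), , drop = FALSE]
  body <- sprintf("chrS\t%d\t%s\t%s\t%s\t.\tPASS\tEFF=%s|%s%d%s\tGT\t%s",
                  v$pos, v$variant_id, v$ref, v$alt, v$effect, v$ref_aa,
                  v$protein_pos, v$alt_aa,
                  ifelse(v$zygosity == "hom", "1/1", "0/1"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read spectra in MGF
#'
#' TITLE lines carry the linkage keys used by [validate_candidates()].
#' Deterministic formatting (5 decimals m/z, 2 decimals intensity).
#'
#' @param spectra list of [spectrum()] objects.
#' @param path file path.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- lapply(spectra, function(s) {
    c("BEGIN IONS",
      paste0("TITLE=", s$title),
      sprintf("PEPMASS=%.5f", s$precursor_mz),
      sprintf("CHARGE=%d+", s$precursor_charge),
      sprintf("%.5f %.2f", s$mz, s$intensity),
      "END IONS", "")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' @rdname write_mgf
#' @return `read_mgf`: named list of [spectrum()] objects keyed by title.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  out <- list()
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1])
    pm <- as.numeric(sub("^PEPMASS=", "",
                         grep("^PEPMASS=", block, value = TRUE)[1]))
    ch <- as.integer(sub("\\+$", "", sub("^CHARGE=", "",
                                         grep("^CHARGE=", block,
                                              value = TRUE)[1])))
    peaks <- block[grepl("^[0-9]", block)]
    mzint <- do.call(rbind, strsplit(peaks, " ", fixed = TRUE))
    role <- if (grepl("\\.ref$", title)) "reference" else "endogenous"
    out[[title]] <- spectrum(as.numeric(mzint[, 1]),
                             as.numeric(mzint[, 2]), pm, ch, role, title)
  }
  out
}

#' Export mirror-plot data as TSV
#'
#' @param mirror one element of `validate_candidates()$mirror`.
#' @param path output path.
#' @export
write_mirror_tsv <- function(mirror, path) {
  write.table(mirror, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
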