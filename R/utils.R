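#' @importFrom stats cor cov median plogis quantile rbinom rexp rnorm runif
#'   sd setNames var complete.cases cor.test
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert between RNA and DNA spelling
#'
#' Sequences are stored internally as DNA (T); user-facing codon labels
#' (start codons, VCF-free contexts) use RNA spelling (U).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector.
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname rna_to_dna
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Collapse isoleucine to leucine
#'
#' Ile and Leu are isobaric and indistinguishable by mass spectrometry, so
#' peptide-to-database matching is performed on I/L-collapsed sequences.
#'
#' @param x character vector of amino acid sequences.
#' @return character vector with every I replaced by L.
#' @export
il_collapse <- function(x) gsub("I", "L", x, fixed = TRUE)

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

assert_aa <- function(seqs, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")), seqs)
  if (any(bad)) {
    stop(sprintf("%s contains residues outside the 20-aa alphabet: %s",
                 what, paste(utils::head(seqs[bad], 3), collapse = ", ")))
  }
  invisible(TRUE)
}

# split a string into a character vector of single residues/bases
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# deterministic child seed derived from a base seed; kept < 2^31
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# sample() without the length-1 surprise (sample(5) permutes 1:5)
sample_vec <- function(x, size = length(x)) {
  if (length(x) == 1L) return(rep_len(x, size))
  sample(x, size)
}
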