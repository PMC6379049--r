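ENZYMES <- list(
  trypsin      = list(residues = c("K", "R"), side = "C", missed = 2L),
  lysc         = list(residues = "K",         side = "C", missed = 2L),
  lysn         = list(residues = "K",         side = "N", missed = 2L),
  argc         = list(residues = "R",         side = "C", missed = 2L),
  gluc         = list(residues = c("D", "E"), side = "C", missed = 3L),
  aspn         = list(residues = "D",         side = "N", missed = 3L),
  chymotrypsin = list(residues = c("F", "Y", "L", "W", "M"),
                      side = "C", missed = 4L)
)

#' Supported proteases and their cleavage rules
#'
#' Seven enzymes with fully-specific cleavage: trypsin (C-terminal of K/R,
#' no proline suppression), LysC (C-term K), LysN (N-term K), ArgC (C-term
#' R), GluC (C-term D/E), AspN (N-term D) and chymotrypsin (C-term
#' F/Y/L/W/M). Default maximum missed cleavages are 2 for trypsin, LysC,
#' LysN and ArgC, 3 for GluC and AspN, and 4 for chymotrypsin.
#'
#' @return named list of cleavage rules.
#' @export
enzyme_rules <- function() ENZYMES

# 0-based cut points (between residue i and i+1), excluding termini
cut_points <- function(seq, enzyme) {
  rule <- ENZYMES[[enzyme]]
  aa <- chars(seq)
  n <- length(aa)
  if (rule$side == "C") {
    cuts <- which(aa %in% rule$residues)
    cuts <- cuts[cuts < n]
  } else {
    cuts <- which(aa %in% rule$residues) - 1L
    cuts <- cuts[cuts >= 1L]
  }
  sort(unique(cuts))
}

#' In-silico proteolytic digestion
#'
#' Emits all fully-specific peptides with at most `max_missed` internal
#' cleavage sites, optionally filtered to a length range. At zero missed
#' cleavages the emitted peptides concatenate back to the input protein.
#'
#' @param protein amino acid string.
#' @param enzyme one of `names(enzyme_rules())`.
#' @param max_missed maximum internal (missed) cleavage sites; `NULL` uses
#'   the enzyme's default.
#' @param length_range numeric length-2 vector, inclusive peptide length
#'   bounds (default no filtering).
#' @return data.frame with `peptide`, `start`, `end` (1-based inclusive)
#'   and `missed`.
#' @export
digest <- function(protein, enzyme = "trypsin", max_missed = NULL,
                   length_range = c(1L, Inf)) {
  if (!enzyme %in% names(ENZYMES)) {
    stop("unknown enzyme '", enzyme, "'; supported: ",
         paste(names(ENZYMES), collapse = ", "))
  }
  assert_aa(protein, "protein")
  if (is.null(max_missed)) max_missed <- ENZYMES[[enzyme]]$missed
  n <- nchar(protein)
  bounds <- c(0L, cut_points(protein, enzyme), n)
  k <- length(bounds)
  out <- vector("list", 64L)
  m <- 0L
  for (i in seq_len(k - 1L)) {
    jmax <- min(k, i + 1L + max_missed)
    for (j in (i + 1L):jmax) {
      s <- bounds[i] + 1L
      e <- bounds[j]
      len <- e - s + 1L
      if (len >= length_range[1] && len <= length_range[2]) {
        m <- m + 1L
        out[[m]] <- list(peptide = substr(protein, s, e),
                         start = s, end = e, missed = j - i - 1L)
      }
    }
  }
  if (m == 0L) {
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), missed = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- out[seq_len(m)]
  data.frame(peptide = vapply(out, `[[`, "", "peptide"),
             start = vapply(out, `[[`, 0L, "start"),
             end = vapply(out, `[[`, 0L, "end"),
             missed = vapply(out, `[[`, 0L, "missed"),
             stringsAsFactors = FALSE)
}
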