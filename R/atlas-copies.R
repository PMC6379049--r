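#' Cellular constants used by the copy-number estimators
#'
#' DNA mass per diploid cell 6.5e-12 g, Avogadro 6.022e23 /mol, mRNA mass
#' fraction of total RNA 0.02, rRNA fraction of total RNA 0.8, ribosomal RNA
#' molar mass 2.32e6 g/mol, mean nucleotide residue mass 321 Da. Every
#' copy-number table records the constants it was computed with.
#'
#' @param ... overrides for individual constants.
#' @return named list of constants.
#' @export
copy_number_constants <- function(...) {
  const <- list(dna_mass_per_cell = 6.5e-12,
                avogadro = 6.022e23,
                mrna_mass_fraction = 0.02,
                rrna_fraction_of_total_rna = 0.8,
                ribosomal_rna_molar_mass = 2.32e6,
                mean_nt_residue_mass = 321)
  over <- list(...)
  const[names(over)] <- over
  const
}

#' Protein copies per cell by the proteomic ruler
#'
#' Anchors total histone MS intensity to the known DNA mass per cell:
#' `copies_i = I_i * (N_A / M_i) * (m_DNA / sum(histone I))`. Histone mass
#' is conserved exactly: the summed histone copies times molar mass equals
#' the DNA mass.
#'
#' @param intensities named nonnegative vector of protein intensities.
#' @param molar_masses named vector of protein molar masses (g/mol).
#' @param histone_ids ids of histone entries (must have intensity > 0).
#' @param constants from [copy_number_constants()].
#' @return data.frame `entity_id`, `copies_per_cell`; constants attached as
#'   attribute `"constants"`. Entities with missing molar mass get `NA`.
#' @export
protein_copy_numbers <- function(intensities, molar_masses, histone_ids,
                                 constants = copy_number_constants()) {
  if (any(molar_masses <= 0, na.rm = TRUE))
    stop("molar masses must be > 0")
  hist_int <- intensities[intersect(histone_ids, names(intensities))]
  if (!length(hist_int) || sum(hist_int) <= 0)
    stop("no histone intensity > 0; the proteomic ruler is undefined")
  scale <- constants$dna_mass_per_cell / sum(hist_int)
  mm <- molar_masses[names(intensities)]
  copies <- unname(intensities) * (constants$avogadro / mm) * scale
  out <- data.frame(entity_id = names(intensities),
                    copies_per_cell = unname(copies),
                    stringsAsFactors = FALSE)
  attr(out, "constants") <- constants
  out
}

#' mRNA copies per cell from FPKM and the ribosome count
#'
#' Reconstruction chain: ribosome count R = median ribosomal-protein
#' copies; rRNA mass = R * M_rRNA / N_A; total RNA mass = rRNA mass / rRNA
#' fraction; mRNA mass = 2% of total RNA mass; transcript copies distribute
#' the mRNA mass proportionally to FPKM * length:
#' `copies_t = FPKM_t * m_mRNA * N_A / (mean_nt_mass * sum_j FPKM_j L_j)`.
#' mRNA mass is conserved exactly by construction.
#'
#' @param fpkm named nonnegative vector of transcript FPKM.
#' @param transcript_lengths named vector of transcript lengths (nt).
#' @param ribosomal_protein_copies vector of ribosomal-protein copy numbers
#'   (from [protein_copy_numbers()]); the median defines the ribosome count.
#' @param constants from [copy_number_constants()].
#' @return data.frame `entity_id`, `copies_per_cell`; constants and the
#'   derived masses attached as attributes.
#' @export
mrna_copy_numbers <- function(fpkm, transcript_lengths,
                              ribosomal_protein_copies,
                              constants = copy_number_constants()) {
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM must be >= 0")
  len <- transcript_lengths[names(fpkm)]
  if (any(len <= 0, na.rm = TRUE)) stop("transcript lengths must be > 0")
  R <- median(ribosomal_protein_copies, na.rm = TRUE)
  if (!is.finite(R) || R <= 0)
    stop("ribosome count not derivable: median ribosomal-protein copies <= 0")
  m_rrna <- R * constants$ribosomal_rna_molar_mass / constants$avogadro
  m_total <- m_rrna / constants$rrna_fraction_of_total_rna
  m_mrna <- constants$mrna_mass_fraction * m_total
  denom <- constants$mean_nt_residue_mass * sum(fpkm * len)
  if (denom == 0) stop("sum(FPKM * length) is zero")
  copies <- unname(fpkm) * m_mrna * constants$avogadro / denom
  out <- data.frame(entity_id = names(fpkm),
                    copies_per_cell = copies,
                    stringsAsFactors = FALSE)
  attr(out, "constants") <- constants
  attr(out, "masses") <- c(rRNA = m_rrna, total_RNA = m_total,
                           mRNA = m_mrna, ribosomes = R)
  out
}
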