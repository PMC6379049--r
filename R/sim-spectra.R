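#' Generate an endogenous/reference spectrum pair for a peptide
#'
#' Both spectra contain the peptide's b/y ions (charges 1-2) with
#' correlated intensities. The endogenous copy is a controlled distortion
#' of the reference: the target spectral contrast angle between the pair is
#' `1 - distortion`, achieved by mixing the reference intensity vector with
#' an independent spiky intensity vector and solving the mixing weight by
#' bisection (SA is monotone in the weight). Optional degradation -- peak
#' dropout, multiplicative intensity noise and chimeric contaminant peaks
#' -- is applied after the SA-controlled mixing, so nonzero degradation
#' moves the realized SA below the target.
#'
#' @param peptide peptide sequence (length >= 5).
#' @param mods modification string or data.frame (see
#'   [theoretical_fragments()]); unsupported mods raise an error naming
#'   the mod.
#' @param distortion target `1 - SA` between the pair, in [0, 0.95].
#' @param seed integer seed; fixed seed reproduces the pair exactly.
#' @param peak_dropout probability an endogenous fragment peak is lost.
#' @param noise_sd multiplicative log-normal intensity noise (log scale SD).
#' @param n_chimeric number of contaminant peaks added to the endogenous
#'   spectrum at random m/z.
#' @param max_charge fragment charges.
#' @param title_prefix prefix for the two spectrum titles
#'   (`<prefix>.endo` / `<prefix>.ref`).
#' @return list with `endogenous` and `reference` [spectrum()] objects and
#'   `target_sa`.
#' @export
gen_spectrum_pair <- function(peptide, mods = NULL, distortion = 0,
                              seed = 1L, peak_dropout = 0, noise_sd = 0,
                              n_chimeric = 0L, max_charge = 2L,
                              title_prefix = peptide) {
  if (nchar(peptide) < 5L) stop("peptide must have at least 5 residues")
  if (distortion < 0 || distortion > 0.95)
    stop("distortion must lie in [0, 0.95]")
  set.seed(seed)
  frags <- theoretical_fragments(peptide, mods, max_charge = max_charge)
  n <- nrow(frags)
  ref_int <- exp(rnorm(n, log(1e5), 1))
  endo_int <- ref_int
  if (distortion > 0) {
    target <- 1 - distortion
    spike <- rexp(n)^4            # near-orthogonal to any dense vector
    spike <- spike / max(spike) * max(ref_int) * 4
    sa_at <- function(alpha)
      spectral_contrast_angle((1 - alpha) * ref_int + alpha * spike,
                              ref_int)
    lo <- 0; hi <- 1
    if (sa_at(1) > target) {
      warning("distortion target below what the mixing can reach; using maximum")
    } else {
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (sa_at(mid) >= target) lo <- mid else hi <- mid
      }
    }
    alpha <- (lo + hi) / 2
    endo_int <- (1 - alpha) * ref_int + alpha * spike
  }
  if (noise_sd > 0) endo_int <- endo_int * exp(rnorm(n, 0, noise_sd))
  if (peak_dropout > 0) endo_int[runif(n) < peak_dropout] <- 0
  endo_mz <- frags$mz
  if (n_chimeric > 0) {
    endo_mz <- c(endo_mz, runif(n_chimeric, min(frags$mz), max(frags$mz)))
    endo_int <- c(endo_int, exp(rnorm(n_chimeric, log(5e4), 1)))
  }
  pep_mass <- sum(residue_masses(
    peptide, if (is.character(mods)) parse_mods(mods) else mods)) + WATER
  prec <- (pep_mass + 2 * PROTON) / 2
  keep <- endo_int > 0
  list(endogenous = spectrum(endo_mz[keep], endo_int[keep], prec, 2L,
                             "endogenous",
                             paste0(title_prefix, ".endo")),
       reference = spectrum(frags$mz, ref_int, prec, 2L, "reference",
                            paste0(title_prefix, ".ref")),
       target_sa = 1 - distortion)
}
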