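AA_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
             V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
             I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
             K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
             F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
PROTON <- 1.00727646688
WATER <- 18.0105646863

SUPPORTED_MODS <- c(carbamidomethyl = 57.02146,
                    oxidation = 15.99491,
                    acetyl = 42.01057)

# residue-mass vector with site modifications folded in; N-terminal mods
# attach to residue 1 (so they shift all b ions and only the full-length y)
residue_masses <- function(peptide, mods = NULL) {
  aa <- chars(peptide)
  assert_aa(peptide, "peptide")
  m <- unname(AA_MONO[aa])
  if (!is.null(mods) && nrow(mods)) {
    for (i in seq_len(nrow(mods))) {
      name <- mods$name[i]
      if (!name %in% names(SUPPORTED_MODS))
        stop("unsupported modification '", name, "'")
      site <- mods$site[i]
      site <- if (identical(site, 0L) || identical(site, 0) ||
                  identical(site, "nterm")) 1L else as.integer(site)
      if (site < 1L || site > length(m))
        stop("modification site out of range: ", mods$site[i])
      m[site] <- m[site] + SUPPORTED_MODS[[name]]
    }
  }
  m
}

parse_mods <- function(mods_string) {
  # "5|oxidation;0|acetyl" -> data.frame(site, name)
  if (is.null(mods_string) || is.na(mods_string) || mods_string == "")
    return(NULL)
  parts <- strsplit(strsplit(mods_string, ";", fixed = TRUE)[[1]],
                    "|", fixed = TRUE)
  data.frame(site = as.integer(vapply(parts, `[`, "", 1L)),
             name = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

format_mods <- function(mods) {
  if (is.null(mods) || !nrow(mods)) return("")
  paste(sprintf("%d|%s", mods$site, mods$name), collapse = ";")
}

#' Theoretical b/y fragment ions of a peptide
#'
#' Monoisotopic fragment m/z values: `b_n` = sum of the first n residue
#' masses + proton; `y_n` = sum of the last n residue masses + water +
#' proton; charge-z m/z = (singly-protonated mass + (z-1) proton) / z.
#' Supported modifications: carbamidomethyl-C (+57.02146), oxidation-M
#' (+15.99491), N-terminal acetyl (+42.01057; site 0).
#'
#' @param peptide amino acid string.
#' @param mods data.frame (`site`, `name`) or a `"site|name;..."` string;
#'   site 0 denotes the N-terminus.
#' @param ion_types subset of `c("b", "y")`.
#' @param max_charge fragment charges 1..max_charge.
#' @return data.frame `label`, `type`, `index`, `charge`, `mz`, ordered by
#'   type, index, charge.
#' @export
theoretical_fragments <- function(peptide, mods = NULL,
                                  ion_types = c("b", "y"),
                                  max_charge = 2L) {
  if (is.character(mods)) mods <- parse_mods(mods)
  m <- residue_masses(peptide, mods)
  n <- length(m)
  if (n < 2L) stop("peptide must have at least 2 residues")
  idx <- seq_len(n - 1L)
  rows <- list()
  for (type in ion_types) {
    neutral <- switch(type,
                      b = cumsum(m)[idx],
                      y = cumsum(rev(m))[idx] + WATER,
                      stop("unsupported ion type '", type, "'"))
    mono <- neutral + PROTON  # singly protonated
    for (z in seq_len(max_charge)) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("%s%d^%d", type, idx, z),
        type = type, index = idx, charge = z,
        mz = (mono + (z - 1L) * PROTON) / z,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$type, out$index, out$charge), , drop = FALSE]
}

#' Centroided spectrum container
#'
#' @param mz,intensity equal-length numeric vectors; peaks are sorted by
#'   m/z and exact duplicates summed so m/z is strictly increasing.
#' @param precursor_mz,precursor_charge precursor information.
#' @param role `"endogenous"` or `"reference"`.
#' @param title spectrum title (MGF linkage key).
#' @return object of class `spectrum`.
#' @export
spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                     precursor_charge = NA_integer_,
                     role = c("endogenous", "reference"),
                     title = "") {
  role <- match.arg(role)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.vector(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(mz = mz, intensity = intensity,
                 precursor_mz = precursor_mz,
                 precursor_charge = precursor_charge,
                 role = role, title = title),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum '%s' [%s]: %d peaks, precursor %.4f (%s+)\n",
              x$title, x$role, length(x$mz), x$precursor_mz,
              x$precursor_charge))
  invisible(x)
}

#' Match theoretical fragments to spectrum peaks
#'
#' Each theoretical fragment is matched to the closest peak within
#' `tol_ppm`; every peak is used at most once (globally nearest-first
#' assignment). Unmatched fragments contribute zero intensity.
#'
#' @param spec a [spectrum()].
#' @param theoretical data.frame from [theoretical_fragments()].
#' @param tol_ppm matching tolerance in parts per million.
#' @return list with `intensity` (named by fragment label, in annotation
#'   order), `peak_index` (NA where unmatched) and `n_matched`.
#' @export
match_peaks <- function(spec, theoretical, tol_ppm = 20) {
  if (tol_ppm <= 0) stop("tolerance must be > 0")
  nf <- nrow(theoretical)
  out <- setNames(numeric(nf), theoretical$label)
  pk <- rep(NA_integer_, nf)
  if (!length(spec$mz)) {
    warning("empty spectrum: all-zero intensity vector")
    return(list(intensity = out, peak_index = pk, n_matched = 0L))
  }
  pairs <- list()
  for (i in seq_len(nf)) {
    ppm <- abs(spec$mz - theoretical$mz[i]) / theoretical$mz[i] * 1e6
    js <- which(ppm <= tol_ppm)
    for (j in js) pairs[[length(pairs) + 1L]] <-
        c(frag = i, peak = j, ppm = ppm[j])
  }
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, "ppm"]), , drop = FALSE]
    used_f <- logical(nf); used_p <- logical(length(spec$mz))
    for (r in seq_len(nrow(pm))) {
      f <- pm[r, "frag"]; p <- pm[r, "peak"]
      if (!used_f[f] && !used_p[p]) {
        used_f[f] <- used_p[p] <- TRUE
        out[f] <- spec$intensity[p]
        pk[f] <- p
      }
    }
  }
  list(intensity = out, peak_index = pk, n_matched = sum(!is.na(pk)))
}

#' Normalized spectral contrast angle
#'
#' `SA = 1 - 2 * acos(v1.v2 / (||v1|| ||v2||)) / pi`: 1 for identical
#' spectra, 0 for orthogonal ones. Symmetric and invariant to positive
#' scaling. An SA of 0.7 corresponds to an inner-product (cosine)
#' similarity of cos(0.15 pi) ~ 0.89.
#'
#' @param v1,v2 equal-length nonnegative intensity vectors over the same
#'   fragment annotations.
#' @param sqrt_transform square-root the intensities before normalizing
#'   (off by default).
#' @return SA in [0, 1]; `NA` with a warning if either vector is all zero.
#' @export
spectral_contrast_angle <- function(v1, v2, sqrt_transform = FALSE) {
  if (length(v1) != length(v2)) stop("vectors must have equal length")
  if (sqrt_transform) { v1 <- sqrt(v1); v2 <- sqrt(v2) }
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    warning("zero intensity vector: spectral contrast angle undefined")
    return(NA_real_)
  }
  cosv <- min(1, max(-1, sum(v1 * v2) / (n1 * n2)))
  1 - 2 * acos(cosv) / pi
}

#' Validate candidates against synthetic reference spectra
#'
#' For each candidate, every linked endogenous spectrum is compared to the
#' reference spectrum on the matched b/y intensity vectors; the spectrum
#' with the highest SA decides. A candidate is `confirmed` iff best SA >=
#' `sa_min` *and* its endogenous primary score >= `score_min`; candidates
#' without a reference spectrum are `unsynthesizable`, never confirmed.
#' Pearson correlation of the matched vectors is reported alongside SA for
#' cross-checking, never used as the pass criterion.
#'
#' @param candidates data.frame with columns `id`, `peptide`, `mods`
#'   (string, may be empty), `score` (endogenous primary score, NA
#'   allowed) and `endo_titles` (`;`-separated titles of endogenous
#'   spectra) plus `ref_title` (reference spectrum title, NA if none).
#' @param spectra named list of [spectrum()] objects keyed by title.
#' @param sa_min,score_min pass thresholds (0.7 and 50).
#' @param tol_ppm,max_charge fragment matching parameters.
#' @return list with `results` (data.frame: id, sa, pearson, n_matched,
#'   score, verdict, reason) and `mirror` (per-candidate mirror-plot
#'   data.frame: mz, intensity with the reference negated, label, side).
#' @export
validate_candidates <- function(candidates, spectra, sa_min = 0.7,
                                score_min = 50, tol_ppm = 20,
                                max_charge = 2L) {
  res <- list(); mirrors <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    frags <- theoretical_fragments(cand$peptide, cand$mods,
                                   max_charge = max_charge)
    ref <- if (!is.na(cand$ref_title)) spectra[[cand$ref_title]] else NULL
    if (is.null(ref)) {
      res[[i]] <- data.frame(id = cand$id, sa = NA_real_,
                             pearson = NA_real_, n_matched = NA_integer_,
                             score = cand$score,
                             verdict = "unsynthesizable",
                             reason = "no reference spectrum",
                             best_title = NA_character_,
                             stringsAsFactors = FALSE)
      next
    }
    vref <- match_peaks(ref, frags, tol_ppm)
    titles <- strsplit(cand$endo_titles, ";", fixed = TRUE)[[1]]
    best <- list(sa = -Inf, title = NA_character_, v = NULL)
    for (t in titles) {
      endo <- spectra[[t]]
      if (is.null(endo)) next
      v <- match_peaks(endo, frags, tol_ppm)
      sa <- suppressWarnings(
        spectral_contrast_angle(v$intensity, vref$intensity))
      if (!is.na(sa) && sa > best$sa) best <- list(sa = sa, title = t,
                                                   v = v)
    }
    if (!is.finite(best$sa)) {
      res[[i]] <- data.frame(id = cand$id, sa = NA_real_,
                             pearson = NA_real_, n_matched = NA_integer_,
                             score = cand$score, verdict = "rejected",
                             reason = "no endogenous spectrum",
                             best_title = NA_character_,
                             stringsAsFactors = FALSE)
      next
    }
    n_matched <- sum(best$v$intensity > 0 & vref$intensity > 0)
    pearson <- if (n_matched >= 3L)
      suppressWarnings(cor(best$v$intensity, vref$intensity)) else NA_real_
    score_ok <- !is.na(cand$score) && cand$score >= score_min
    sa_ok <- best$sa >= sa_min
    verdict <- if (sa_ok && score_ok) "confirmed" else "rejected"
    reason <- if (verdict == "confirmed") "" else
      if (!sa_ok) sprintf("SA %.3f below %.2f", best$sa, sa_min) else
        if (is.na(cand$score)) "score missing" else
          sprintf("score %.1f below %.0f", cand$score, score_min)
    res[[i]] <- data.frame(id = cand$id, sa = best$sa, pearson = pearson,
                           n_matched = n_matched, score = cand$score,
                           verdict = verdict, reason = reason,
                           best_title = best$title,
                           stringsAsFactors = FALSE)
    mirrors[[as.character(cand$id)]] <- data.frame(
      mz = c(frags$mz, frags$mz),
      intensity = c(best$v$intensity, -vref$intensity),
      label = c(frags$label, frags$label),
      side = rep(c("endogenous", "reference"), each = nrow(frags)),
      stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, res), mirror = mirrors,
       thresholds = list(sa_min = sa_min, score_min = score_min))
}
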