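#' Select plantable candidate peptides from a variant database
#'
#' Digests each variant entry and keeps tryptic peptides that would satisfy
#' the mapping criteria (variant-db-only, single locus, site shown or novel
#' terminus), then assigns planted flags: `pass` peptides later receive
#' scores above both engine-A thresholds, `fail_ion` / `fail_delta` scores
#' below the respective threshold, and `fail_map` rows are canonical
#' peptides (good scores, failing the variant-only mapping criterion).
#'
#' @param db concatenated protein-entry data.frame containing `canonical`
#'   and `variant` sources.
#' @param counts named integer vector over
#'   `c("pass", "fail_ion", "fail_delta", "fail_map")`.
#' @param enzyme protease (criterion v semantics).
#' @param seed integer seed.
#' @param allow_fewer if the plantable pool is smaller than the requested
#'   counts, scale the requests down (flags assigned round-robin) instead
#'   of erroring.
#' @return data.frame `peptide`, `accession`, `flag`, `role`.
#' @export
plant_candidate_peptides <- function(db, counts = c(pass = 10L,
                                                    fail_ion = 5L,
                                                    fail_delta = 5L,
                                                    fail_map = 5L),
                                     enzyme = "trypsin", seed = 1L,
                                     allow_fewer = FALSE) {
  set.seed(child_seed(seed, 404L))
  vdb <- db[db$source_db == "variant", , drop = FALSE]
  cdb <- db[db$source_db == "canonical", , drop = FALSE]
  if (!nrow(vdb)) stop("database has no variant entries to plant from")
  # peptides eligible as variant evidence: digest, keep those that pass
  # criteria (iii)-(vi) by construction (verified by mapping)
  pool <- list()
  for (i in seq_len(nrow(vdb))) {
    e <- vdb[i, ]
    pep <- digest(e$sequence, enzyme, max_missed = 1L,
                  length_range = c(7L, 30L))
    if (!nrow(pep)) next
    ok <- if (e$var_effect == "missense") {
      pep$start <= e$var_pos & e$var_pos <= pep$end
    } else {
      pep$end == nchar(e$sequence)
    }
    pep <- pep[ok, , drop = FALSE]
    if (nrow(pep))
      pool[[length(pool) + 1L]] <- data.frame(
        peptide = pep$peptide, accession = e$accession,
        stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, pool)
  if (is.null(pool) || !nrow(pool)) stop("no plantable variant peptides")
  # keep peptides that map to the variant db only, at a single locus
  mp <- map_peptides(unique(pool$peptide), db, enzyme = enzyme)
  good <- mp$summary$peptide[mp$summary$source_dbs == "variant" &
                               mp$summary$n_loci == 1L]
  pool <- pool[pool$peptide %in% good, , drop = FALSE]
  pool <- pool[!duplicated(pool$peptide), , drop = FALSE]
  n_var <- sum(counts[c("pass", "fail_ion", "fail_delta")], na.rm = TRUE)
  flags <- rep(c("pass", "fail_ion", "fail_delta"),
               times = c(counts["pass"] %||% 0L,
                         counts["fail_ion"] %||% 0L,
                         counts["fail_delta"] %||% 0L))
  if (nrow(pool) < n_var) {
    if (!allow_fewer)
      stop(sprintf("only %d plantable variant peptides for %d requested",
                   nrow(pool), n_var))
    flags <- rep_len(unique(flags), nrow(pool))
    n_var <- nrow(pool)
  }
  pool <- pool[sample.int(nrow(pool), n_var), , drop = FALSE]
  pool$flag <- flags
  pool$role <- "variant"

  out <- pool
  n_map <- counts["fail_map"] %||% 0L
  if (!is.na(n_map) && n_map > 0L) {
    cpep <- unique(do.call(rbind, lapply(
      sample_vec(seq_len(nrow(cdb)), min(nrow(cdb), 4L * n_map)),
      function(i) digest(cdb$sequence[i], enzyme, 0L,
                         c(8L, 25L))))$peptide)
    cpep <- setdiff(cpep, out$peptide)
    cpep <- cpep[seq_len(min(n_map, length(cpep)))]
    out <- rbind(out, data.frame(peptide = cpep, accession = NA_character_,
                                 flag = "fail_map", role = "variant",
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

rtrunc0 <- function(n, mean, sd) pmax(0, rnorm(n, mean, sd))

#' Simulate PSM tables for two search engines
#'
#' Background PSMs are tryptic peptides of canonical entries with scores
#' from the configured null distributions. Planted candidates receive
#' scores sampled above or below the filtering thresholds according to
#' their flag: `pass` rows exceed both engine-A criteria and appear in
#' engine B with a high score; `fail_ion` rows have ion score < score_min
#' (delta fine); `fail_delta` the converse; `fail_map` rows get passing
#' scores (they fail on mapping, not score); `fail_engine_b` rows pass
#' engine A but are absent from engine B.
#'
#' @param db concatenated protein-entry data.frame (background source).
#' @param planted data.frame from [plant_candidate_peptides()] (or with
#'   columns peptide, accession, flag, role); may be `NULL`.
#' @param config a [sim_config()] (score distributions + seed).
#' @param n_background number of background PSMs.
#' @param score_min,delta_min the thresholds the flags are planted against.
#' @return list `engine_a` (spectrum_file, scan, peptide, mods, charge,
#'   ion_score, delta_score, proteins, planted_flag) and `engine_b`
#'   (spectrum_file, scan, peptide, mods, charge, score, proteins).
#' @export
gen_psm_tables <- function(db, planted = NULL, config = sim_config(),
                           n_background = 200L, score_min = 25,
                           delta_min = 10) {
  set.seed(child_seed(config$seed, 505L))
  sd_ <- config$score_distributions
  cdb <- db[db$source_db == "canonical", , drop = FALSE]
  bg_pool <- unique(do.call(rbind, lapply(
    seq_len(min(nrow(cdb), 80L)),
    function(i) digest(cdb$sequence[i], "trypsin", 1L,
                       c(7L, 30L))))$peptide)
  bg <- sample_vec(bg_pool, min(n_background, length(bg_pool)))
  a_rows <- data.frame(
    peptide = bg, mods = "",
    charge = sample(2:3, length(bg), replace = TRUE),
    ion_score = rtrunc0(length(bg), sd_$engine_a_ion["mean"],
                        sd_$engine_a_ion["sd"]),
    delta_score = rtrunc0(length(bg), sd_$engine_a_delta["mean"],
                          sd_$engine_a_delta["sd"]),
    planted_flag = "", stringsAsFactors = FALSE)
  b_keep <- runif(length(bg)) < 0.7
  b_rows <- data.frame(
    peptide = bg[b_keep], mods = "",
    charge = a_rows$charge[b_keep],
    score = rtrunc0(sum(b_keep), sd_$engine_b["mean"],
                    sd_$engine_b["sd"]),
    stringsAsFactors = FALSE)

  if (!is.null(planted) && nrow(planted)) {
    n <- nrow(planted)
    ion <- numeric(n); delta <- numeric(n)
    for (i in seq_len(n)) {
      f <- planted$flag[i]
      ion[i] <- if (f == "fail_ion") runif(1, 5, score_min - 0.5) else
        runif(1, score_min + 5, score_min + 55)
      delta[i] <- if (f == "fail_delta") runif(1, 0, delta_min - 0.5) else
        runif(1, delta_min + 5, delta_min + 30)
    }
    a_rows <- rbind(a_rows, data.frame(
      peptide = planted$peptide, mods = "",
      charge = 2L, ion_score = ion, delta_score = delta,
      planted_flag = planted$flag, stringsAsFactors = FALSE))
    in_b <- planted$flag != "fail_engine_b"
    b_rows <- rbind(b_rows, data.frame(
      peptide = planted$peptide[in_b], mods = "",
      charge = 2L, score = runif(sum(in_b), 120, 250),
      stringsAsFactors = FALSE))
  }

  finish <- function(df, file) {
    df$spectrum_file <- file
    df$scan <- seq_len(nrow(df))
    df$proteins <- ""
    df[, c("spectrum_file", "scan", "peptide", "mods", "charge",
           setdiff(names(df), c("spectrum_file", "scan", "peptide",
                                "mods", "charge", "proteins")),
           "proteins")]
  }
  list(engine_a = finish(a_rows, "engineA.sim"),
       engine_b = finish(b_rows, "engineB.sim"))
}
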