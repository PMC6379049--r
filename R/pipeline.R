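#' Pipeline configuration
#'
#' Bundles the simulation configuration, every analysis threshold and the
#' stage toggles. The resolved configuration is serialized alongside every
#' run's results.
#'
#' @param sim a [sim_config()].
#' @param stages named logical toggles: simulate, dbforge, filter,
#'   validate, atlas.
#' @param fold specificity fold (5).
#' @param fpkm_cutoff detection / inclusion cutoff (1, strict >).
#' @param score_min,delta_min engine-A candidate criteria (25, 10).
#' @param sa_min,validate_score_min spectral validation thresholds (0.7,
#'   50).
#' @param missing_protein_score engine-B floor for the missing-protein
#'   profile (100); `NULL` disables the floor for the engine intersection.
#' @param hpp_min_peptides,hpp_min_length HPP guideline (2, 9).
#' @param min_tissues per-gene correlation eligibility (10).
#' @param constants copy-number constants.
#' @param out_dir optional output directory; when set, result tables and
#'   the resolved config are written there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c(simulate = TRUE, dbforge = TRUE,
                                       filter = TRUE, validate = TRUE,
                                       atlas = TRUE),
                            fold = 5, fpkm_cutoff = 1,
                            score_min = 25, delta_min = 10,
                            sa_min = 0.7, validate_score_min = 50,
                            missing_protein_score = 100,
                            hpp_min_peptides = 2L, hpp_min_length = 9L,
                            min_tissues = 10L,
                            constants = copy_number_constants(),
                            out_dir = NULL) {
  structure(list(sim = sim, stages = stages, fold = fold,
                 fpkm_cutoff = fpkm_cutoff, score_min = score_min,
                 delta_min = delta_min, sa_min = sa_min,
                 validate_score_min = validate_score_min,
                 missing_protein_score = missing_protein_score,
                 hpp_min_peptides = hpp_min_peptides,
                 hpp_min_length = hpp_min_length,
                 min_tissues = min_tissues, constants = constants,
                 out_dir = out_dir),
            class = "pipeline_config")
}

log_count <- function(log, stage, what, n) {
  log[[length(log) + 1L]] <- data.frame(stage = stage, what = what,
                                        n = n, stringsAsFactors = FALSE)
  log
}

#' Run the full synthetic-atlas pipeline
#'
#' Executes simulate -> database construction -> candidate filtering ->
#' spectral validation and/or the expression analytics, per the stage
#' toggles. Every stage's input/output counts are recorded in an audit log
#' (the identification funnel is a first-class output). A run is a pure
#' function of the configuration: same config + seed, same results.
#'
#' @param config a [pipeline_config()].
#' @return list with the stage outputs (`models`, `atlas`, `dbs`,
#'   `candidates`, `validation`, `analytics`), the audit `log` (data.frame)
#'   and the resolved `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  log <- list()
  out <- list(config = config)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (isTRUE(st[["simulate"]])) {
    out$models <- run_stage("simulate", gen_transcript_models(config$sim))
    out$atlas <- run_stage("simulate",
                           gen_abundance_atlas(out$models, config$sim))
    out$variants <- run_stage("simulate",
                              gen_variant_set(out$models, config$sim))
    log <- log_count(log, "simulate", "transcript models",
                     nrow(out$models$models))
    log <- log_count(log, "simulate", "planted aTIS sites",
                     nrow(out$models$atis_truth))
    log <- log_count(log, "simulate", "variants", nrow(out$variants))
  }

  if (isTRUE(st[["dbforge"]])) {
    out$dbs <- run_stage("dbforge", {
      canonical <- build_canonical_db(out$models)
      vdb <- suppressWarnings(build_variant_db(canonical, out$variants))
      list(canonical = canonical, variant = vdb,
           sample_rna = build_sample_db(out$models,
                                        out$atlas$mrna,
                                        fpkm_cutoff = config$fpkm_cutoff),
           atis = build_atis_db(out$models),
           lncrna = build_lncrna_db(out$models))
    })
    for (nm in names(out$dbs))
      log <- log_count(log, "dbforge", paste(nm, "entries"),
                       nrow(out$dbs[[nm]]))
  }

  if (isTRUE(st[["filter"]])) {
    out$candidates <- run_stage("filter", {
      db_all <- do.call(rbind, out$dbs[c("canonical", "variant")])
      planted <- plant_candidate_peptides(
        db_all, counts = c(pass = 8L, fail_ion = 4L, fail_delta = 4L,
                           fail_map = 4L),
        seed = config$sim$seed, allow_fewer = TRUE)
      psms <- gen_psm_tables(db_all, planted, config$sim,
                             n_background = 150L,
                             score_min = config$score_min,
                             delta_min = config$delta_min)
      cand <- filter_variant_candidates(
        psms$engine_a, db_all, score_min = config$score_min,
        delta_min = config$delta_min)
      both <- intersect_engines(cand, psms$engine_b)
      both <- homology_exclude(both, out$dbs$canonical)
      list(planted = planted, psms = psms, variant = cand,
           variant_both_engines = both)
    })
    log <- log_count(log, "filter", "engine-A PSMs",
                     nrow(out$candidates$psms$engine_a))
    log <- log_count(log, "filter", "variant candidates pass",
                     sum(out$candidates$variant$records$pass))
    log <- log_count(log, "filter", "pass both engines",
                     nrow(out$candidates$variant_both_engines$records))
  }

  if (isTRUE(st[["validate"]])) {
    out$validation <- run_stage("validate", {
      recs <- out$candidates$variant_both_engines$records
      if (nrow(recs)) {
        spectra <- list()
        cands <- lapply(seq_len(nrow(recs)), function(i) {
          pair <- gen_spectrum_pair(
            recs$peptide[i], distortion = 0.1,
            seed = child_seed(config$sim$seed, 606L + i))
          spectra[[pair$endogenous$title]] <<- pair$endogenous
          spectra[[pair$reference$title]] <<- pair$reference
          data.frame(id = recs$peptide[i], peptide = recs$peptide[i],
                     mods = "", score = recs$ion_score[i] + 30,
                     endo_titles = pair$endogenous$title,
                     ref_title = pair$reference$title,
                     stringsAsFactors = FALSE)
        })
        validate_candidates(do.call(rbind, cands), spectra,
                            sa_min = config$sa_min,
                            score_min = config$validate_score_min)
      } else list(results = NULL, mirror = list())
    })
    if (!is.null(out$validation$results))
      log <- log_count(log, "validate", "confirmed",
                       sum(out$validation$results$verdict == "confirmed"))
  }

  if (isTRUE(st[["atlas"]])) {
    out$analytics <- run_stage("atlas", {
      mrna <- out$atlas$mrna; prot <- out$atlas$protein
      coding <- rownames(as_values(prot))
      mrna_coding <- expression_matrix(
        as_values(mrna)[coding, , drop = FALSE], "fpkm", 1)
      spec <- classify_specificity(mrna_coding, fold = config$fold)
      slopes <- atlas_slopes(mrna_coding, prot)
      cors <- correlation_suite(mrna_coding, prot,
                                min_tissues = min(config$min_tissues,
                                                  config$sim$n_tissues))
      lm_ <- log10(impute_floor(as_values(mrna_coding)))
      lp <- log10(impute_floor(as_values(prot)))
      ci <- coinertia_rv(lm_, lp)   # genes as rows, tissues as variables
      n_both <- min(colSums(as_values(mrna_coding) > 0 &
                              as_values(prot) > 0))
      list(specificity = spec, slopes = slopes, correlations = cors,
           coinertia = ci,
           rank_mrna = rank_abundance_profile(mrna_coding, 1L),
           overlap_top100 = top_n_overlap(mrna_coding, prot,
                                          min(100L, n_both)))
    })
    log <- log_count(log, "atlas", "tissue-enriched genes",
                     sum(out$analytics$specificity$category ==
                           "tissue_enriched"))
  }

  out$log <- do.call(rbind, log)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- out$config
  cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  write.table(out$log, file.path(dir, "audit_log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(out$atlas)) {
    write_expression_tsv(out$atlas$mrna, file.path(dir, "mrna_fpkm.tsv"))
    write_expression_tsv(out$atlas$protein,
                         file.path(dir, "protein_intensity.tsv"))
    write.table(out$atlas$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$analytics)) {
    write.table(out$analytics$specificity,
                file.path(dir, "specificity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$analytics$slopes, file.path(dir, "slopes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$candidates)) {
    write.table(out$candidates$variant$records,
                file.path(dir, "variant_candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$validation$results)) {
    write.table(out$validation$results,
                file.path(dir, "validation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
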