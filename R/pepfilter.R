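#' Map peptides onto the concatenated search space
#'
#' Exact substring search of each peptide against every database entry,
#' with I and L collapsed by default (isobaric). When `enzyme` is given,
#' an occurrence only counts if both peptide termini are enzymatically
#' consistent with that entry (a cleavage site or the protein terminus) --
#' the digestion-aware sense of "maps to" the candidate criteria need:
#' without it, a nonsense-truncation peptide would always "map" to its
#' canonical parent as a plain substring and the novel-C-terminus criterion
#' could never fire. Reports, per peptide, the source databases hit, the
#' matching entries with positions, and the number of distinct genomic
#' loci covered.
#'
#' @param peptides character vector of peptide sequences.
#' @param db protein-entry data.frame (rbind of the dbforge builders); must
#'   be nonempty.
#' @param il_equivalent collapse I/L before matching (default TRUE).
#' @param enzyme `NULL` for plain substring mapping, or an enzyme name for
#'   digestion-aware mapping.
#' @return object of class `peptide_mapping`: list with `matches`
#'   (peptide, accession, source_db, locus_id, start, end) and `summary`
#'   (peptide, source_dbs, n_dbs, n_loci, n_entries).
#' @export
map_peptides <- function(peptides, db, il_equivalent = TRUE,
                         enzyme = NULL) {
  if (is.null(db) || !nrow(db)) stop("empty database set")
  if (!is.null(enzyme) && !enzyme %in% names(ENZYMES))
    stop("unknown enzyme '", enzyme, "'")
  peptides <- unique(peptides)
  key <- function(x) if (il_equivalent) il_collapse(x) else x
  db_seq <- key(db$sequence)
  rule <- if (!is.null(enzyme)) ENZYMES[[enzyme]] else NULL
  res_set <- if (!is.null(rule))
    key(paste(rule$residues, collapse = "")) else NULL
  term_ok <- function(seqc, s, e) {
    if (is.null(rule)) return(TRUE)
    n <- nchar(seqc)
    if (rule$side == "C") {
      start_ok <- s == 1L ||
        grepl(substr(seqc, s - 1L, s - 1L), res_set, fixed = TRUE)
      end_ok <- e == n ||
        grepl(substr(seqc, e, e), res_set, fixed = TRUE)
    } else {
      start_ok <- s == 1L ||
        grepl(substr(seqc, s, s), res_set, fixed = TRUE)
      end_ok <- e == n ||
        grepl(substr(seqc, e + 1L, e + 1L), res_set, fixed = TRUE)
    }
    start_ok && end_ok
  }
  rows <- list()
  for (pep in peptides) {
    pk <- key(pep)
    for (h in seq_along(db_seq)) {
      starts <- gregexpr(pk, db_seq[h], fixed = TRUE)[[1]]
      if (starts[1] == -1L) next
      for (s in as.integer(starts)) {
        e <- s + nchar(pep) - 1L
        if (!term_ok(db_seq[h], s, e)) next
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, accession = db$accession[h],
          source_db = db$source_db[h], locus_id = db$locus_id[h],
          start = s, end = e, stringsAsFactors = FALSE)
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(), accession = character(),
               source_db = character(), locus_id = character(),
               start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(peptides, function(pep) {
    m <- matches[matches$peptide == pep, , drop = FALSE]
    data.frame(peptide = pep,
               source_dbs = paste(sort(unique(m$source_db)),
                                  collapse = ","),
               n_dbs = length(unique(m$source_db)),
               n_loci = length(unique(m$locus_id)),
               n_entries = nrow(m), stringsAsFactors = FALSE)
  }))
  structure(list(matches = matches, summary = summ,
                 il_equivalent = il_equivalent),
            class = "peptide_mapping")
}

new_candidate_set <- function(role, records, thresholds = list()) {
  structure(list(role = role, records = records, thresholds = thresholds),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  n <- nrow(x$records)
  np <- sum(x$records$pass)
  cat(sprintf("candidate set [%s]: %d records, %d pass\n", x$role, n, np))
  if (n > np) {
    ff <- table(x$records$first_fail[!x$records$pass])
    cat("  first failures:",
        paste(sprintf("%s=%d", names(ff), ff), collapse = ", "), "\n")
  }
  invisible(x)
}

first_false <- function(flags) {
  i <- which(!unlist(flags))
  if (!length(i)) "" else names(flags)[i[1]]
}

# does `enzyme` cleave C-terminal (or N-terminal) of residue `aa`?
cleaves <- function(enzyme, aa, side) {
  rule <- ENZYMES[[enzyme]]
  rule$side == side && aa %in% rule$residues
}

#' Filter variant-peptide PSMs by the six-criterion rule
#'
#' Criteria, evaluated in printed order so the first failure is well
#' defined: (i) engine-A ion score >= `score_min`; (ii) engine-A delta
#' score >= `delta_min`; (iii) the peptide maps only to the variant
#' database; (iv) the peptide maps to a single genomic locus; (v) missense:
#' the peptide shows the variant residue, or one of its termini is created
#' by a novel cleavage site arising from the variant under `enzyme`;
#' (vi) nonsense: the peptide ends at the novel C-terminus.
#'
#' Mapping for criteria (iii)/(iv) is digestion-aware (see
#' [map_peptides()]): occurrences must respect enzymatic termini, otherwise
#' truncation and novel-cleavage peptides would always co-map to their
#' canonical parent and criteria (v)-(vi) could never pass.
#'
#' @param psms engine-A PSM table (columns peptide, ion_score, delta_score,
#'   and optionally mods, spectrum_file, scan).
#' @param db concatenated protein-entry data.frame (canonical + variant +
#'   any other search spaces the PSMs were searched against).
#' @param enzyme protease used (mapping termini and the novel-cleavage
#'   branch of criterion v).
#' @param score_min,delta_min score thresholds (defaults 25 and 10).
#' @param il_equivalent I/L-collapsed mapping (default TRUE).
#' @return a `candidate_set` (role `variant`) whose `records` carry
#'   per-criterion audit columns `c1`..`c6`, `pass` and `first_fail`.
#' @export
filter_variant_candidates <- function(psms, db, enzyme = "trypsin",
                                      score_min = 25, delta_min = 10,
                                      il_equivalent = TRUE) {
  if (!enzyme %in% names(ENZYMES)) stop("unknown enzyme '", enzyme, "'")
  mapping <- map_peptides(unique(psms$peptide), db, il_equivalent,
                          enzyme = enzyme)
  key <- function(x) if (il_equivalent) il_collapse(x) else x

  eval_row <- function(i) {
    p <- psms[i, ]
    m <- mapping$matches[mapping$matches$peptide == p$peptide, ,
                         drop = FALSE]
    s <- mapping$summary[mapping$summary$peptide == p$peptide, ]
    flags <- list(
      c1 = isTRUE(p$ion_score >= score_min),
      c2 = isTRUE(p$delta_score >= delta_min),
      c3 = nrow(m) > 0 && identical(unique(m$source_db), "variant"),
      c4 = nrow(m) > 0 && s$n_loci == 1L)
    vm <- m[m$source_db == "variant", , drop = FALSE]
    site_ok <- FALSE
    if (nrow(vm)) {
      ent <- db[match(vm$accession, db$accession), , drop = FALSE]
      for (j in seq_len(nrow(vm))) {
        e <- ent[j, ]
        if (e$var_effect == "missense") {
          covered <- vm$start[j] <= e$var_pos && e$var_pos <= vm$end[j]
          shows_alt <- covered &&
            key(substr(p$peptide, e$var_pos - vm$start[j] + 1L,
                       e$var_pos - vm$start[j] + 1L)) == key(e$var_alt)
          novel_c <- cleaves(enzyme, e$var_alt, "C") &&
            vm$start[j] == e$var_pos + 1L
          novel_n <- cleaves(enzyme, e$var_alt, "N") &&
            vm$end[j] == e$var_pos - 1L
          if (shows_alt || novel_c || novel_n) site_ok <- TRUE
        } else if (e$var_effect == "nonsense") {
          if (vm$end[j] == nchar(e$sequence)) site_ok <- TRUE
        }
      }
    }
    effects <- if (nrow(vm))
      db$var_effect[match(vm$accession, db$accession)] else character(0)
    flags$c5 <- if ("missense" %in% effects) site_ok else TRUE
    flags$c6 <- if ("nonsense" %in% effects) site_ok else TRUE
    if (!nrow(vm)) flags$c5 <- flags$c6 <- FALSE
    cbind(p, as.data.frame(flags),
          pass = all(unlist(flags)), first_fail = first_false(flags),
          variant_ids = paste(vm$accession, collapse = ";"),
          stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, lapply(seq_len(nrow(psms)), eval_row))
  new_candidate_set("variant", records,
                    list(score_min = score_min, delta_min = delta_min,
                         enzyme = enzyme))
}

#' Filter canonical-counterpart PSMs
#'
#' Counterparts of variant sites showing the reference genotype. Criteria:
#' (i) ion score, (ii) delta score as for variants; (iii) at least one
#' mapped protein is *not* from the variant database; (iv) single genomic
#' locus; (v) missense: the peptide covers the variant site and shows the
#' wild-type residue; (vi) nonsense: the peptide extends past the novel
#' C-terminus.
#'
#' @param psms engine-A PSM table.
#' @param db concatenated protein-entry data.frame.
#' @param variants variant table ([gen_variant_set()] output).
#' @param score_min,delta_min,il_equivalent as in
#'   [filter_variant_candidates()].
#' @return a `candidate_set` (role `canonical_counterpart`).
#' @export
filter_canonical_counterparts <- function(psms, db, variants,
                                          score_min = 25, delta_min = 10,
                                          il_equivalent = TRUE) {
  mapping <- map_peptides(unique(psms$peptide), db, il_equivalent)
  key <- function(x) if (il_equivalent) il_collapse(x) else x
  eval_row <- function(i) {
    p <- psms[i, ]
    m <- mapping$matches[mapping$matches$peptide == p$peptide, ,
                         drop = FALSE]
    s <- mapping$summary[mapping$summary$peptide == p$peptide, ]
    nonvar <- m[m$source_db != "variant", , drop = FALSE]
    flags <- list(
      c1 = isTRUE(p$ion_score >= score_min),
      c2 = isTRUE(p$delta_score >= delta_min),
      c3 = nrow(nonvar) > 0,
      c4 = nrow(m) > 0 && s$n_loci == 1L)
    hit_vars <- character(0)
    site_ok <- FALSE
    any_applicable <- FALSE
    ent <- db[match(nonvar$accession, db$accession), , drop = FALSE]
    for (j in seq_len(nrow(nonvar))) {
      vv <- variants[variants$transcript_id == ent$transcript_id[j], ,
                     drop = FALSE]
      for (k in seq_len(nrow(vv))) {
        v <- vv[k, ]
        if (v$effect == "missense") {
          covered <- nonvar$start[j] <= v$protein_pos &&
            v$protein_pos <= nonvar$end[j]
          if (!covered) next
          any_applicable <- TRUE
          off <- v$protein_pos - nonvar$start[j] + 1L
          if (key(substr(p$peptide, off, off)) == key(v$ref_aa)) {
            site_ok <- TRUE
            hit_vars <- c(hit_vars, v$variant_id)
          }
        } else if (v$effect == "nonsense") {
          # novel C-terminus sits at protein_pos - 1
          if (nonvar$start[j] > v$protein_pos ||
              nonvar$end[j] < v$protein_pos) next
          any_applicable <- TRUE
          if (nonvar$end[j] >= v$protein_pos) {
            site_ok <- TRUE
            hit_vars <- c(hit_vars, v$variant_id)
          }
        }
      }
    }
    flags$c5 <- any_applicable && site_ok
    flags$c6 <- TRUE  # folded into c5's per-effect check above
    cbind(p, as.data.frame(flags),
          pass = all(unlist(flags)), first_fail = first_false(flags),
          variant_ids = paste(unique(hit_vars), collapse = ";"),
          stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, lapply(seq_len(nrow(psms)), eval_row))
  new_candidate_set("canonical_counterpart", records,
                    list(score_min = score_min, delta_min = delta_min))
}

#' Filter novel (aTIS / lncRNA) peptide PSMs
#'
#' Criteria in printed order: (i) the peptide maps to the `role` database
#' only; (ii) ion score >= `score_min`; (iii) delta score >= `delta_min`;
#' (iv) the underlying transcript is expressed (FPKM strictly > 1) in at
#' least one tissue.
#'
#' @param psms engine-A PSM table.
#' @param db concatenated protein-entry data.frame.
#' @param fpkm FPKM matrix with transcript (or gene) rownames.
#' @param role `"atis"` or `"lncrna"`.
#' @param score_min,delta_min,fpkm_cutoff thresholds.
#' @param il_equivalent I/L-collapsed mapping.
#' @return a `candidate_set` with audit columns `c1`..`c4`.
#' @export
filter_novel_candidates <- function(psms, db, fpkm,
                                    role = c("atis", "lncrna"),
                                    score_min = 25, delta_min = 10,
                                    fpkm_cutoff = 1, il_equivalent = TRUE) {
  role <- match.arg(role)
  mapping <- map_peptides(unique(psms$peptide), db, il_equivalent)
  fv <- as_values(fpkm)
  eval_row <- function(i) {
    p <- psms[i, ]
    m <- mapping$matches[mapping$matches$peptide == p$peptide, ,
                         drop = FALSE]
    flags <- list(
      c1 = nrow(m) > 0 && identical(unique(m$source_db), role),
      c2 = isTRUE(p$ion_score >= score_min),
      c3 = isTRUE(p$delta_score >= delta_min))
    note <- ""
    ent <- db[match(m$accession[m$source_db == role], db$accession), ,
              drop = FALSE]
    parents <- unique(stats::na.omit(c(
      ent$transcript_id[ent$transcript_id %in% rownames(fv)],
      ent$gene_id[ent$gene_id %in% rownames(fv)])))
    if (!length(parents)) {
      flags$c4 <- FALSE
      note <- "no parent transcript in the FPKM table"
    } else {
      flags$c4 <- any(fv[parents, , drop = FALSE] > fpkm_cutoff)
    }
    cbind(p, as.data.frame(flags),
          pass = all(unlist(flags)), first_fail = first_false(flags),
          note = note, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, lapply(seq_len(nrow(psms)), eval_row))
  new_candidate_set(role, records,
                    list(score_min = score_min, delta_min = delta_min,
                         fpkm_cutoff = fpkm_cutoff))
}

#' Require identification by both search engines
#'
#' Keeps passing candidates of the engine-A set whose modified peptide
#' (sequence + modification string) also appears in the engine-B table,
#' optionally above an engine-B score floor (the missing-protein profile
#' sets 100; default no floor). Candidates are deduplicated by modified
#' peptide; spectrum references from both engines are retained.
#'
#' @param set_a a `candidate_set` from one of the filters.
#' @param psms_b engine-B PSM table (columns peptide, score, and optionally
#'   mods, spectrum_file, scan).
#' @param b_score_min optional engine-B score floor (`NULL` = off).
#' @return a `candidate_set` of the intersection.
#' @export
intersect_engines <- function(set_a, psms_b, b_score_min = NULL) {
  stopifnot(inherits(set_a, "candidate_set"))
  recs <- set_a$records[set_a$records$pass, , drop = FALSE]
  modkey <- function(df) paste(df$peptide,
                               df$mods %||% rep("", nrow(df)))
  if (!nrow(recs)) return(new_candidate_set(set_a$role, recs,
                                            set_a$thresholds))
  b <- psms_b
  if (!is.null(b_score_min)) b <- b[b$score >= b_score_min, , drop = FALSE]
  bkeys <- modkey(b)
  keep <- modkey(recs) %in% bkeys
  recs <- recs[keep, , drop = FALSE]
  if (nrow(recs)) {
    k <- modkey(recs)
    specs_a <- tapply(paste0(recs$spectrum_file %||% "", ":",
                             recs$scan %||% ""), k,
                      function(x) paste(unique(x), collapse = ";"))
    recs <- recs[!duplicated(k), , drop = FALSE]
    recs$spectra_a <- unname(specs_a[modkey(recs)])
    bk <- modkey(b)
    recs$spectra_b <- vapply(modkey(recs), function(key)
      paste(unique(paste0(b$spectrum_file[bk == key] %||% "", ":",
                          b$scan[bk == key])), collapse = ";"), "")
  }
  th <- set_a$thresholds
  th$b_score_min <- b_score_min
  new_candidate_set(set_a$role, recs, th)
}

#' Exclude candidates explainable by canonical sequences
#'
#' Deterministic replacement for a BLAST screen: a candidate is dropped if
#' its I/L-collapsed sequence occurs in any canonical entry with at most
#' `max_mismatches` substitutions. The audit names the matching accession.
#'
#' @param candidates a `candidate_set`.
#' @param canonical_db canonical protein-entry data.frame.
#' @param max_mismatches allowed substitutions (default 0 = exact).
#' @param il_equivalent collapse I/L (default TRUE).
#' @return the `candidate_set` with excluded records marked
#'   (`homology_hit` column) and `pass` updated.
#' @export
homology_exclude <- function(candidates, canonical_db, max_mismatches = 0L,
                             il_equivalent = TRUE) {
  stopifnot(inherits(candidates, "candidate_set"))
  recs <- candidates$records
  if (!nrow(recs)) return(candidates)
  key <- function(x) if (il_equivalent) il_collapse(x) else x
  seqs <- key(canonical_db$sequence)
  find_hit <- function(pep) {
    pc <- chars(key(pep)); lp <- length(pc)
    for (i in seq_along(seqs)) {
      sc <- chars(seqs[i]); n <- length(sc)
      if (n < lp) next
      for (s in 1:(n - lp + 1L)) {
        if (sum(sc[s:(s + lp - 1L)] != pc) <= max_mismatches)
          return(canonical_db$accession[i])
      }
    }
    NA_character_
  }
  recs$homology_hit <- vapply(recs$peptide, find_hit, "")
  dropped <- recs$pass & !is.na(recs$homology_hit)
  recs$pass[dropped] <- FALSE
  recs$first_fail[dropped] <- "homology"
  candidates$records <- recs
  candidates
}

#' Human Proteome Project evidence rule
#'
#' A protein claim passes when it is supported by at least `min_peptides`
#' distinct peptide sequences, each of at least `min_length` residues.
#'
#' @param protein_candidates data.frame with columns `protein` and
#'   `peptide` (one row per identification; duplicates are collapsed).
#' @param min_peptides,min_length the guideline thresholds (2 and 9).
#' @return data.frame `protein`, `n_qualifying_peptides`, `hpp_pass`.
#' @export
hpp_guideline_check <- function(protein_candidates, min_peptides = 2L,
                                min_length = 9L) {
  u <- unique(protein_candidates[, c("protein", "peptide")])
  n_ok <- tapply(nchar(u$peptide) >= min_length, u$protein, sum)
  data.frame(protein = names(n_ok),
             n_qualifying_peptides = as.integer(n_ok),
             hpp_pass = as.integer(n_ok) >= min_peptides,
             stringsAsFactors = FALSE)
}

#' Infer the start codon behind a confirmed aTIS peptide
#'
#' An N-terminally acetylated peptide pins the start site exactly when it
#' aligns to position 1 of the aTIS product, or position 2 when the product
#' starts with Met (initiator-Met excision). Non-acetylated or internal
#' peptides report the entry's start codon as tentative.
#'
#' @param peptide confirmed peptide sequence.
#' @param atis_entry the aTIS entry it maps to (needs `sequence`,
#'   `start_codon` or `atis_codon`).
#' @param acetylated is the peptide N-terminally acetylated?
#' @param il_equivalent I/L-collapsed alignment.
#' @return list with `codon` (RNA spelling) and `exact` (logical).
#' @export
infer_start_codon <- function(peptide, atis_entry, acetylated,
                              il_equivalent = TRUE) {
  key <- function(x) if (il_equivalent) il_collapse(x) else x
  seq <- as.character(atis_entry$sequence)
  pos <- as.integer(regexpr(key(peptide), key(seq), fixed = TRUE))
  if (pos < 1L) stop("peptide is not contained in the aTIS entry")
  codon <- as.character(atis_entry$start_codon %||% atis_entry$atis_codon)
  exact <- isTRUE(acetylated) &&
    (pos == 1L || (pos == 2L && startsWith(seq, "M")))
  list(codon = codon, exact = exact)
}
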