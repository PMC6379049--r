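#' Log-transform and median-centre an expression matrix
#'
#' Values are log10-transformed and each tissue column is centred on the
#' median of its *detected* entries, so the per-tissue median of detected
#' genes is exactly zero afterwards. Undetected entries (below the
#' detection threshold, or zero intensities) become `NA` -- they are
#' missing, never zero.
#'
#' @param matrix an [expression_matrix()] (or plain nonnegative matrix).
#' @return numeric matrix on the log10 scale with `NA` for undetected
#'   entries; per-tissue medians of the attribute `"centres"` record the
#'   subtracted medians.
#' @export
log_median_normalize <- function(matrix) {
  v <- as_values(matrix)
  det <- detected(matrix)
  if (any(colSums(det, na.rm = TRUE) == 0))
    stop("tissue column with no detected entries: ",
         paste(colnames(v)[colSums(det) == 0], collapse = ", "))
  lg <- suppressWarnings(log10(v))
  lg[!det] <- NA_real_
  centres <- apply(lg, 2, median, na.rm = TRUE)
  out <- sweep(lg, 2, centres, "-")
  attr(out, "centres") <- centres
  out
}

SPECIFICITY_LEVELS <- c("tissue_enriched", "group_enriched",
                        "tissue_enhanced", "expressed_in_all", "mixed",
                        "not_detected")

#' Classify tissue specificity of expression
#'
#' Five-class scheme on the natural scale: *tissue-enriched* (one tissue at
#' least `fold` above every other tissue), *group-enriched* (a group of 2-7
#' tissues, all detected, whose mean is at least `fold` above the maximum of
#' the remaining tissues; groups are the top-k tissues by abundance),
#' *tissue-enhanced* (a tissue at least `fold` above the mean of all other
#' tissues), *expressed-in-all* (detected in every tissue) and *mixed*
#' (none of the above); genes detected nowhere are *not-detected*.
#' Precedence follows that order. For all fold comparisons, undetected
#' values are floored at the detection threshold so that folds against
#' unexpressed tissues are finite and conservative.
#'
#' @param matrix an [expression_matrix()] on the natural scale.
#' @param fold fold-change defining elevation (default 5).
#' @return data.frame with `gene_id`, `category` (factor with the six
#'   levels), `supporting_tissues` (comma-separated) and `fold_achieved`.
#' @export
classify_specificity <- function(matrix, fold = 5) {
  v <- as_values(matrix)
  if (ncol(v) < 3L) stop("specificity classes need at least 3 tissues")
  det <- detected(matrix)
  thr <- if (inherits(matrix, "expr_matrix")) matrix$detect_threshold else
    .Machine$double.xmin
  floored <- pmax(v, thr)
  tissues <- colnames(v)

  one <- function(i) {
    x <- v[i, ]; xf <- floored[i, ]; d <- det[i, ]
    if (!any(d)) return(list("not_detected", "", NA_real_))
    ord <- order(xf, decreasing = TRUE)
    top <- ord[1]
    rest_max <- max(xf[-top])
    if (xf[top] >= fold * rest_max)
      return(list("tissue_enriched", tissues[top], xf[top] / rest_max))
    for (k in 2:min(7L, ncol(v) - 1L)) {
      grp <- ord[seq_len(k)]
      if (!all(d[grp])) next
      rest <- max(xf[-grp])
      if (mean(xf[grp]) >= fold * rest)
        return(list("group_enriched",
                    paste(tissues[sort(grp)], collapse = ","),
                    mean(xf[grp]) / rest))
    }
    enh <- vapply(seq_along(xf), function(j)
      xf[j] >= fold * mean(xf[-j]), TRUE)
    if (any(enh & d)) {
      j <- which(enh & d)
      return(list("tissue_enhanced",
                  paste(tissues[j], collapse = ","),
                  max(xf[j] / vapply(j, function(jj) mean(xf[-jj]), 1))))
    }
    if (all(d)) return(list("expressed_in_all", "", NA_real_))
    list("mixed", "", NA_real_)
  }

  res <- lapply(seq_len(nrow(v)), one)
  data.frame(
    gene_id = rownames(v),
    category = factor(vapply(res, `[[`, "", 1L),
                      levels = SPECIFICITY_LEVELS),
    supporting_tissues = vapply(res, `[[`, "", 2L),
    fold_achieved = vapply(res, `[[`, 0, 3L),
    stringsAsFactors = FALSE)
}
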