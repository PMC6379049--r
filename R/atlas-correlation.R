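#' Correlation analytics between the mRNA and protein layers
#'
#' Computes (a) per-tissue Spearman correlation of protein vs mRNA over
#' genes detected in both layers, (b) per-gene across-tissue correlation of
#' protein and mRNA for genes detected in at least `min_tissues` tissues in
#' both layers, (c) tissue x tissue Spearman correlation matrices within
#' each layer and of the per-gene protein/mRNA log-ratio. All pairing is
#' complete-case per comparison; comparisons with fewer than 3 paired
#' observations yield `NA`, never 0. Ties receive average ranks.
#'
#' @param mrna,protein [expression_matrix()]s sharing gene/tissue universes.
#' @param min_tissues minimum tissues a gene must be detected in (both
#'   layers) for the per-gene statistics (default 10; 20 or 29 tighten it).
#' @param method correlation method for the per-gene and tissue-matrix
#'   statistics (Spearman throughout by default).
#' @return list of class `correlation_suite`: `per_tissue`, `per_gene`,
#'   `tissue_cor_mrna`, `tissue_cor_protein`, `tissue_cor_ratio`.
#' @export
correlation_suite <- function(mrna, protein, min_tissues = 10L,
                              method = "spearman") {
  mv <- as_values(mrna); pv <- as_values(protein)
  genes <- intersect(rownames(mv), rownames(pv))
  tissues <- intersect(colnames(mv), colnames(pv))
  mv <- mv[genes, tissues, drop = FALSE]
  pv <- pv[genes, tissues, drop = FALSE]
  md <- detected(mrna)[genes, tissues, drop = FALSE]
  pd <- detected(protein)[genes, tissues, drop = FALSE]
  lm_ <- suppressWarnings(log10(mv)); lm_[!md] <- NA
  lp <- suppressWarnings(log10(pv)); lp[!pd] <- NA

  safe_cor <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L) return(c(rho = NA_real_, n = sum(ok)))
    # zero-variance pairs (e.g. perfectly flat genes) yield NA, silently
    c(rho = suppressWarnings(cor(a[ok], b[ok], method = method)),
      n = sum(ok))
  }

  per_tissue <- do.call(rbind, lapply(tissues, function(t) {
    s <- safe_cor(lm_[, t], lp[, t])
    data.frame(tissue = t, rho = s[["rho"]], n = s[["n"]],
               stringsAsFactors = FALSE)
  }))

  eligible <- rowSums(md & pd) >= min_tissues
  per_gene <- do.call(rbind, lapply(genes[eligible], function(g) {
    s <- safe_cor(lm_[g, ], lp[g, ])
    data.frame(gene_id = g, rho = s[["rho"]], n = s[["n"]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_gene))
    per_gene <- data.frame(gene_id = character(), rho = numeric(),
                           n = integer(), stringsAsFactors = FALSE)

  pairwise <- function(mat) {
    k <- ncol(mat)
    out <- matrix(NA_real_, k, k, dimnames = list(tissues, tissues))
    for (i in seq_len(k)) for (j in i:k) {
      s <- safe_cor(mat[, i], mat[, j])
      out[i, j] <- out[j, i] <- s[["rho"]]
    }
    out
  }
  ratio <- lp - lm_
  structure(list(per_tissue = per_tissue,
                 per_gene = per_gene,
                 tissue_cor_mrna = pairwise(lm_),
                 tissue_cor_protein = pairwise(lp),
                 tissue_cor_ratio = pairwise(ratio),
                 min_tissues = min_tissues, method = method),
            class = "correlation_suite")
}

#' @export
print.correlation_suite <- function(x, ...) {
  off <- function(m) m[upper.tri(m)]
  cat(sprintf(
    "correlation suite (%s): median per-tissue rho %.3f; %d genes with >= %d tissues\n",
    x$method, median(x$per_tissue$rho, na.rm = TRUE),
    nrow(x$per_gene), x$min_tissues))
  cat(sprintf("  tissue-tissue medians: mRNA %.3f, protein %.3f\n",
              median(off(x$tissue_cor_mrna), na.rm = TRUE),
              median(off(x$tissue_cor_protein), na.rm = TRUE)))
  invisible(x)
}

#' Ranked cumulative-abundance profile of one tissue
#'
#' Shares of total abundance contributed by genes ranked from most to least
#' abundant, plus the top-k shares for k in {1, 5, 10, 100}.
#'
#' @param matrix an [expression_matrix()].
#' @param tissue tissue (column) name or index.
#' @return list with `profile` (data.frame: rank, gene_id, share,
#'   cum_share) and `top_shares` (named vector).
#' @export
rank_abundance_profile <- function(matrix, tissue) {
  v <- as_values(matrix)[, tissue]
  tot <- sum(v)
  if (tot <= 0) stop("tissue column has no positive total")
  ord <- order(v, decreasing = TRUE)
  share <- v[ord] / tot
  prof <- data.frame(rank = seq_along(share),
                     gene_id = names(v)[ord] %||% as.character(ord),
                     share = unname(share),
                     cum_share = cumsum(unname(share)),
                     stringsAsFactors = FALSE)
  ks <- c(1L, 5L, 10L, 100L)
  ks <- ks[ks <= length(share)]
  top <- setNames(prof$cum_share[ks], paste0("top", ks))
  list(profile = prof, top_shares = top)
}

#' Overlap of the top-n most abundant genes between layers
#'
#' For each tissue, the fraction of genes shared between the n most
#' abundant transcripts and the n most abundant proteins. Ties are broken
#' by stable gene-id order.
#'
#' @param mrna,protein [expression_matrix()]s.
#' @param n size of the top set.
#' @return data.frame with `tissue` and `overlap` in [0, 1].
#' @export
top_n_overlap <- function(mrna, protein, n) {
  mv <- as_values(mrna); pv <- as_values(protein)
  genes <- intersect(rownames(mv), rownames(pv))
  tissues <- intersect(colnames(mv), colnames(pv))
  mv <- mv[genes, tissues, drop = FALSE]
  pv <- pv[genes, tissues, drop = FALSE]
  top_set <- function(x) {
    ord <- order(-x, names(x), method = "radix")  # stable tie-break
    names(x)[ord][seq_len(n)]
  }
  rows <- lapply(tissues, function(t) {
    det_both <- sum(mv[, t] > 0 & pv[, t] > 0)
    if (n > det_both)
      stop(sprintf("n = %d exceeds the %d genes detected in both layers (%s)",
                   n, det_both, t))
    a <- top_set(setNames(mv[, t], genes))
    b <- top_set(setNames(pv[, t], genes))
    data.frame(tissue = t, overlap = length(intersect(a, b)) / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Co-inertia analysis and the RV coefficient
#'
#' RV = trace(X'Y Y'X) / sqrt(trace((X'X)^2) trace((Y'Y)^2)) for
#' column-centred matrices with matched observations (genes) in rows and
#' the tissue profiles as columns -- a matrix correlation in [0, 1]
#' generalizing squared Pearson correlation, 1 when the two configurations
#' agree up to rotation/scaling. Orientation matters: with genes as the
#' observations the null value for unrelated data is near
#' `n_tissues / (n_tissues + n_genes)` (tiny), whereas transposing the
#' tables inflates the null towards 1 for gene-rich data, so the tissue
#' profiles must be the variables. Co-inertia axes come from the singular
#' decomposition of the tissue x tissue cross-covariance X'Y; the per-tissue
#' coordinates of each layer are the singular vectors scaled by the square
#' root of the axis covariance.
#'
#' @param X,Y numeric gene x tissue matrices (same genes as rows; matrices
#'   given as tissue x gene are detected by shared row/column names and
#'   transposed). Columns are centred internally. Missing values must be
#'   pre-imputed (see [impute_floor()]).
#' @param k number of co-inertia axes to return.
#' @return object of class `coinertia`: `rv`, `sample_scores_X`,
#'   `sample_scores_Y` (tissues x k), `axis_covariances` (decreasing).
#' @export
coinertia_rv <- function(X, Y, k = 2L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || ncol(X) != ncol(Y))
    stop("X and Y must have matching dimensions (genes x tissues)")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  S <- crossprod(Xc)    # tissue x tissue covariance structure
  T_ <- crossprod(Yc)
  C <- crossprod(Xc, Yc)
  den <- sqrt(sum(S * S) * sum(T_ * T_))
  if (den == 0) stop("zero total variance")
  rv <- sum(C * C) / den
  sk <- svd(C)
  k <- min(k, length(sk$d))
  scores_x <- sk$u[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(sk$d[seq_len(k)]), k)
  scores_y <- sk$v[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(sk$d[seq_len(k)]), k)
  rownames(scores_x) <- rownames(scores_y) <- colnames(X)
  colnames(scores_x) <- colnames(scores_y) <- paste0("axis", seq_len(k))
  structure(list(rv = rv,
                 sample_scores_X = scores_x,
                 sample_scores_Y = scores_y,
                 axis_covariances = sk$d[seq_len(k)]),
            class = "coinertia")
}

#' @export
print.coinertia <- function(x, ...) {
  cat(sprintf("co-inertia: RV = %.4f, %d axes (covariances %s)\n",
              x$rv, ncol(x$sample_scores_X),
              paste(signif(x$axis_covariances, 3), collapse = ", ")))
  invisible(x)
}

#' Replace missing values by a small positive floor
#'
#' Pre-imputation for co-inertia: missing entries are replaced by a
#' positive value `factor` times smaller than the smallest observed value
#' in the dataset.
#'
#' @param values numeric matrix with `NA` (or zeros treated as missing when
#'   `zero_as_missing`).
#' @param factor divisor applied to the dataset minimum (default 1e4).
#' @param zero_as_missing treat exact zeros as missing too.
#' @return matrix with missing entries replaced.
#' @export
impute_floor <- function(values, factor = 1e4, zero_as_missing = TRUE) {
  v <- as.matrix(values)
  miss <- is.na(v)
  if (zero_as_missing) miss <- miss | v == 0
  lo <- min(v[!miss])
  v[miss] <- lo / factor
  v
}
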