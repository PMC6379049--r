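#' Ranged major-axis (model II) regression
#'
#' Symmetric regression tolerating error in both variables: both variables
#' are range-standardized to [0, 1], the major-axis slope is computed on the
#' standardized data and back-transformed by `range(y)/range(x)`. The
#' intercept is `mean(y) - slope * mean(x)`. On noise-free collinear data
#' this equals ordinary least squares exactly; exchanging the axes inverts
#' the slope.
#'
#' @param x,y numeric vectors on the log10 scale, complete pairs, `n >= 3`.
#' @return object of class `rma_fit`: list with `slope`, `intercept`, `n`,
#'   `method = "rma"` and the Pearson correlation `r`.
#' @export
rma_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("ranged major-axis regression needs at least 3 pairs")
  rx <- diff(range(x)); ry <- diff(range(y))
  if (rx == 0 || ry == 0) stop("zero range in one of the variables")
  xs <- (x - min(x)) / rx
  ys <- (y - min(y)) / ry
  sxx <- var(xs); syy <- var(ys); sxy <- cov(xs, ys)
  if (sxx == 0 || syy == 0) stop("zero variance in one of the variables")
  b <- if (sxy == 0) {
    # degenerate: no covariance; major axis is undefined in sign, take +1
    sqrt(syy / sxx)
  } else {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  slope <- b * ry / rx
  structure(list(slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 n = n, method = "rma",
                 r = cor(x, y)),
            class = "rma_fit")
}

#' @export
print.rma_fit <- function(x, ...) {
  cat(sprintf("ranged major-axis fit: slope %.4f, intercept %.4f (n = %d, r = %.3f)\n",
              x$slope, x$intercept, x$n, x$r))
  invisible(x)
}

#' Per-tissue protein~mRNA log-log slopes
#'
#' Convenience wrapper fitting [rma_regression()] of log10 protein on log10
#' mRNA in every tissue, using genes detected in both layers.
#'
#' @param mrna,protein [expression_matrix()]s sharing gene and tissue
#'   universes.
#' @return data.frame with tissue, slope, intercept, n and r.
#' @export
atlas_slopes <- function(mrna, protein) {
  mv <- as_values(mrna); pv <- as_values(protein)
  common <- intersect(rownames(mv), rownames(pv))
  mv <- mv[common, , drop = FALSE]; pv <- pv[common, , drop = FALSE]
  md <- detected(mrna)[common, , drop = FALSE]
  pd <- detected(protein)[common, , drop = FALSE]
  rows <- lapply(colnames(mv), function(t) {
    ok <- md[, t] & pd[, t]
    fit <- rma_regression(log10(mv[ok, t]), log10(pv[ok, t]))
    data.frame(tissue = t, slope = fit$slope, intercept = fit$intercept,
               n = fit$n, r = fit$r, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
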