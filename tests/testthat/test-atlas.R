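test_that("log/median normalization centres detected entries at zero", {
  m <- expression_matrix(matrix(c(1, 10, 100), 3, 1,
                                dimnames = list(paste0("g", 1:3), "t1")),
                         "fpkm", detect_threshold = 1)
  out <- log_median_normalize(m)
  expect_equal(unname(out[, 1]), c(-1, 0, 1))

  # already centred on the log scale: unchanged
  m2 <- expression_matrix(matrix(c(0.1, 1, 10), 3, 1), "fpkm",
                          detect_threshold = 0.01)
  expect_equal(unname(log_median_normalize(m2)[, 1]), c(-1, 0, 1))

  # 2x2 toy: per-tissue medians land on 0
  m3 <- expression_matrix(matrix(c(1, 100, 10, 10), 2, 2), "fpkm",
                          detect_threshold = 0.1)
  out3 <- log_median_normalize(m3)
  expect_equal(unname(apply(out3, 2, median)), c(0, 0))

  # undetected entries become NA, not 0
  m4 <- expression_matrix(matrix(c(0.5, 10, 100, 2), 2, 2), "fpkm", 1)
  expect_true(is.na(log_median_normalize(m4)[1, 1]))

  expect_error(log_median_normalize(
    expression_matrix(matrix(c(0, 0, 1, 2), 2, 2), "intensity")),
    "no detected")
})

test_that("specificity classes follow the fivefold rules and precedence", {
  mk <- function(x) expression_matrix(
    matrix(x, 1, length(x), dimnames = list("g", paste0("t", seq_along(x)))),
    "fpkm", 1)
  cls <- function(x, fold = 5)
    as.character(classify_specificity(mk(x), fold)$category)
  expect_identical(cls(c(50, 2, 1, 1, 1)), "tissue_enriched")
  expect_identical(cls(c(20, 18, 1, 1, 1, 1, 1, 1)), "group_enriched")
  expect_identical(cls(c(10, 10, 10, 10, 10)), "expressed_in_all")
  expect_identical(cls(c(3, 2, 0, 0, 0)), "mixed")
  expect_identical(cls(c(0, 0, 0)), "not_detected")
  # enhanced: above fold x mean of others, but no enriched/group call
  expect_identical(cls(c(30, 7, 6, 5, 5, 5)), "tissue_enhanced")
  # group rule reports the group members
  call <- classify_specificity(mk(c(20, 18, 1, 1, 1, 1, 1, 1)))
  expect_identical(call$supporting_tissues, "t1,t2")
  expect_error(classify_specificity(mk(c(1, 2))), "at least 3")
})

test_that("classification is exhaustive and mutually exclusive", {
  set.seed(42)
  for (rep in 1:3) {
    v <- matrix(rexp(60 * 8, rate = 0.2), 60, 8)
    v[sample(length(v), 50)] <- 0
    m <- expression_matrix(v, "fpkm", 1)
    calls <- classify_specificity(m)
    expect_equal(nrow(calls), 60L)
    expect_false(any(is.na(calls$category)))
    # at fold -> infinity only the non-elevated classes survive
    calls_inf <- classify_specificity(m, fold = Inf)
    expect_true(all(as.character(calls_inf$category) %in%
                      c("expressed_in_all", "mixed", "not_detected")))
  }
})

test_that("RMA regression is exact on collinear data and symmetric", {
  fit <- rma_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$slope, 2.0)
  expect_equal(fit$intercept, 0.0)
  expect_identical(fit$method, "rma")

  # equals OLS exactly on noise-free collinear data
  set.seed(1)
  x <- rnorm(50); y <- 3.7 * x - 1.2
  fit2 <- rma_regression(x, y)
  ols <- unname(coef(lm(y ~ x)))
  expect_equal(fit2$slope, ols[2], tolerance = 1e-12)
  expect_equal(fit2$intercept, ols[1], tolerance = 1e-12)

  # symmetry: slope(x,y) * slope(y,x) = 1
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(40); y <- 2 * x + rnorm(40, 0, 0.7)
    expect_equal(rma_regression(x, y)$slope * rma_regression(y, x)$slope,
                 1, tolerance = 1e-9)
  }
  expect_error(rma_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(rma_regression(c(1, 1, 1), c(1, 2, 3)), "zero range")
})

test_that("proteomic ruler conserves histone mass and known closed forms", {
  const <- copy_number_constants()
  # single histone of 14 kDa: copies = N_A * m_DNA / M
  out <- protein_copy_numbers(c(H1 = 123), c(H1 = 14000), "H1")
  expect_equal(out$copies_per_cell,
               const$avogadro * const$dna_mass_per_cell / 14000,
               tolerance = 1e-12)
  expect_equal(out$copies_per_cell, 2.80e8, tolerance = 0.01)

  set.seed(2)
  ints <- setNames(rexp(20, 1e-6), paste0("P", 1:20))
  mm <- setNames(runif(20, 1e4, 2e5), names(ints))
  hist_ids <- c("P1", "P2", "P3")
  out <- protein_copy_numbers(ints, mm, hist_ids)
  # conservation: sum of histone copies x molar mass / N_A = DNA mass
  h <- out$copies_per_cell[match(hist_ids, out$entity_id)]
  expect_equal(sum(h * mm[hist_ids]) / const$avogadro,
               const$dna_mass_per_cell, tolerance = 1e-12)
  # scale invariance
  out10 <- protein_copy_numbers(ints * 10, mm, hist_ids)
  expect_equal(out$copies_per_cell, out10$copies_per_cell,
               tolerance = 1e-12)
  # zero intensity -> zero copies
  ints["P4"] <- 0
  expect_equal(protein_copy_numbers(ints, mm, hist_ids)$copies_per_cell[4],
               0)
  expect_error(protein_copy_numbers(c(A = 1), c(A = 1e4), "H9"),
               "histone")
})

test_that("mRNA copy numbers follow the ruler chain and conserve mass", {
  const <- copy_number_constants()
  # hand evaluation: R=1e6, one transcript L=1000, FPKM=1
  out <- mrna_copy_numbers(c(t1 = 1), c(t1 = 1000), rep(1e6, 5))
  expected <- (0.02 * (1e6 * 2.32e6 / 0.8)) / (321 * 1000)
  expect_equal(out$copies_per_cell, expected, tolerance = 1e-12)
  expect_equal(out$copies_per_cell, 1.81e5, tolerance = 0.01)

  set.seed(3)
  fpkm <- setNames(rexp(30, 0.1), paste0("t", 1:30))
  len <- setNames(sample(500:3000, 30), names(fpkm))
  out <- mrna_copy_numbers(fpkm, len, c(2e6, 1e6, 3e6))
  masses <- attr(out, "masses")
  # conservation: total transcript mass = mRNA mass = 2% of total RNA
  got <- sum(out$copies_per_cell * len) * const$mean_nt_residue_mass /
    const$avogadro
  expect_equal(got, masses[["mRNA"]], tolerance = 1e-12)
  expect_equal(masses[["mRNA"]], 0.02 * masses[["total_RNA"]],
               tolerance = 1e-12)
  # copies track FPKM ratios at fixed lengths
  len2 <- setNames(rep(1000, 3), c("a", "b", "c"))
  o2 <- mrna_copy_numbers(c(a = 1, b = 2, c = 4), len2, 1e6)
  expect_equal(o2$copies_per_cell[2] / o2$copies_per_cell[1], 2)
  expect_error(mrna_copy_numbers(c(a = 0), c(a = 1000), 1e6), "zero")
})

test_that("correlation suite behaves on monotone and identical layers", {
  set.seed(4)
  v <- matrix(10^runif(200, 0, 3), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("t", 1:4)))
  mrna <- expression_matrix(v, "fpkm", 1)
  prot <- expression_matrix(v^1.7, "intensity")  # monotone transform
  cs <- correlation_suite(mrna, prot, min_tissues = 3L)
  expect_true(all(abs(cs$per_tissue$rho - 1) < 1e-12))
  expect_true(all(diag(cs$tissue_cor_mrna) == 1))
  expect_true(all(cs$per_tissue$rho >= -1 & cs$per_tissue$rho <= 1))

  # noise-free generator: across-tissue correlations are 1 wherever defined
  cfg <- sim_config(n_genes = 300L, n_tissues = 12L, seed = 6,
                    noise_sd = 0, dropout_rate = 0,
                    frac_tissue_enriched = 0.2)
  at <- gen_abundance_atlas(NULL, cfg)
  cs2 <- correlation_suite(at$mrna, at$protein, min_tissues = 10L)
  rho <- cs2$per_gene$rho
  expect_true(all(abs(rho[!is.na(rho)] - 1) < 1e-9))
  enr <- at$truth$gene_id[at$truth$enriched]
  expect_false(any(is.na(cs2$per_gene$rho[cs2$per_gene$gene_id %in% enr])))
})

test_that("rank-abundance shares and top-n overlap are exact", {
  m <- expression_matrix(matrix(c(8, 1, 1), 3, 1,
                                dimnames = list(paste0("g", 1:3), "t")),
                         "fpkm", 1)
  ra <- rank_abundance_profile(m, 1L)
  expect_equal(unname(ra$top_shares["top1"]), 0.8)
  expect_equal(max(ra$profile$cum_share), 1)
  expect_true(all(diff(ra$profile$cum_share) >= 0))

  u <- expression_matrix(matrix(rep(2, 40), 40, 1), "fpkm", 1)
  expect_equal(unname(rank_abundance_profile(u, 1L)$top_shares["top10"]),
               10 / 40)

  single <- expression_matrix(matrix(c(5, 0, 0), 3, 1), "fpkm", 1)
  expect_equal(unname(rank_abundance_profile(single, 1L)$top_shares["top1"]),
               1.0)

  # overlap: identical ranking = 1; reversed 6 genes, n = 3 -> 0
  v6 <- matrix(c(6:1), 6, 1, dimnames = list(paste0("g", 1:6), "t"))
  m6 <- expression_matrix(v6, "fpkm", 1)
  p6 <- expression_matrix(v6[6:1, , drop = FALSE][paste0("g", 1:6), ,
                                                  drop = FALSE] * 0 +
                            matrix(1:6, 6, 1,
                                   dimnames = list(paste0("g", 1:6), "t")),
                          "intensity")
  expect_equal(top_n_overlap(m6, m6, 3)$overlap, 1.0)
  expect_equal(top_n_overlap(m6, p6, 3)$overlap, 0.0)
  expect_error(top_n_overlap(m6, p6, 7), "exceeds")
})

test_that("co-inertia RV matches its definition and invariances", {
  set.seed(5)
  X <- matrix(rnorm(200 * 8), 200, 8)   # genes x tissues
  expect_equal(coinertia_rv(X, X)$rv, 1.0, tolerance = 1e-12)

  # rotation invariance of the Y side (orthogonal mix of tissue profiles)
  Q <- qr.Q(qr(matrix(rnorm(8 * 8), 8, 8)))
  expect_equal(coinertia_rv(X, X %*% Q)$rv, 1.0, tolerance = 1e-10)

  # independent oracle: the same trace on the observation configurations
  # W = Xc Xc' (cyclic-trace identity), computed the long way round
  Y <- matrix(rnorm(200 * 8), 200, 8)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  WX <- tcrossprod(Xc); WY <- tcrossprod(Yc)
  rv_bf <- sum(WX * WY) / sqrt(sum(WX^2) * sum(WY^2))
  expect_equal(coinertia_rv(X, Y)$rv, rv_bf, tolerance = 1e-12)

  ci <- coinertia_rv(X, Y, k = 3)
  expect_true(all(diff(ci$axis_covariances) <= 1e-9))
  expect_true(ci$rv >= 0 && ci$rv <= 1)
  expect_equal(dim(ci$sample_scores_X), c(8L, 3L))
  expect_error(coinertia_rv(matrix(0, 4, 3), matrix(0, 4, 3)),
               "zero total variance")

  # imputation floor: 1e4 below the observed minimum
  v <- matrix(c(NA, 5, 2, 0), 2, 2)
  imp <- impute_floor(v)
  expect_equal(imp[1, 1], 2 / 1e4)
  expect_equal(imp[2, 2], 2 / 1e4)
})
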