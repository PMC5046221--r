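test_that("predictability computes r and clipped explained variance", {
  set.seed(2)
  obs <- matrix(rnorm(3 * 2000), 3, 2000,
                dimnames = list(c("a", "b", "c"), NULL))
  pred <- obs
  pred["b", ] <- -obs["b", ]
  pred["c", ] <- obs["c", ] + rnorm(2000)   # equal signal and noise sd
  pr <- predictability(pred, obs)
  expect_equal(pr$R2[pr$gene == "a"], 1 - 1e-9)
  expect_equal(pr$R2[pr$gene == "b"], 0)          # negative r is unpredictable
  expect_equal(pr$r[pr$gene == "c"], sqrt(0.5), tolerance = 0.05)

  const <- pred; const["a", ] <- 1
  pr2 <- predictability(const, obs)
  expect_true(is.na(pr2$r[pr2$gene == "a"]))
  expect_equal(pr2$R2[pr2$gene == "a"], 0)
  expect_error(predictability(pred[, 1:2], obs[, 1:2]), "3 samples")
})

test_that("flow matrix splits explained variance among predictors", {
  genes <- c("r", "t")
  net <- make_network_shim(genes,
                           edges = data.frame(regulator = "r", target = "t",
                                              coefficient = 1),
                           cis = stats::setNames(c(0, 1), genes))
  expr <- matrix(c(1, 0.5), 2, 1, dimnames = list(genes, "p1"))
  cn <- matrix(c(0, 1), 2, 1, dimnames = list(genes, "p1"))
  prof <- data.frame(gene = genes, r = c(NA, 1), R2 = c(0, 1 - 1e-9))
  fm <- build_flow_matrix(net, expr, cn, prof, mode = "patient",
                          patient = "p1")
  expect_equal(fm$F["r", "t"], 0.5, tolerance = 1e-6)
  expect_equal(unname(fm$p_cis["t"]), 0.5, tolerance = 1e-6)

  # R2 = 0 zeroes the whole column
  prof0 <- prof; prof0$R2[2] <- 0
  fm0 <- build_flow_matrix(net, expr, cn, prof0, mode = "patient",
                           patient = "p1")
  expect_equal(Matrix::colSums(abs(fm0$F))[["t"]], 0)

  # absent edge means zero proportion
  expect_equal(fm$F["t", "r"], 0)
  expect_lt(max(Matrix::colSums(abs(fm$F))), 1)
})

test_that("propagation matches the geometric-series closed form", {
  # acyclic single edge: F* = F, standardized column sums to 100
  F1 <- matrix(c(0, 0, 0.5, 0), 2, 2, dimnames = list(c("a", "b"),
                                                      c("a", "b")))
  ip <- propagate(F1, tol = 1e-9)
  expect_equal(as.matrix(ip$raw), F1)
  expect_equal(Matrix::colSums(ip$standardized)[["b"]], 100)

  # 2-cycle closed form (I - F)^-1 - I
  F2 <- matrix(c(0, .5, .5, 0), 2, 2)
  ip2 <- propagate(F2, tol = 1e-12)
  expect_equal(as.matrix(ip2$raw),
               matrix(c(1/3, 2/3, 2/3, 1/3), 2, 2), tolerance = 1e-9)

  # zero flow stays zero
  expect_equal(sum(abs(propagate(matrix(0, 3, 3))$raw)), 0)

  # random sparse contractive matrices: series vs closed form
  set.seed(10)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    F <- as.matrix(Matrix::rsparsematrix(n, n, 0.1,
                                         rand.x = function(k) runif(k)))
    cs <- colSums(F)
    F <- sweep(F, 2, pmax(cs / 0.9, 1), "/")   # column sums <= 0.9
    a <- propagate(F, tol = 1e-10)
    b <- propagate(F, method = "closed")
    expect_lt(max(abs(a$raw - b$raw)), 1e-6)
    std_sums <- Matrix::colSums(a$standardized)
    expect_true(all(abs(std_sums[std_sums > 0] - 100) < 1e-6))
  }

  expect_error(propagate(matrix(c(0, 1, 1, 0), 2, 2)), "contractive")
})

test_that("impacts grow monotonically with predictability", {
  set.seed(4)
  n <- 15
  F <- as.matrix(Matrix::rsparsematrix(n, n, 0.2,
                                       rand.x = function(k) runif(k)))
  F <- sweep(F, 2, pmax(colSums(F) / 0.5, 1), "/")
  up <- F
  up[, 3] <- up[, 3] * 1.5   # emulate an increase of R2 for gene 3
  a <- propagate(F, tol = 1e-10)$raw
  b <- propagate(up, tol = 1e-10)$raw
  expect_true(all(b[, 3] >= a[, 3] - 1e-12))
})

test_that("direct-neighbour baseline is dominated by full propagation", {
  genes <- c("j", "m", "i")
  F <- matrix(0, 3, 3, dimnames = list(genes, genes))
  F["j", "m"] <- 0.4; F["m", "i"] <- 0.5
  full <- propagate(F, tol = 1e-12)
  base <- direct_neighbor_impacts(F)
  expect_equal(base$raw["j", "i"], 0)
  expect_gt(full$raw["j", "i"], 0)
  expect_true(all(as.matrix(base$raw) <= as.matrix(full$raw) + 1e-12))

  # acyclic single edge: baseline identical to full propagation
  F1 <- matrix(c(0, 0, .5, 0), 2, 2)
  expect_equal(as.matrix(direct_neighbor_impacts(F1)$raw),
               as.matrix(propagate(F1, tol = 1e-12)$raw))
})

test_that("signed patient impacts carry sign products along paths", {
  genes <- c("j", "m", "i")
  # activator j -> m, repressor m -> i
  net <- make_network_shim(genes,
    edges = data.frame(regulator = c("j", "m"), target = c("m", "i"),
                       coefficient = c(0.6, -0.5)),
    cis = stats::setNames(c(1, 0, 0), genes))
  expr <- matrix(c(1, 0.6, -0.3), 3, 1, dimnames = list(genes, "p1"))
  cn <- matrix(c(1, 0, 0), 3, 1, dimnames = list(genes, "p1"))
  prof <- data.frame(gene = genes, r = 1, R2 = c(0.9, 0.9, 0.9))
  si <- signed_patient_impacts(net, expr, cn, prof, "p1", tol = 1e-10)
  expect_gt(si$raw["j", "m"], 0)          # activating impact
  expect_lt(si$raw["m", "i"], 0)          # repressing impact
  expect_lt(si$raw["j", "i"], 0)          # two-step activator + repressor

  # magnitudes equal the unsigned propagation of |entries|
  fm <- build_flow_matrix(net, expr, cn, prof, mode = "patient",
                          patient = "p1", signed = TRUE)
  unsigned <- propagate(abs(fm$F), tol = 1e-10)
  expect_equal(abs(as.matrix(si$raw)), as.matrix(unsigned$raw),
               tolerance = 1e-9)

  # |signed| <= unsigned on the same patient
  fm_abs <- build_flow_matrix(net, expr, cn, prof, mode = "patient",
                              patient = "p1", signed = FALSE)
  full_abs <- propagate(fm_abs, tol = 1e-10)
  expect_true(all(abs(as.matrix(si$raw)) <= as.matrix(full_abs$raw) + 1e-9))
})

test_that("patient-mode impacts average to cohort-mode impacts", {
  cfg <- sim_config(n_genes = 30, n_samples = 40, cis_fraction = 1,
                    cna_rate_frequent = 0.3, cna_rate_rare = 0.3,
                    noise_sd = 0.4, seed = 12)
  gt <- simulate_network(cfg, fixed_in_degree = TRUE)
  coh <- simulate_cohort(gt, cfg)
  net <- shim_from_gt(gt)
  pred <- predict_expression(net, coh$expression, coh$copy_number)
  prof <- predictability(pred, coh$expression)
  cohort_imp <- propagate(build_flow_matrix(net, coh$expression,
                                            coh$copy_number, prof),
                          tol = 1e-8)
  acc <- NULL
  for (p in colnames(coh$expression)) {
    fm <- build_flow_matrix(net, coh$expression, coh$copy_number, prof,
                            mode = "patient", patient = p)
    imp <- propagate(fm, tol = 1e-8)
    acc <- if (is.null(acc)) imp$raw else acc + imp$raw
  }
  acc <- acc / ncol(coh$expression)
  nz <- as.matrix(cohort_imp$raw) != 0 | as.matrix(acc) != 0
  rho <- stats::cor(as.matrix(cohort_imp$raw)[nz], as.matrix(acc)[nz],
                    method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("forward model beats reverse on a directed chain", {
  genes <- c("j", "i", "x", "w", "v", "u")
  n <- length(genes)
  # j drives i; u weakly drives j, so the reverse model has flow to rank
  gt <- list(genes = genes,
             cis = stats::setNames(c(1, rep(0, n - 1)), genes),
             edges = data.frame(regulator = c("j", "u"), target = c("i", "j"),
                                coefficient = c(0.8, 0.3)),
             A = Matrix::sparseMatrix(i = c(1, 6), j = c(2, 1),
                                      x = c(0.8, 0.3), dims = c(n, n),
                                      dimnames = list(genes, genes)))
  class(gt) <- "gt_network"
  pert <- simulate_perturbations(gt, genes = "j", n_experiments_per_gene = 15,
                                 top_k = 4, noise_sd = 0.01, seed = 2)
  imp <- structure(list(
    raw = gt$A, standardized = cnaimpact:::standardize_columns(gt$A),
    genes = genes, signed = FALSE, iterations = 1L, method = "direct",
    tol = NA_real_), class = "impact_matrix")
  v <- forward_reverse_validation(imp, pert)
  expect_lte(v$table$forward_p, v$table$reverse_p)
  expect_true(is.na(v$ks_forward))   # pooling undefined for one gene
})
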