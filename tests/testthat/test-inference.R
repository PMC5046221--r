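make_planted_cohort <- function(n = 120, seed = 1) {
  # g1, g2 regulate g3; regulators driven by their own copy number
  set.seed(seed)
  genes <- c("g1", "g2", "g3", "g4", "g5")
  cn <- matrix(sample(c(-1, 0, 1), 5 * n, replace = TRUE, c(.2, .6, .2)),
               5, n, dimnames = list(genes, paste0("s", 1:n)))
  e1 <- cn[1, ] + rnorm(n, 0, 0.3)
  e2 <- cn[2, ] + rnorm(n, 0, 0.3)
  e3 <- 0.7 * e1 - 0.5 * e2 + rnorm(n, 0, 0.2)
  e4 <- rnorm(n); e5 <- rnorm(n)
  expr <- rbind(e1, e2, e3, e4, e5)
  dimnames(expr) <- dimnames(cn)
  list(expr = expr, cn = cn)
}

test_that("fit_gene_model recovers a planted sparse model", {
  d <- make_planted_cohort()
  m <- fit_gene_model("g3", d$expr, d$cn, cv_repeats = 3, seed = 7)
  expect_setequal(names(m$trans_coefs)[abs(m$trans_coefs) > 0.05],
                  c("g1", "g2"))
  expect_equal(unname(m$trans_coefs["g1"]), 0.7, tolerance = 0.1)
  expect_equal(unname(m$trans_coefs["g2"]), -0.5, tolerance = 0.1)
  expect_lt(max(m$trans_pvalues[c("g1", "g2")]), 5e-5)

  m2 <- fit_gene_model("g3", d$expr, d$cn, cv_repeats = 3, seed = 7)
  expect_identical(m[c("lambda", "trans_coefs", "cis_coef")],
                   m2[c("lambda", "trans_coefs", "cis_coef")])

  flat <- d$expr; flat["g3", ] <- 1
  expect_error(fit_gene_model("g3", flat, d$cn, cv_repeats = 1),
               "unpredictable")
  expect_error(fit_gene_model("g3", d$expr[, 1:5], d$cn[, 1:5]),
               "folds")
})

test_that("stability filter keeps only predictors significant in all instances", {
  mk <- function(p1, p2) structure(list(
    target = "t", lambda = 1, cis_coef = 0, cis_pvalue = 1,
    trans_coefs = c(a = 0.5, b = 0.2),
    trans_pvalues = c(a = p1, b = p2), rmse = 0.1, n_samples = 50L),
    class = "gene_model")
  fits <- c(replicate(9, mk(1e-6, 1e-6), simplify = FALSE),
            list(mk(1e-6, 1e-3)))   # b misses the cut in one instance
  cons <- stability_filter(fits)
  expect_identical(names(cons$trans_coefs), "a")
  expect_equal(unname(cons$trans_coefs["a"]), 0.5)

  all10 <- replicate(10, mk(1e-6, 1e-6), simplify = FALSE)
  expect_setequal(names(stability_filter(all10)$trans_coefs), c("a", "b"))

  none <- replicate(10, mk(0.5, 0.9), simplify = FALSE)
  expect_length(stability_filter(none)$trans_coefs, 0L)

  # lowering alpha never adds predictors
  loose <- names(stability_filter(fits, alpha = 1e-2)$trans_coefs)
  tight <- names(stability_filter(fits, alpha = 1e-6)$trans_coefs)
  expect_true(all(tight %in% loose))

  bad <- c(all10[1:9], list(structure(modifyList(all10[[1]],
                                                 list(target = "u")),
                                      class = "gene_model")))
  expect_error(stability_filter(bad), "mismatched")
})

test_that("local-predictor removal works on gene ranks per chromosome", {
  ann <- make_annotation(paste0("g", 1:120),
                         c(rep("1", 110), rep("2", 10)),
                         c(seq(1e4, 110e4, by = 1e4),
                           seq(1e4, 10e4, by = 1e4)) ,
                         c(seq(1e4, 110e4, by = 1e4),
                           seq(1e4, 10e4, by = 1e4)) + 5000)
  m <- structure(list(
    target = "g60", lambda = 1, cis_coef = 0.5, cis_pvalue = 1e-9,
    trans_coefs = c(g10 = 0.3, g9 = 0.4, g111 = 0.2, gZ = 0.1),
    trans_pvalues = c(g10 = 1e-9, g9 = 1e-9, g111 = 1e-9, gZ = 1e-9),
    rmse = 0, n_samples = 100L), class = "gene_model")
  # g10 is exactly 50 ranks upstream of g60 -> removed; g9 is 51 -> kept;
  # g111 is adjacent in bp but on chromosome 2 -> kept; gZ unknown -> kept
  expect_warning(out <- remove_local_predictors(m, ann), "gZ")
  expect_setequal(names(out$trans_coefs), c("g9", "g111", "gZ"))
  expect_equal(out$cis_coef, 0.5)
})

test_that("degree-preserving randomization keeps degrees and moves edges", {
  set.seed(3)
  genes <- paste0("g", 1:12)
  edges <- data.frame(regulator = rep(genes[1:6], each = 2),
                      target = c(genes[7:12], genes[c(8, 7, 10, 9, 12, 11)]),
                      coefficient = rnorm(12))
  net <- make_network_shim(genes, edges = edges)
  deg <- function(e) list(out = table(factor(e$regulator, levels = genes)),
                          inn = table(factor(e$target, levels = genes)))
  moved <- 0L
  for (s in 1:10) {
    r <- randomize_network(net, seed = s)
    tr <- r$edges[r$edges$type == "trans", ]
    expect_identical(deg(tr), deg(net$edges[net$edges$type == "trans", ]))
    if (!setequal(paste(tr$regulator, tr$target),
                  paste(edges$regulator, edges$target))) moved <- moved + 1L
  }
  expect_gte(moved, 9L)

  tiny <- make_network_shim(c("a", "b"),
                            edges = data.frame(regulator = "a", target = "b",
                                               coefficient = 1))
  expect_warning(same <- randomize_network(tiny, seed = 1), "too small")
  expect_identical(same$edges, tiny$edges)
})

test_that("variance inflation factors match their closed form", {
  set.seed(5)
  n <- 400
  x1 <- rnorm(n); x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  expr <- rbind(t = rnorm(n), a = x1, b = x2)
  colnames(expr) <- paste0("s", 1:n)
  cn <- expr * 0
  m <- structure(list(target = "t", lambda = 1, cis_coef = 0, cis_pvalue = 1,
                      trans_coefs = c(a = 1, b = 1),
                      trans_pvalues = c(a = 0, b = 0), rmse = 0,
                      n_samples = n), class = "gene_model")
  v <- compute_vif(m, expr, cn)
  r2 <- stats::cor(x1, x2)^2
  expect_equal(unname(v["a"]), 1 / (1 - r2), tolerance = 1e-6)

  expr2 <- rbind(t = rnorm(n), a = x1, b = x1)
  colnames(expr2) <- colnames(expr)
  expect_warning(v2 <- compute_vif(m, expr2, cn), "collinear")
  expect_true(all(is.infinite(v2)))

  # orthogonal predictors have VIF ~ 1
  expr3 <- rbind(t = rnorm(n), a = rnorm(n), b = rnorm(n))
  colnames(expr3) <- colnames(expr)
  expect_equal(max(compute_vif(m, expr3, cn)), 1, tolerance = 0.05)
})

test_that("infer_network is deterministic and prunes a permuted cohort", {
  cfg <- sim_config(n_genes = 15, n_samples = 80, cis_fraction = 1,
                    cna_rate_frequent = 0.3, cna_rate_rare = 0.3,
                    noise_sd = 0.4, seed = 6)
  net <- simulate_network(cfg, fixed_in_degree = TRUE)
  coh <- simulate_cohort(net, cfg)
  f1 <- infer_network(coh$expression, coh$copy_number, net$annotation,
                      n_instances = 2, cv_repeats = 1, seed = 5)
  f2 <- infer_network(coh$expression, coh$copy_number, net$annotation,
                      n_instances = 2, cv_repeats = 1, seed = 5)
  expect_identical(f1$edges, f2$edges)
  expect_gt(nrow(f1$edges), 0)

  # destroying the cross-gene structure removes nearly all consensus edges
  set.seed(1)
  permuted <- t(apply(coh$expression, 1, sample))
  dimnames(permuted) <- dimnames(coh$expression)
  f0 <- infer_network(permuted, coh$copy_number, net$annotation,
                      n_instances = 2, cv_repeats = 1, seed = 5)
  expect_lte(nrow(f0$edges[f0$edges$type == "trans", ]),
             0.05 * max(nrow(f1$edges[f1$edges$type == "trans", ]), 20))
})

test_that("consensus predictions reproduce a noiseless cohort", {
  cfg <- sim_config(n_genes = 12, n_samples = 60, cis_fraction = 1,
                    cna_rate_frequent = 0.3, cna_rate_rare = 0.3,
                    regulators_per_gene = 1, noise_sd = 1e-3, seed = 21)
  gt <- simulate_network(cfg, fixed_in_degree = TRUE)
  coh <- simulate_cohort(gt, cfg)
  fit <- infer_network(coh$expression, coh$copy_number, gt$annotation,
                       n_instances = 2, cv_repeats = 1, seed = 2)
  pred <- predict_expression(fit, coh$expression, coh$copy_number)
  prof <- predictability(pred, coh$expression)
  expect_true(all(prof$r > 0.99, na.rm = TRUE))

  # residuals and simulate methods round out the model interface
  res <- residuals(fit, coh$expression, coh$copy_number)
  expect_equal(res, coh$expression - pred)
  sim <- simulate(fit, nsim = 20, seed = 3)
  expect_equal(dim(sim$expression), c(12L, 20L))
  expect_identical(simulate(fit, nsim = 20, seed = 3), sim)
})
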