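#' Fit the sparse linear expression model of one target gene
#'
#' Models the expression of `target` as a linear combination of its own copy
#' number (cis term) and the expression of all other genes (trans terms),
#' fitted by the lasso. The penalty is chosen as the mean of the CV-optimal
#' lambda over `cv_repeats` independent repeats of `cv_folds`-fold
#' cross-validation; the reported coefficients are the lasso solution at that
#' penalty on all samples. Active predictors receive covariance-test p-values
#' at their first entry into the lasso path ([lasso_path_pvalues()] computed
#' on the active set).
#'
#' @param target Gene id (must be a row of both matrices).
#' @param expr,cn Genes-by-samples expression and copy-number matrices with a
#'   common sample order.
#' @param cv_repeats,cv_folds Repeats and folds of the cross-validation used
#'   to pick the penalty.
#' @param nlambda Length of the lambda path handed to the solver.
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `gene_model`: list(target, lambda, cis_coef,
#'   cis_pvalue, trans_coefs (named), trans_pvalues (named), rmse,
#'   n_samples). Predictors absent from the maps have coefficient exactly 0.
#' @export
fit_gene_model <- function(target, expr, cn, cv_repeats = 10, cv_folds = 10,
                           nlambda = 100, seed = 1L) {
  if (!target %in% rownames(expr) || !target %in% rownames(cn))
    stop("target '", target, "' missing from input matrices", call. = FALSE)
  D <- ncol(expr)
  if (D < cv_folds) stop("fewer samples than cross-validation folds",
                         call. = FALSE)
  y <- expr[target, ]
  if (stats::sd(y) == 0) stop("unpredictable target '", target,
                              "': zero variance", call. = FALSE)
  cis_name <- ".cis"
  X <- t(rbind(cn[target, , drop = FALSE],
               expr[setdiff(rownames(expr), target), , drop = FALSE]))
  colnames(X)[1L] <- cis_name

  lam <- numeric(cv_repeats)
  for (r in seq_len(cv_repeats)) {
    set.seed(derive_seed(seed, r))
    foldid <- sample(rep_len(seq_len(cv_folds), D))
    cvfit <- glmnet::cv.glmnet(X, y, foldid = foldid, intercept = FALSE,
                               nlambda = nlambda)
    lam[r] <- cvfit$lambda.min
  }
  lambda_i <- mean(lam)
  fit <- glmnet::glmnet(X, y, lambda = lambda_i, intercept = FALSE)
  beta <- drop(as.matrix(fit$beta))
  active <- names(beta)[beta != 0]
  pv <- stats::setNames(numeric(0), character(0))
  if (length(active) >= 1L)
    pv <- suppressWarnings(
      lasso_path_pvalues(X[, active, drop = FALSE], y))
  rmse <- sqrt(mean((y - drop(X %*% beta))^2))
  trans <- setdiff(active, cis_name)
  structure(list(target = target, lambda = lambda_i,
                 cis_coef = unname(beta[cis_name]),
                 cis_pvalue = if (cis_name %in% active)
                   unname(pv[cis_name]) else 1,
                 trans_coefs = beta[trans],
                 trans_pvalues = pv[trans],
                 rmse = rmse, n_samples = D),
            class = "gene_model")
}

#' Stability filter across repeated fits of one target
#'
#' Keeps exactly those predictors whose covariance-test p-value is below
#' `alpha` in every fit instance; retained coefficients are the mean across
#' instances and the reported p-value is the maximum (worst case) across
#' instances.
#'
#' @param fits List of `gene_model` objects for the same target.
#' @param alpha Per-predictor significance threshold (default 5e-5).
#' @return A consensus `gene_model`.
#' @export
stability_filter <- function(fits, alpha = 5e-5) {
  targets <- unique(vapply(fits, `[[`, "", "target"))
  if (length(targets) != 1L)
    stop("fits have mismatched targets: ", paste(targets, collapse = ", "),
         call. = FALSE)
  k <- length(fits)
  cis_ok <- all(vapply(fits, function(f)
    f$cis_coef != 0 && f$cis_pvalue < alpha, TRUE))
  cand <- Reduce(intersect, lapply(fits, function(f) names(f$trans_coefs)))
  keep <- cand[vapply(cand, function(g)
    all(vapply(fits, function(f) f$trans_pvalues[[g]] < alpha, TRUE)), TRUE)]
  trans <- vapply(keep, function(g)
    mean(vapply(fits, function(f) f$trans_coefs[[g]], 0)), 0)
  trans_p <- vapply(keep, function(g)
    max(vapply(fits, function(f) f$trans_pvalues[[g]], 0)), 0)
  structure(list(
    target = targets, lambda = mean(vapply(fits, `[[`, 0, "lambda")),
    cis_coef = if (cis_ok) mean(vapply(fits, `[[`, 0, "cis_coef")) else 0,
    cis_pvalue = if (cis_ok)
      max(vapply(fits, `[[`, 0, "cis_pvalue")) else 1,
    trans_coefs = trans, trans_pvalues = trans_p,
    rmse = mean(vapply(fits, `[[`, 0, "rmse")),
    n_samples = fits[[1L]]$n_samples, n_instances = k),
    class = "gene_model")
}

#' Remove local chromosomal predictors from a gene model
#'
#' Drops trans regulators that lie on the target's chromosome within
#' `window_genes` gene ranks up- or downstream (inclusive). Such predictors
#' tend to reflect the shared copy-number state of the chromosomal
#' neighbourhood rather than a regulatory dependency. The cis term and
#' regulators on other chromosomes are untouched; regulators missing from
#' the annotation are kept with a warning.
#'
#' @param model A `gene_model`.
#' @param annotation Annotation data.frame from [make_annotation()].
#' @param window_genes Window half-width in gene ranks (default 50).
#' @return The filtered `gene_model`.
#' @export
remove_local_predictors <- function(model, annotation, window_genes = 50) {
  regs <- names(model$trans_coefs)
  if (!length(regs)) return(model)
  ti <- match(model$target, annotation$gene_id)
  if (is.na(ti)) stop("target missing from annotation", call. = FALSE)
  ri <- match(regs, annotation$gene_id)
  if (anyNA(ri)) {
    warning("regulator(s) missing from annotation kept: ",
            paste(regs[is.na(ri)], collapse = ", "))
  }
  local <- !is.na(ri) &
    annotation$chromosome[ri] == annotation$chromosome[ti] &
    abs(annotation$order_index[ri] - annotation$order_index[ti]) <= window_genes
  model$trans_coefs <- model$trans_coefs[!local]
  model$trans_pvalues <- model$trans_pvalues[!local]
  model
}

#' Infer the sparse transcriptional network from a cohort
#'
#' The central fitting routine: for every gene, fits `n_instances` lasso
#' models of its expression from its own copy number and the expression of
#' all other genes ([fit_gene_model()]), retains predictors significant at
#' `alpha` in every instance ([stability_filter()]), and removes local
#' chromosomal predictors ([remove_local_predictors()]). Gene-specific tasks
#' are independent; results are identical regardless of evaluation order
#' because each (target, instance) pair derives its own seed from `seed`.
#'
#' @param expr,cn Harmonized genes-by-samples matrices (same genes, same
#'   samples).
#' @param annotation Annotation covering the gene universe
#'   ([make_annotation()]); NULL skips the local-predictor filter.
#' @param n_instances Number of repeated fit instances (default 10).
#' @param cv_repeats,cv_folds,nlambda Passed to [fit_gene_model()].
#' @param alpha Stability-filter threshold (default 5e-5).
#' @param window_genes Local-filter window (default 50).
#' @param seed Integer seed.
#' @param targets Optional subset of genes to fit (default all).
#' @return An object of class `cna_network` with elements `consensus` (list
#'   of consensus `gene_model`s), `instances` (list of per-instance model
#'   lists), `edges` (data.frame regulator/target/coefficient/p_max/type/
#'   sign), `genes`, `failures`, and the call parameters. Methods: `print`,
#'   `summary`, `coef` (edge table), `predict` (expression prediction).
#' @export
infer_network <- function(expr, cn, annotation = NULL, n_instances = 10,
                          cv_repeats = 10, cv_folds = 10, nlambda = 100,
                          alpha = 5e-5, window_genes = 50, seed = 1L,
                          targets = rownames(expr)) {
  stopifnot(identical(rownames(expr), rownames(cn)),
            identical(colnames(expr), colnames(cn)))
  genes <- rownames(expr)
  consensus <- vector("list", length(targets))
  instances <- lapply(seq_len(n_instances), function(i) vector("list", 0L))
  failures <- list()
  names(consensus) <- targets
  for (t in seq_along(targets)) {
    g <- targets[t]
    fits <- tryCatch(
      lapply(seq_len(n_instances), function(i)
        fit_gene_model(g, expr, cn, cv_repeats = cv_repeats,
                       cv_folds = cv_folds, nlambda = nlambda,
                       seed = derive_seed(seed, match(g, genes), i))),
      error = function(e) e)
    if (inherits(fits, "error")) {
      failures[[g]] <- conditionMessage(fits)
      next
    }
    for (i in seq_len(n_instances)) instances[[i]][[g]] <- fits[[i]]
    cm <- stability_filter(fits, alpha = alpha)
    if (!is.null(annotation))
      cm <- remove_local_predictors(cm, annotation, window_genes)
    consensus[[g]] <- cm
  }
  consensus <- Filter(Negate(is.null), consensus)
  net <- structure(list(consensus = consensus, instances = instances,
                        genes = genes, failures = failures,
                        alpha = alpha, n_instances = n_instances,
                        window_genes = window_genes, seed = seed),
                   class = "cna_network")
  net$edges <- edge_table(net)
  net
}

edge_table <- function(net) {
  rows <- lapply(net$consensus, function(m) {
    out <- NULL
    if (m$cis_coef != 0)
      out <- data.frame(regulator = m$target, target = m$target,
                        coefficient = m$cis_coef, p_max = m$cis_pvalue,
                        type = "cis", stringsAsFactors = FALSE)
    if (length(m$trans_coefs))
      out <- rbind(out, data.frame(
        regulator = names(m$trans_coefs), target = m$target,
        coefficient = unname(m$trans_coefs),
        p_max = unname(m$trans_pvalues), type = "trans",
        stringsAsFactors = FALSE))
    out
  })
  rows <- Filter(Negate(is.null), rows)
  tab <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(regulator = character(0), target = character(0),
               coefficient = numeric(0), p_max = numeric(0),
               type = character(0), stringsAsFactors = FALSE)
  tab$sign <- ifelse(tab$coefficient > 0, "activator", "repressor")
  rownames(tab) <- NULL
  tab
}

#' @export
print.cna_network <- function(x, ...) {
  tr <- x$edges[x$edges$type == "trans", ]
  cat("Sparse transcriptional network (", length(x$genes), " genes)\n", sep = "")
  cat("  consensus trans edges:", nrow(tr),
      sprintf("(%d activating, %d repressing)", sum(tr$coefficient > 0),
              sum(tr$coefficient < 0)), "\n")
  cat("  genes with cis copy-number effect:",
      sum(x$edges$type == "cis"), "\n")
  cat("  instances:", x$n_instances, " significance threshold:", x$alpha, "\n")
  if (length(x$failures))
    cat("  unfitted targets:", length(x$failures), "\n")
  invisible(x)
}

#' @export
summary.cna_network <- function(object, ...) {
  tr <- object$edges[object$edges$type == "trans", ]
  out <- list(
    n_genes = length(object$genes),
    n_trans_edges = nrow(tr),
    n_cis = sum(object$edges$type == "cis"),
    activator_fraction = if (nrow(tr)) mean(tr$coefficient > 0) else NA_real_,
    mean_predictors_per_target = if (length(object$consensus))
      nrow(tr) / length(object$consensus) else 0,
    out_degree = table(factor(tr$regulator, levels = object$genes)),
    failures = object$failures)
  class(out) <- "summary.cna_network"
  out
}

#' @export
print.summary.cna_network <- function(x, ...) {
  cat("Network summary:", x$n_genes, "genes,", x$n_trans_edges,
      "trans edges,", x$n_cis, "cis effects\n")
  cat("  activator fraction:", format(x$activator_fraction, digits = 3), "\n")
  cat("  mean trans predictors per target:",
      format(x$mean_predictors_per_target, digits = 3), "\n")
  hubs <- sort(x$out_degree, decreasing = TRUE)
  hubs <- hubs[hubs > 0]
  if (length(hubs))
    cat("  top regulators:", paste(names(hubs)[seq_len(min(5, length(hubs)))],
                                   collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.cna_network <- function(object, ...) object$edges

# Sparse coefficient matrix A (rows = regulators, cols = targets) and cis
# vector from consensus (or one instance's) models.
coefficient_matrix <- function(net, instance = NULL) {
  models <- if (is.null(instance)) net$consensus else
    net$instances[[instance]]
  genes <- net$genes
  n <- length(genes)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  cis <- stats::setNames(numeric(n), genes)
  for (m in models) {
    ti <- match(m$target, genes)
    cis[ti] <- m$cis_coef
    if (length(m$trans_coefs)) {
      ri <- match(names(m$trans_coefs), genes)
      i <- c(i, ri); j <- c(j, rep.int(ti, length(ri)))
      x <- c(x, unname(m$trans_coefs))
    }
  }
  list(A = Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                                dimnames = list(genes, genes)),
       cis = cis)
}

#' Predict expression from a fitted network
#'
#' @param object A `cna_network`.
#' @param expr,cn Genes-by-samples matrices harmonized to the network's gene
#'   universe.
#' @param use "consensus" (default) uses the stability-filtered consensus
#'   coefficients; "instances" averages the predictions of the unfiltered
#'   fit instances.
#' @param ... Unused.
#' @return Predicted expression matrix; see [predict_expression()].
#' @export
predict.cna_network <- function(object, expr, cn,
                                use = c("consensus", "instances"), ...) {
  predict_expression(object, expr, cn, use = match.arg(use))
}

#' Residuals of the network's expression predictions
#'
#' @param object A `cna_network`.
#' @param expr,cn Matrices harmonized to the network genes.
#' @param ... Passed to [predict_expression()].
#' @return Matrix of residuals `expr - predicted`.
#' @export
residuals.cna_network <- function(object, expr, cn, ...) {
  expr - predict_expression(object, expr, cn, ...)
}

#' Simulate a cohort from a fitted network
#'
#' Draws copy-number profiles and Gaussian noise and solves the fitted
#' simultaneous linear system, mirroring the generator but with the
#' estimated (consensus) coefficients.
#'
#' @param object A `cna_network`.
#' @param nsim Number of samples.
#' @param seed Integer seed.
#' @param noise_sd Expression noise standard deviation.
#' @param cna_rate,cna_magnitude CNA occurrence probability and log-ratio.
#' @param ... Unused.
#' @return list(expression, copy_number).
#' @export
simulate.cna_network <- function(object, nsim = 100, seed = 1L,
                                 noise_sd = 0.3, cna_rate = 0.2,
                                 cna_magnitude = 1.0, ...) {
  cm <- coefficient_matrix(object)
  n <- length(object$genes)
  rho <- max(Mod(eigen(abs(as.matrix(cm$A)), only.values = TRUE)$values), 0)
  if (rho >= 1)
    stop("fitted coefficient matrix is not contractive; cannot simulate",
         call. = FALSE)
  set.seed(seed)
  samples <- sprintf("sim%04d", seq_len(nsim))
  cn <- matrix(0, n, nsim, dimnames = list(object$genes, samples))
  hit <- matrix(stats::runif(n * nsim), n, nsim) < cna_rate
  cn[hit] <- sample(c(-1, 1), sum(hit), TRUE) * cna_magnitude
  eps <- matrix(stats::rnorm(n * nsim, 0, noise_sd), n, nsim)
  expr <- as.matrix(solve(diag(n) - Matrix::t(cm$A),
                          cm$cis * cn + eps))
  dimnames(expr) <- dimnames(cn)
  list(expression = expr, copy_number = cn)
}

#' @export
plot.cna_network <- function(x, ...) {
  tr <- x$edges[x$edges$type == "trans", ]
  outdeg <- table(factor(tr$regulator, levels = x$genes))
  indeg <- table(factor(tr$target, levels = x$genes))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(as.numeric(outdeg), breaks = "FD", main = "out-degree",
                 xlab = "trans edges out", ...)
  graphics::hist(as.numeric(indeg), breaks = "FD", main = "in-degree",
                 xlab = "trans edges in", ...)
  invisible(x)
}

#' Degree-preserving network randomization
#'
#' Randomly exchanges trans predictors between targets: two trans edges
#' (j1 -> i1) and (j2 -> i2) swap their targets, carrying coefficients and
#' p-values with the moved predictor. Every gene keeps its exact in- and
#' out-degree. Cis terms are left in place. Swaps creating self-loops or
#' duplicate edges are rejected.
#'
#' @param net A `cna_network`.
#' @param seed Integer seed.
#' @param n_swaps Number of attempted swaps (default 10 per edge).
#' @return A new `cna_network` with rewired consensus (instances dropped).
#' @export
randomize_network <- function(net, seed = 1L, n_swaps = NULL) {
  ed <- net$edges
  tr <- which(ed$type == "trans")
  if (length(tr) < 2L) {
    warning("network too small to rewire; returned unchanged")
    return(net)
  }
  set.seed(derive_seed(seed, 5L))
  n_swaps <- n_swaps %||% (10L * length(tr))
  reg <- ed$regulator[tr]; tgt <- ed$target[tr]
  key <- function(r, t) paste(r, t, sep = "\r")
  existing <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(reg, tgt)) assign(k, TRUE, existing)
  for (s in seq_len(n_swaps)) {
    ab <- sample.int(length(tr), 2L)
    a <- ab[1L]; b <- ab[2L]
    if (reg[a] == tgt[b] || reg[b] == tgt[a]) next
    ka <- key(reg[a], tgt[b]); kb <- key(reg[b], tgt[a])
    if (exists(ka, existing, inherits = FALSE) ||
        exists(kb, existing, inherits = FALSE) || ka == kb) next
    rm(list = c(key(reg[a], tgt[a]), key(reg[b], tgt[b])), envir = existing)
    tmp <- tgt[a]; tgt[a] <- tgt[b]; tgt[b] <- tmp
    assign(ka, TRUE, existing); assign(kb, TRUE, existing)
  }
  ed$regulator[tr] <- reg; ed$target[tr] <- tgt
  # rebuild consensus models from the rewired edge table
  consensus <- list()
  for (g in unique(ed$target)) {
    sub <- ed[ed$target == g, , drop = FALSE]
    cis <- sub[sub$type == "cis", , drop = FALSE]
    trs <- sub[sub$type == "trans", , drop = FALSE]
    consensus[[g]] <- structure(list(
      target = g,
      lambda = net$consensus[[g]]$lambda %||% NA_real_,
      cis_coef = if (nrow(cis)) cis$coefficient else 0,
      cis_pvalue = if (nrow(cis)) cis$p_max else 1,
      trans_coefs = stats::setNames(trs$coefficient, trs$regulator),
      trans_pvalues = stats::setNames(trs$p_max, trs$regulator),
      rmse = NA_real_, n_samples = NA_integer_), class = "gene_model")
  }
  out <- structure(list(consensus = consensus, instances = list(),
                        genes = net$genes, failures = list(),
                        alpha = net$alpha, n_instances = 0L,
                        window_genes = net$window_genes, seed = seed),
                   class = "cna_network")
  out$edges <- ed[order(ed$target, ed$type, ed$regulator), ]
  rownames(out$edges) <- NULL
  out
}

#' Variance inflation factors of a gene model's retained predictors
#'
#' Regresses each retained predictor on the other retained predictors;
#' VIF_j = 1 / (1 - R^2_j). Values above ten flag strong multicollinearity.
#' Perfectly collinear predictors are reported as +Inf with a warning.
#'
#' @param model A `gene_model` with at least two retained predictors.
#' @param expr,cn Matrices the model was fitted on.
#' @return Named numeric vector of VIFs (>= 1).
#' @export
compute_vif <- function(model, expr, cn) {
  preds <- names(model$trans_coefs)
  X <- t(expr[preds, , drop = FALSE])
  if (model$cis_coef != 0)
    X <- cbind(.cis = cn[model$target, ], X)
  if (ncol(X) < 2L) stop("need at least two retained predictors",
                         call. = FALSE)
  vif <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) {
      warning("perfectly collinear predictor: ", colnames(X)[j])
      vif[j] <- Inf
    } else vif[j] <- 1 / (1 - r2)
  }
  vif
}
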