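#' Predict cohort expression from a fitted network
#'
#' For each gene i and sample d, the prediction is
#' `a_ii * c_id + sum_j a_ji * e_jd` using the network's coefficients. With
#' `use = "consensus"` the consensus (stability-filtered) coefficients are
#' used, which equals the average prediction of the fit instances restricted
#' to the consensus predictor set; `use = "instances"` averages the
#' predictions of the unfiltered fit instances. Genes with an empty model
#' predict zero.
#'
#' @param net A `cna_network`.
#' @param expr,cn Genes-by-samples matrices harmonized to `net$genes`.
#' @param use "consensus" (default) or "instances".
#' @return Matrix of predicted expression, same shape as `expr`.
#' @export
predict_expression <- function(net, expr, cn,
                               use = c("consensus", "instances")) {
  use <- match.arg(use)
  stopifnot(identical(rownames(expr), net$genes))
  one <- function(instance) {
    cm <- coefficient_matrix(net, instance)
    as.matrix(Matrix::crossprod(cm$A, expr)) + cm$cis * cn
  }
  if (use == "consensus" || !length(net$instances)) {
    pred <- one(NULL)
  } else {
    preds <- lapply(seq_along(net$instances), one)
    pred <- Reduce(`+`, preds) / length(preds)
  }
  dimnames(pred) <- dimnames(expr)
  pred
}

#' Gene-wise predictability of a cohort
#'
#' Computes the per-gene Pearson correlation r_i between predicted and
#' observed expression across samples, and the explained variance
#' `R2_i = r_i^2` for predictable genes (r_i > 0), 0 otherwise. Genes whose
#' predicted (or observed) values are constant have undefined correlation
#' and are treated as unpredictable. R2 is clipped at 1 - 1e-9 so the flow
#' matrix stays strictly contractive even for a perfect fit.
#'
#' @param predicted,observed Matched genes-by-samples matrices (>= 3
#'   samples).
#' @return data.frame of class `predictability_profile` with columns gene,
#'   r, R2.
#' @export
predictability <- function(predicted, observed) {
  stopifnot(identical(dim(predicted), dim(observed)))
  if (ncol(observed) < 3L) stop("need at least 3 samples", call. = FALSE)
  sp <- apply(predicted, 1L, stats::sd)
  so <- apply(observed, 1L, stats::sd)
  r <- rep(NA_real_, nrow(observed))
  ok <- sp > 0 & so > 0
  if (any(ok)) {
    zp <- t(scale(t(predicted[ok, , drop = FALSE])))
    zo <- t(scale(t(observed[ok, , drop = FALSE])))
    r[ok] <- rowSums(zp * zo) / (ncol(observed) - 1L)
  }
  R2 <- ifelse(!is.na(r) & r > 0, pmin(r^2, 1 - 1e-9), 0)
  structure(data.frame(gene = rownames(observed), r = r, R2 = R2,
                       stringsAsFactors = FALSE),
            class = c("predictability_profile", "data.frame"))
}

#' Build the basic network flow matrix
#'
#' Allocates each target's explained variance R2_i to its direct predictors
#' in proportion to their average absolute contribution to the prediction:
#' `p_ji = mean_d |a_ji e_jd| / (|a_ii c_id| + sum_v |a_vi e_vd|)` and
#' analogously `p_ii` for the cis copy-number term; the flow entry is
#' `f_ji = p_ji * R2_i`. Samples with an all-zero denominator are skipped in
#' the average; a gene whose denominator vanishes in every sample gets a zero
#' column. In patient mode the proportions use the single patient only (no
#' average); with `signed = TRUE` (patient mode only) the numerators keep the
#' sign of `a_ji e_jd` while the denominator stays absolute, so inhibitory
#' contributions propagate as negative flow.
#'
#' @param net A `cna_network`.
#' @param expr,cn Cohort matrices harmonized to the network genes.
#' @param profile A [predictability()] profile computed on the same cohort.
#' @param mode "cohort" or "patient".
#' @param patient Sample id (required in patient mode).
#' @param signed Keep contribution signs (patient mode only).
#' @return Object of class `flow_matrix`: list(F (sparse, rows = regulators,
#'   columns = targets), p_cis, R2, genes, mode, patient, signed). Every
#'   column of |F| sums to strictly less than 1.
#' @export
build_flow_matrix <- function(net, expr, cn, profile,
                              mode = c("cohort", "patient"), patient = NULL,
                              signed = FALSE) {
  mode <- match.arg(mode)
  stopifnot(identical(rownames(expr), net$genes))
  if (signed && mode != "patient")
    stop("signed flow is defined per patient", call. = FALSE)
  if (mode == "patient") {
    if (is.null(patient)) stop("patient id required", call. = FALSE)
    expr <- expr[, patient, drop = FALSE]
    cn <- cn[, patient, drop = FALSE]
  }
  genes <- net$genes
  R2 <- stats::setNames(profile$R2, profile$gene)[genes]
  cm <- coefficient_matrix(net)
  n <- length(genes)
  D <- ncol(expr)
  Psum <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(n, n))
  cis_sum <- numeric(n)
  valid_count <- numeric(n)
  for (d in seq_len(D)) {
    W <- Matrix::Diagonal(x = expr[, d]) %*% cm$A  # (j,i) = a_ji * e_jd
    cisnum <- cm$cis * cn[, d]
    denom <- Matrix::colSums(abs(W)) + abs(cisnum)
    ok <- denom > 0
    inv <- ifelse(ok, 1 / denom, 0)
    P <- (if (signed) W else abs(W)) %*% Matrix::Diagonal(x = inv)
    Psum <- Psum + P
    cis_sum <- cis_sum + (if (signed) cisnum else abs(cisnum)) * inv
    valid_count <- valid_count + ok
  }
  colscale <- ifelse(valid_count > 0, R2 / valid_count, 0)
  F <- methods::as(Psum %*% Matrix::Diagonal(x = colscale), "CsparseMatrix")
  dimnames(F) <- list(genes, genes)
  p_cis <- stats::setNames(cis_sum * colscale, genes)
  structure(list(F = Matrix::drop0(F), p_cis = p_cis, R2 = R2, genes = genes,
                 mode = mode, patient = patient, signed = signed),
            class = "flow_matrix")
}

#' @export
print.flow_matrix <- function(x, ...) {
  cat("Flow matrix:", length(x$genes), "genes,",
      Matrix::nnzero(x$F), "non-zero entries,",
      if (x$signed) "signed," else "unsigned,", x$mode, "mode\n")
  cat("  max |column sum|:", format(max(Matrix::colSums(abs(x$F))),
                                    digits = 4), "\n")
  invisible(x)
}

as_flow <- function(F) {
  if (inherits(F, "flow_matrix")) F$F else Matrix::Matrix(F, sparse = TRUE)
}

#' Propagate flow through all network paths
#'
#' Accumulates the geometric series `F* = sum_{k>=1} F^k`, the total direct
#' plus indirect impact over all directed paths. Partial sums are accumulated
#' until the summed absolute change of the (absolute) column sums drops below
#' `tol`; `method = "closed"` evaluates the limit `(I - F)^-1 - I` by direct
#' inversion instead. A standardized copy scales every non-zero column to sum
#' to 100 (percent of total column impact; for signed matrices the absolute
#' column sum is scaled to 100).
#'
#' @param F A `flow_matrix` or a square (sparse) matrix whose absolute column
#'   sums are all strictly below 1.
#' @param tol Convergence threshold on the change of column sums.
#' @param max_iter Iteration cap for the series.
#' @param method "series" (default) or "closed".
#' @return Object of class `impact_matrix`: list(raw, standardized, genes,
#'   signed, iterations, method).
#' @export
propagate <- function(F, tol = 1e-3, max_iter = 500,
                      method = c("series", "closed")) {
  method <- match.arg(method)
  signed <- inherits(F, "flow_matrix") && isTRUE(F$signed)
  M <- as_flow(F)
  cs <- Matrix::colSums(abs(M))
  if (any(cs >= 1)) stop("flow not contractive: column sum >= 1",
                         call. = FALSE)
  iterations <- NA_integer_
  if (method == "closed") {
    n <- nrow(M)
    S <- Matrix::Matrix(solve(Matrix::Diagonal(n) - M) - Matrix::Diagonal(n),
                        sparse = TRUE)
  } else {
    # partial sums densify quickly; plain BLAS beats sparse ops here
    dense <- nrow(M) <= 1000
    Mw <- if (dense) as.matrix(M) else M
    S <- Mw; P <- Mw
    cs_prev <- colSums(abs(S))
    for (k in 2:max_iter) {
      P <- Mw %*% P
      S <- S + P
      cs_new <- colSums(abs(S))
      delta <- sum(abs(cs_new - cs_prev))
      cs_prev <- cs_new
      if (delta < tol) { iterations <- k; break }
    }
    if (is.na(iterations)) iterations <- max_iter
    if (dense) S <- Matrix::Matrix(S, sparse = TRUE)
  }
  std <- standardize_columns(S, signed = signed)
  genes <- rownames(M)
  structure(list(raw = S, standardized = std, genes = genes, signed = signed,
                 iterations = iterations, method = method, tol = tol),
            class = "impact_matrix")
}

standardize_columns <- function(S, signed = FALSE) {
  tot <- Matrix::colSums(if (signed) abs(S) else S)
  scale <- ifelse(tot > 0, 100 / tot, 0)
  out <- S %*% Matrix::Diagonal(x = scale, n = length(scale))
  dimnames(out) <- dimnames(S)
  out
}

#' @export
print.impact_matrix <- function(x, ...) {
  cat("Impact matrix:", length(x$genes), "genes,",
      if (x$signed) "signed" else "unsigned",
      sprintf("(%s%s)\n", x$method,
              if (!is.na(x$iterations))
                paste0(", ", x$iterations, " iterations") else ""))
  invisible(x)
}

#' Direct-neighbour impact baseline
#'
#' Replaces the full path propagation by paths of length exactly one: the
#' impact matrix is the flow matrix itself, standardized identically. Used
#' as a baseline to quantify the value of indirect effects.
#'
#' @param F A `flow_matrix` or matrix.
#' @return An `impact_matrix` (iterations = 1).
#' @export
direct_neighbor_impacts <- function(F) {
  signed <- inherits(F, "flow_matrix") && isTRUE(F$signed)
  M <- as_flow(F)
  structure(list(raw = M, standardized = standardize_columns(M, signed),
                 genes = rownames(M), signed = signed, iterations = 1L,
                 method = "direct", tol = NA_real_),
            class = "impact_matrix")
}

#' Patient-specific signed impact matrix
#'
#' Builds the signed single-patient flow matrix (contribution signs kept in
#' the numerators, absolute denominator) and propagates it. Entries may be
#' negative: a negative impact of gene j on gene i means the realized state
#' of j in this patient pushes the expression of i down (inhibitory impact);
#' positive entries are activating.
#'
#' @param net A `cna_network`.
#' @param expr,cn Cohort matrices (the patient's columns are selected).
#' @param profile Cohort [predictability()] profile.
#' @param patient Sample id.
#' @param tol,max_iter,method Passed to [propagate()].
#' @return A signed `impact_matrix`.
#' @export
signed_patient_impacts <- function(net, expr, cn, profile, patient,
                                   tol = 1e-3, max_iter = 500,
                                   method = c("series", "closed")) {
  fm <- build_flow_matrix(net, expr, cn, profile, mode = "patient",
                          patient = patient, signed = TRUE)
  propagate(fm, tol = tol, max_iter = max_iter, method = match.arg(method))
}

#' Validate impact directionality against perturbation experiments
#'
#' For each perturbed gene j, computes a response-frequency score per gene
#' (the fraction of j's experiments in which the gene appears among the top
#' responders) and tests the rank correlation between the impact flowing out
#' of j (row j of the standardized impact matrix; forward model) — or into j
#' (column j; reverse model) — and the response scores, one-sided for
#' positive association. The two p-value sets are each compared to
#' Uniform(0,1) with a one-sided Kolmogorov-Smirnov test (enrichment of
#' small p-values), plus a one-sided KS comparison of forward versus
#' reverse.
#'
#' @param impact An `impact_matrix`.
#' @param perturbations data.frame as produced by
#'   [simulate_perturbations()]: perturbed_gene, experiment, response_gene,
#'   direction.
#' @return list(table (gene, n_experiments, forward_p, reverse_p),
#'   ks_forward, ks_reverse, ks_forward_vs_reverse) where the ks entries are
#'   p-values.
#' @export
forward_reverse_validation <- function(impact, perturbations) {
  genes <- impact$genes
  pg <- intersect(unique(perturbations$perturbed_gene), genes)
  if (!length(pg)) stop("no perturbed gene in the impact gene universe",
                        call. = FALSE)
  std <- impact$standardized
  rows <- list()
  for (g in pg) {
    sub <- perturbations[perturbations$perturbed_gene == g, ]
    nexp <- length(unique(sub$experiment))
    counts <- table(factor(sub$response_gene, levels = genes))
    scores <- as.numeric(counts) / nexp
    keep <- genes != g
    if (sum(scores[keep] > 0) < 2L) {
      warning("gene ", g, " has fewer than 2 responders; skipped")
      next
    }
    fwd <- suppressWarnings(stats::cor.test(
      as.numeric(std[g, ])[keep], scores[keep], method = "spearman",
      alternative = "greater", exact = FALSE)$p.value)
    rev <- suppressWarnings(stats::cor.test(
      as.numeric(std[, g])[keep], scores[keep], method = "spearman",
      alternative = "greater", exact = FALSE)$p.value)
    rows[[g]] <- data.frame(gene = g, n_experiments = nexp,
                            forward_p = fwd, reverse_p = rev,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  fp <- tab$forward_p[!is.na(tab$forward_p)]
  rp <- tab$reverse_p[!is.na(tab$reverse_p)]
  ks1 <- function(x) {
    if (length(x) < 2L) return(NA_real_)  # pooling needs several genes
    suppressWarnings(
      stats::ks.test(x, "punif", alternative = "greater")$p.value)
  }
  list(table = tab,
       ks_forward = ks1(fp),
       ks_reverse = ks1(rp),
       ks_forward_vs_reverse = if (length(fp) < 2L || length(rp) < 2L)
         NA_real_ else suppressWarnings(
           stats::ks.test(fp, rp, alternative = "greater")$p.value))
}
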