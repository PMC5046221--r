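#' Standardize expression gene-wise
#'
#' Scales each gene to mean 0 and standard deviation 1 (sample sd, n-1)
#' across samples. Constant genes become all-zero rows with a warning.
#'
#' @param expr Genes-by-samples matrix (>= 2 samples).
#' @return Standardized matrix of the same shape.
#' @export
standardize_expression <- function(expr) {
  if (ncol(expr) < 2L) stop("need at least 2 samples", call. = FALSE)
  s <- apply(expr, 1L, stats::sd)
  if (any(s == 0)) warning(sum(s == 0), " constant gene(s) set to zero")
  z <- (expr - rowMeans(expr)) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Repeated random-forest survival fits on random 90/10 splits
#'
#' Restricts the cohort to uncensored patients (status "dead"), then
#' repeatedly draws a random `train_frac` training subset, fits a regression
#' random forest of survival time on the expression profiles with the
#' library's standard settings, and stores each forest together with its
#' held-out test patients. By default the forest is trained on
#' log(1 + time): survival times are strongly right-skewed and a
#' squared-error forest fitted on the raw scale spends its splits on the
#' longest survivors.
#'
#' @param expr Genes-by-samples (standardized) expression matrix.
#' @param clinical Clinical data.frame (sample_id, survival_time, status).
#' @param n_splits Number of train/test splits (default 100).
#' @param train_frac Training fraction (default 0.9).
#' @param ntree Trees per forest (randomForest default 500).
#' @param log_time Train on log(1 + time) (default) instead of raw time.
#' @param seed Integer seed.
#' @return Object of class `rf_splits`: list(splits = list of (forest,
#'   train_ids, test_ids), expr, time (named, raw scale), y (training
#'   scale), seed, ntree, log_time).
#' @export
fit_rf_splits <- function(expr, clinical, n_splits = 100, train_frac = 0.9,
                          ntree = 500, log_time = TRUE, seed = 1L) {
  dead <- clinical[clinical$status == "dead", ]
  dead <- dead[dead$sample_id %in% colnames(expr), ]
  if (nrow(dead) <= 20L)
    stop("need more than 20 uncensored patients with expression data",
         call. = FALSE)
  time <- stats::setNames(dead$survival_time, dead$sample_id)
  y <- if (log_time) log1p(time) else time
  X <- t(expr[, names(time), drop = FALSE])
  n <- nrow(X)
  n_train <- round(train_frac * n)
  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    set.seed(derive_seed(seed, s))
    tr <- sample.int(n, n_train)
    forest <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                         ntree = ntree)
    splits[[s]] <- list(forest = forest, train_ids = rownames(X)[tr],
                        test_ids = rownames(X)[-tr])
  }
  structure(list(splits = splits, expr = expr, time = time, y = y,
                 seed = seed, ntree = ntree, train_frac = train_frac,
                 log_time = log_time), class = "rf_splits")
}

#' Gene selection frequencies from the forests
#'
#' The selection frequency of a gene is the number of tree splits that use
#' the gene, normalized by the total number of splits in the forest (so the
#' frequencies of one forest sum to 1), averaged over all forests. With
#' `permuted = TRUE` each split's forest is refitted with the training
#' survival times randomly permuted, yielding the null selection frequencies
#' used for bias correction.
#'
#' @param rfs An `rf_splits` object.
#' @param permuted Refit with permuted survival (null model)?
#' @param seed Seed for the permutations.
#' @return Named numeric vector of per-gene selection frequencies.
#' @export
selection_frequencies <- function(rfs, permuted = FALSE, seed = 1L) {
  one <- function(s, idx) {
    forest <- s$forest
    if (permuted) {
      set.seed(derive_seed(seed, idx, 1L))
      X <- t(rfs$expr[, s$train_ids, drop = FALSE])
      y <- sample(rfs$y[s$train_ids])
      set.seed(derive_seed(seed, idx, 2L))
      forest <- randomForest::randomForest(X, y, ntree = rfs$ntree)
    }
    counts <- randomForest::varUsed(forest, count = TRUE)
    counts / sum(counts)
  }
  sf <- Reduce(`+`, Map(one, rfs$splits, seq_along(rfs$splits))) /
    length(rfs$splits)
  stats::setNames(sf, rownames(rfs$expr))
}

#' Bias-correct and rank selection frequencies
#'
#' corrected = raw - null; genes are ranked by decreasing corrected
#' selection frequency with ties broken by gene id (stable).
#'
#' @param raw,null Named selection-frequency vectors over the same genes.
#' @return data.frame of class `sf_profile` (gene, raw_sf, null_sf,
#'   corrected_sf, rank), sorted by rank.
#' @export
rank_and_correct <- function(raw, null) {
  stopifnot(identical(sort(names(raw)), sort(names(null))))
  null <- null[names(raw)]
  corrected <- raw - null
  ord <- order(-corrected, names(raw))
  out <- data.frame(gene = names(raw)[ord], raw_sf = unname(raw[ord]),
                    null_sf = unname(null[ord]),
                    corrected_sf = unname(corrected[ord]),
                    rank = seq_along(raw), stringsAsFactors = FALSE)
  class(out) <- c("sf_profile", "data.frame")
  out
}

#' Successive-permutation importance profile
#'
#' For increasing numbers m of top-ranked genes, permutes the expression of
#' those genes across the test patients of each split (each gene permuted
#' independently; permutations accumulate as m grows), predicts test
#' survival with the split's forest, and records the correlation between
#' observed and predicted survival. The curve starts at m = 0 (unpermuted
#' baseline) and is averaged over all (split x repeat) runs; splits with
#' fewer than 3 test patients are skipped.
#'
#' @param rfs An `rf_splits` object.
#' @param profile An `sf_profile` ranking ([rank_and_correct()]).
#' @param steps Increasing vector of m values; the default takes steps of
#'   one gene for the first 1000 top-ranked genes, then steps of 100.
#' @param repeats Permutation repeats per forest (default 10).
#' @param cor_method Correlation between observed and predicted survival:
#'   "spearman" (default; robust to the right-skew of survival times) or
#'   "pearson".
#' @param seed Integer seed.
#' @return data.frame of class `importance_curve` (m, mean_r).
#' @export
importance_profile <- function(rfs, profile, steps = NULL, repeats = 10,
                               cor_method = c("spearman", "pearson"),
                               seed = 1L) {
  cor_method <- match.arg(cor_method)
  genes <- profile$gene
  N <- length(genes)
  if (is.null(steps)) {
    steps <- seq_len(min(1000L, N))
    if (N > 1000L) steps <- c(steps, seq(1100L, N, by = 100L))
  }
  steps <- sort(unique(c(0L, steps)))
  acc <- matrix(0, length(steps), 2L)  # sum of r, count
  for (si in seq_along(rfs$splits)) {
    s <- rfs$splits[[si]]
    if (length(s$test_ids) < 3L) next
    Xt <- t(rfs$expr[, s$test_ids, drop = FALSE])
    yt <- rfs$y[s$test_ids]
    for (rep in seq_len(repeats)) {
      set.seed(derive_seed(seed, si, rep))
      Xp <- Xt
      prev <- 0L
      for (k in seq_along(steps)) {
        m <- steps[k]
        if (m > prev) {
          for (g in genes[(prev + 1L):m])
            Xp[, g] <- Xp[sample.int(nrow(Xp)), g]
          prev <- m
        }
        pred <- stats::predict(s$forest, Xp)
        r <- suppressWarnings(stats::cor(yt, pred, method = cor_method))
        if (!is.na(r)) {
          acc[k, 1L] <- acc[k, 1L] + r
          acc[k, 2L] <- acc[k, 2L] + 1
        }
      }
    }
  }
  out <- data.frame(m = steps, mean_r = ifelse(acc[, 2L] > 0,
                                               acc[, 1L] / acc[, 2L], NA_real_))
  class(out) <- c("importance_curve", "data.frame")
  out
}

#' Select signature genes from the importance curve
#'
#' Smooths the curve to be non-increasing (isotonic regression) and selects
#' the top-ranked genes that carry the predictive signal. With the default
#' `method = "curve"`, a gene at step m belongs to the signature while the
#' smoothed correlation entering its permutation step is still more than
#' `cutoff` above the curve's plateau (its final level): these are the genes
#' whose permutation still has predictive signal left to destroy. With
#' `method = "decrement"`, a gene qualifies when its own per-gene decrement
#' of the smoothed correlation exceeds `cutoff`. An empty selection (curve
#' never exceeds the cutoff above its plateau) yields an empty signature
#' with a warning.
#'
#' @param curve An `importance_curve`.
#' @param profile The `sf_profile` ranking the curve was computed from.
#' @param cutoff Correlation cutoff (default 0.1).
#' @param method Cutoff semantics, see above.
#' @return Character vector of signature genes (possibly empty), with the
#'   smoothed curve attached as attribute `smoothed`.
#' @export
select_signature <- function(curve, profile, cutoff = 0.1,
                             method = c("curve", "decrement")) {
  method <- match.arg(method)
  ok <- !is.na(curve$mean_r)
  m <- curve$m[ok]; r <- curve$mean_r[ok]
  iso <- stats::isoreg(m, -r)     # non-decreasing fit of -r
  sm <- -iso$yf
  if (method == "curve") {
    plateau <- max(min(sm), 0)   # negative tails mean signal is exhausted
    above <- which(sm[-length(sm)] > plateau + cutoff)  # value entering step
    m_star <- if (length(above)) m[max(above) + 1L] else 0L
  } else {
    contrib <- c(NA_real_, -diff(sm) / diff(m))
    above <- which(!is.na(contrib) & contrib > cutoff)
    m_star <- if (length(above)) m[max(above)] else 0L
  }
  if (m_star == 0L) {
    warning("no gene exceeds the correlation cutoff; cohort not predictive")
    genes <- character(0)
  } else {
    genes <- profile$gene[seq_len(m_star)]
  }
  attr(genes, "smoothed") <- data.frame(m = m, mean_r = sm)
  genes
}

#' Assign survival-association directions by clustering
#'
#' Hierarchically clusters the signature genes (average linkage on
#' 1 - Pearson correlation distance), cuts at two clusters, and correlates
#' each cluster's mean expression profile with survival time (uncensored
#' patients). Every gene inherits its cluster's correlation sign; a
#' one-sided correlation test p-value is reported per cluster. If both
#' clusters carry the same sign, directions fall back to each gene's own
#' correlation sign with a warning. A single-gene signature gets the sign of
#' its own correlation.
#'
#' @param expr Genes-by-samples expression (signature genes included).
#' @param clinical Clinical data.frame.
#' @param genes Signature gene ids.
#' @param assign "cluster" (default) gives every gene its cluster's sign;
#'   "gene" uses each gene's own correlation sign (useful when the
#'   signature genes are mutually uncorrelated so that expression clusters
#'   are not survival-coherent); cluster memberships and tests are reported
#'   either way.
#' @return data.frame of class `signature_set` (gene, direction, cluster,
#'   cluster_p).
#' @export
direction_clustering <- function(expr, clinical, genes,
                                 assign = c("cluster", "gene")) {
  assign <- match.arg(assign)
  dead <- clinical[clinical$status == "dead", ]
  time <- stats::setNames(log1p(dead$survival_time), dead$sample_id)
  E <- expr[genes, names(time), drop = FALSE]
  corsign <- function(v) {
    r <- suppressWarnings(stats::cor(v, time))
    if (is.na(r)) r <- 0
    r
  }
  if (length(genes) == 1L) {
    r <- corsign(E[1L, ])
    return(structure(data.frame(gene = genes,
                                direction = ifelse(r >= 0, 1, -1),
                                cluster = 1L, cluster_p = NA_real_,
                                stringsAsFactors = FALSE),
                     class = c("signature_set", "data.frame")))
  }
  dc <- stats::as.dist(1 - suppressWarnings(stats::cor(t(E))))
  dc[is.na(dc)] <- 1
  cl <- stats::cutree(stats::hclust(dc, method = "average"), k = 2L)
  dir <- integer(length(genes)); pvals <- numeric(2L)
  signs <- integer(2L)
  for (k in 1:2) {
    prof <- colMeans(E[cl == k, , drop = FALSE])
    r <- corsign(prof)
    signs[k] <- ifelse(r >= 0, 1L, -1L)
    pvals[k] <- if (stats::sd(prof) > 0)
      suppressWarnings(stats::cor.test(
        prof, time, alternative = if (r >= 0) "greater" else "less")$p.value)
    else NA_real_
    dir[cl == k] <- signs[k]
  }
  if (assign == "gene") {
    dir <- ifelse(apply(E, 1L, corsign) >= 0, 1L, -1L)
  } else if (signs[1L] == signs[2L]) {
    warning("both clusters share a survival-association sign; ",
            "falling back to per-gene correlation signs")
    dir <- ifelse(apply(E, 1L, corsign) >= 0, 1L, -1L)
  }
  structure(data.frame(gene = genes, direction = dir, cluster = unname(cl),
                       cluster_p = pvals[cl], stringsAsFactors = FALSE),
            class = c("signature_set", "data.frame"))
}

#' Identify survival signature genes
#'
#' End-to-end signature discovery: standardizes expression, fits repeated
#' random-forest survival models on 90/10 splits, computes raw and
#' permutation-null selection frequencies, ranks genes by bias-corrected
#' selection frequency, profiles the importance of the top-ranked genes by
#' successive permutation, selects the signature at the
#' correlation-contribution cutoff and assigns survival-association
#' directions by clustering.
#'
#' @param expr Genes-by-samples expression matrix (raw; standardized
#'   internally).
#' @param clinical Clinical table (sample_id, survival_time, status).
#' @param n_splits,train_frac,ntree Passed to [fit_rf_splits()].
#' @param repeats,steps,cor_method Passed to [importance_profile()].
#' @param cutoff,cutoff_method Passed to [select_signature()].
#' @param direction_assign Passed to [direction_clustering()].
#' @param seed Integer seed.
#' @return Object of class `survival_signature`: list(signature
#'   (signature_set with directions), profile (sf_profile), curve,
#'   smoothed_curve, cutoff, params). `signature` is empty when no gene
#'   passes the cutoff.
#' @export
survival_signature <- function(expr, clinical, n_splits = 100,
                               train_frac = 0.9, ntree = 500, repeats = 10,
                               steps = NULL, cutoff = 0.1,
                               cutoff_method = "curve",
                               cor_method = "spearman",
                               direction_assign = "cluster", seed = 1L) {
  z <- standardize_expression(expr)
  rfs <- fit_rf_splits(z, clinical, n_splits = n_splits,
                       train_frac = train_frac, ntree = ntree, seed = seed)
  raw <- selection_frequencies(rfs, permuted = FALSE)
  null <- selection_frequencies(rfs, permuted = TRUE,
                                seed = derive_seed(seed, 17L))
  profile <- rank_and_correct(raw, null)
  curve <- importance_profile(rfs, profile, steps = steps, repeats = repeats,
                              cor_method = cor_method,
                              seed = derive_seed(seed, 23L))
  genes <- select_signature(curve, profile, cutoff = cutoff,
                            method = cutoff_method)
  sig <- if (length(genes))
    direction_clustering(z, clinical, genes, assign = direction_assign)
  else
    structure(data.frame(gene = character(0), direction = integer(0),
                         cluster = integer(0), cluster_p = numeric(0)),
              class = c("signature_set", "data.frame"))
  structure(list(signature = sig, profile = profile, curve = curve,
                 smoothed_curve = attr(genes, "smoothed"), cutoff = cutoff,
                 params = list(n_splits = n_splits, train_frac = train_frac,
                               ntree = ntree, repeats = repeats, seed = seed)),
            class = "survival_signature")
}

#' @export
print.survival_signature <- function(x, ...) {
  cat("Survival signature:", nrow(x$signature), "gene(s) at cutoff",
      x$cutoff, "\n")
  if (nrow(x$signature)) {
    neg <- sum(x$signature$direction < 0)
    cat("  ", nrow(x$signature) - neg, " positively and ", neg,
        " negatively survival-associated\n", sep = "")
    cat("  genes:", paste(utils::head(x$signature$gene, 10), collapse = ", "),
        if (nrow(x$signature) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
summary.survival_signature <- function(object, ...) {
  cat("Top of the corrected selection-frequency ranking:\n")
  print(utils::head(object$profile, 10))
  cat("\nImportance curve (first rows):\n")
  print(utils::head(object$curve, 10))
  invisible(object)
}
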