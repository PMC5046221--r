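#' Call copy-number alterations from log-ratios
#'
#' A gene is called amplified in a patient when its copy-number log-ratio is
#' >= `threshold` and deleted when it is <= -`threshold`. Deletions and
#' amplifications are distinct events with separate cohort frequencies; an
#' event is rare when its frequency is below `rare_cutoff`.
#'
#' @param cn Genes-by-samples copy-number log-ratio matrix.
#' @param threshold Absolute log-ratio call threshold (default 0.75).
#' @param rare_cutoff Cohort-frequency boundary between rare and frequent
#'   (default 0.01).
#' @return Object of class `cna_calls`: list(calls (integer matrix, -1/0/+1),
#'   frequency (data.frame gene, event, frequency, rarity), threshold,
#'   rare_cutoff).
#' @export
call_cnas <- function(cn, threshold = 0.75, rare_cutoff = 0.01) {
  calls <- matrix(0L, nrow(cn), ncol(cn), dimnames = dimnames(cn))
  calls[cn >= threshold] <- 1L
  calls[cn <= -threshold] <- -1L
  freq <- rbind(
    data.frame(gene = rownames(cn), event = "del",
               frequency = rowMeans(calls == -1L), stringsAsFactors = FALSE),
    data.frame(gene = rownames(cn), event = "amp",
               frequency = rowMeans(calls == 1L), stringsAsFactors = FALSE))
  freq <- freq[freq$frequency > 0, , drop = FALSE]
  freq$rarity <- ifelse(freq$frequency < rare_cutoff, "rare", "frequent")
  rownames(freq) <- NULL
  structure(list(calls = calls, frequency = freq, threshold = threshold,
                 rare_cutoff = rare_cutoff), class = "cna_calls")
}

#' @export
print.cna_calls <- function(x, ...) {
  cat("CNA calls: |log-ratio| >=", x$threshold, "\n")
  cat("  ", sum(x$calls == 1L), "amplification and", sum(x$calls == -1L),
      "deletion calls over", nrow(x$calls), "genes x", ncol(x$calls),
      "patients\n")
  cat("  ", sum(x$frequency$rarity == "rare"), "rare /",
      sum(x$frequency$rarity == "frequent"), "frequent gene events (cutoff",
      x$rare_cutoff, ")\n")
  invisible(x)
}

#' Mean impact of mutated genes on the survival signature
#'
#' For every gene event with at least one call, averages the standardized
#' (percent) impact entries from that gene to every signature gene.
#'
#' @param impact An unsigned cohort `impact_matrix`.
#' @param signature A `signature_set` (or character vector of signature
#'   genes); must be non-empty.
#' @param calls A `cna_calls` object.
#' @return data.frame of class `impact_table` (gene, event, frequency,
#'   rarity, mean_impact), one row per called gene event.
#' @export
mean_signature_impact <- function(impact, signature, calls) {
  sig <- if (is.data.frame(signature)) signature$gene else signature
  if (!length(sig)) stop("empty signature", call. = FALSE)
  sig <- intersect(sig, impact$genes)
  tab <- calls$frequency
  sub <- impact$standardized[match(tab$gene, impact$genes), match(sig, impact$genes),
                             drop = FALSE]
  tab$mean_impact <- Matrix::rowMeans(sub)
  class(tab) <- c("impact_table", "data.frame")
  tab
}

#' Select high-impact genes by cumulative-impact cutoff
#'
#' Sorts the gene events by increasing mean impact, accumulates the impacts,
#' and flags the events past the point where the cumulative sum exceeds
#' `cumulative_cutoff` (the low-impact head whose cumulative sum stays at or
#' below the cutoff is dropped).
#'
#' @param table An `impact_table`.
#' @param cumulative_cutoff Cumulative percent-impact cutoff (default 1.0).
#' @return The table sorted by increasing impact with columns
#'   cumulative_impact and selected added.
#' @export
select_high_impact <- function(table, cumulative_cutoff = 1.0) {
  tab <- table[order(table$mean_impact, table$gene, table$event), ,
               drop = FALSE]
  tab$cumulative_impact <- cumsum(tab$mean_impact)
  tab$selected <- tab$cumulative_impact > cumulative_cutoff
  rownames(tab) <- NULL
  tab
}

#' Significance of impacts against degree-preserving random networks
#'
#' For each gene, forms the paired differences between its impact under the
#' true network and under each of K >= 5 degree-preserving randomized
#' networks and applies a one-sided Wilcoxon signed-rank test of median
#' difference > 0 (exact for small K without ties). P-values are adjusted
#' across genes by Benjamini-Hochberg.
#'
#' @param true_impacts Named numeric vector of per-gene impacts under the
#'   inferred network.
#' @param random_impacts Matrix genes x K of impacts under randomized
#'   networks (rownames = genes); genes absent from a random network (NA)
#'   have that pair skipped.
#' @return data.frame (gene, p, q) ordered as `true_impacts`.
#' @export
random_network_significance <- function(true_impacts, random_impacts) {
  if (ncol(random_impacts) < 5L)
    stop("need at least 5 random networks", call. = FALSE)
  genes <- names(true_impacts)
  p <- vapply(genes, function(g) {
    d <- true_impacts[g] - random_impacts[g, ]
    d <- d[!is.na(d)]
    if (!length(d) || all(d == 0)) return(1)
    suppressWarnings(stats::wilcox.test(d, alternative = "greater")$p.value)
  }, 0)
  data.frame(gene = genes, p = unname(p),
             q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Patient-specific survival impact score
#'
#' Each called CNA gene contributes the mean, over signature genes, of its
#' signed (activating/inhibitory) impact on the signature gene multiplied by
#' the gene's survival-association direction, so that an inhibitory impact
#' on a negatively survival-associated gene counts as beneficial. The
#' patient score is the average contribution over the patient's called CNA
#' genes after the variant filter; a patient without qualifying CNAs is
#' unclassifiable (NA score).
#'
#' @param signed_impact A signed patient `impact_matrix`
#'   ([signed_patient_impacts()]).
#' @param signature A `signature_set` with directions.
#' @param patient_calls Integer vector (-1/0/+1) of the patient's calls,
#'   named by gene.
#' @param variant "all", "frequent_only" or "rare_only"; frequency
#'   membership is judged against `train_frequency`.
#' @param train_frequency The `frequency` table of the training cohort's
#'   [call_cnas()] (required for the filtered variants).
#' @param rare_cutoff Frequency boundary (default 0.01).
#' @return list(score, class ("positive"/"negative" or NA), contributions
#'   (data.frame gene, event, contribution), n_cnas).
#' @export
patient_survival_score <- function(signed_impact, signature, patient_calls,
                                   variant = c("all", "frequent_only",
                                               "rare_only"),
                                   train_frequency = NULL,
                                   rare_cutoff = 0.01) {
  variant <- match.arg(variant)
  dir <- stats::setNames(signature$direction, signature$gene)
  sig <- intersect(names(dir), signed_impact$genes)
  called <- names(patient_calls)[patient_calls != 0L]
  called <- intersect(called, signed_impact$genes)
  if (variant != "all") {
    if (is.null(train_frequency))
      stop("train_frequency required for variant '", variant, "'",
           call. = FALSE)
    ev <- ifelse(patient_calls[called] > 0L, "amp", "del")
    f <- train_frequency$frequency[
      match(paste(called, ev), paste(train_frequency$gene,
                                     train_frequency$event))]
    f[is.na(f)] <- 0  # event unseen in training cohort -> frequency 0
    keep <- if (variant == "frequent_only") f >= rare_cutoff else
      f < rare_cutoff
    called <- called[keep]
  }
  if (!length(called) || !length(sig))
    return(list(score = NA_real_, class = NA_character_,
                contributions = data.frame(), n_cnas = 0L))
  imp <- signed_impact$standardized[match(called, signed_impact$genes),
                                    match(sig, signed_impact$genes),
                                    drop = FALSE]
  contrib <- as.numeric(imp %*% dir[sig]) / length(sig)
  score <- mean(contrib)
  list(score = score,
       class = if (score >= 0) "positive" else "negative",
       contributions = data.frame(
         gene = called,
         event = ifelse(patient_calls[called] > 0L, "amp", "del"),
         contribution = contrib, stringsAsFactors = FALSE),
       n_cnas = length(called))
}

#' Score every patient of a cohort
#'
#' Convenience wrapper: builds each patient's signed impact matrix and
#' computes its survival impact score.
#'
#' @param net A `cna_network`.
#' @param expr,cn Cohort matrices.
#' @param profile Cohort [predictability()] profile.
#' @param signature A `signature_set`.
#' @param calls Cohort [call_cnas()] (also supplies training frequencies).
#' @param variant,rare_cutoff Passed to [patient_survival_score()].
#' @param tol,method Passed to [signed_patient_impacts()].
#' @return data.frame (patient, score, class, n_cnas), one row per patient.
#' @export
score_patients <- function(net, expr, cn, profile, signature, calls,
                           variant = "all", rare_cutoff = calls$rare_cutoff,
                           tol = 1e-3, method = "series") {
  rows <- lapply(colnames(expr), function(d) {
    si <- signed_patient_impacts(net, expr, cn, profile, d, tol = tol,
                                 method = method)
    ps <- patient_survival_score(si, signature, calls$calls[, d],
                                 variant = variant,
                                 train_frequency = calls$frequency,
                                 rare_cutoff = rare_cutoff)
    data.frame(patient = d, score = ps$score, class = ps$class,
               n_cnas = ps$n_cnas, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Kaplan-Meier stratification with a permutation test
#'
#' Splits classifiable patients by the sign of their survival impact score,
#' fits Kaplan-Meier curves per class (censoring honored through follow-up
#' time for patients alive), and tests the separation with a permutation
#' test: the observed statistic is the signed restricted-mean-survival
#' difference (positive-class area minus negative-class area up to the
#' shorter of the two last observation times), and the p-value is the
#' fraction of class-label permutations with a separation at least as large
#' (one-sided, with +1 smoothing).
#'
#' @param scores data.frame from [score_patients()] (patient, score, class).
#' @param clinical Clinical table.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return Object of class `km_strat`: list(fit (survfit), p_value,
#'   statistic, n_perm, n (per-class counts), n_unclassifiable).
#' @export
km_stratify <- function(scores, clinical, n_perm = 1000, seed = 1L) {
  df <- merge(scores[!is.na(scores$class), ], clinical,
              by.x = "patient", by.y = "sample_id")
  n_uncl <- sum(is.na(scores$class))
  counts <- table(factor(df$class, levels = c("negative", "positive")))
  if (any(counts == 0L)) {
    warning("a score class is empty; p-value undefined")
    return(structure(list(fit = NULL, p_value = NA_real_,
                          statistic = NA_real_, n_perm = n_perm,
                          n = counts, n_unclassifiable = n_uncl),
                     class = "km_strat"))
  }
  time <- ifelse(df$status == "dead", df$survival_time, df$follow_up)
  if (anyNA(time)) {
    warning("dropping ", sum(is.na(time)),
            " censored patient(s) without follow-up time")
    keep <- !is.na(time)
    df <- df[keep, , drop = FALSE]
    time <- time[keep]
  }
  event <- as.integer(df$status == "dead")
  cls <- df$class == "positive"
  obs <- rmst_difference(time, event, cls)
  set.seed(derive_seed(seed, 29L))
  perm <- replicate(n_perm, rmst_difference(time, event, sample(cls)))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ class, data = df)
  structure(list(fit = fit, p_value = p, statistic = obs, n_perm = n_perm,
                 n = counts, n_unclassifiable = n_uncl),
            class = "km_strat")
}

# Signed area between the two KM curves: restricted mean survival of the
# TRUE class minus the FALSE class, up to the shorter last observation time.
# Product-limit estimator written out directly so the permutation loop does
# not pay survfit's overhead.
rmst_difference <- function(time, event, cls) {
  tau <- min(max(time[cls]), max(time[!cls]))
  km_rmst(time[cls], event[cls], tau) - km_rmst(time[!cls], event[!cls], tau)
}

km_rmst <- function(time, event, tau) {
  o <- order(time)
  t <- time[o]; e <- event[o]
  n <- length(t)
  surv_after <- cumprod(1 - e / (n - seq_len(n) + 1))
  tt <- pmin(t, tau)
  widths <- diff(c(0, tt))
  area <- sum(widths * c(1, surv_after[-n]))
  if (tau > t[n]) area <- area + surv_after[n] * (tau - t[n])
  area
}

#' @export
print.km_strat <- function(x, ...) {
  cat("Kaplan-Meier stratification by survival impact score\n")
  cat("  negative:", x$n[["negative"]], " positive:", x$n[["positive"]],
      " unclassifiable:", x$n_unclassifiable, "\n")
  cat("  restricted-mean-survival difference (positive - negative):",
      format(x$statistic, digits = 4), "\n")
  cat("  permutation p-value:", format(x$p_value, digits = 4),
      sprintf("(%d permutations)\n", x$n_perm))
  invisible(x)
}

#' @export
plot.km_strat <- function(x, ...) {
  if (is.null(x$fit)) stop("no fit to plot", call. = FALSE)
  graphics::plot(x$fit, col = c("blue", "red"), xlab = "time (days)",
                 ylab = "survival probability", ...)
  graphics::legend("topright", legend = c("negative score", "positive score"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Impact by CNA frequency bins
#'
#' Groups gene events into log-spaced frequency bins and summarizes, per
#' bin, the percentage of events flagged high-impact and the median impact
#' of the flagged events; empty bins are NA. A one-sided correlation test
#' (frequency versus selection) quantifies whether more frequently mutated
#' genes are more likely high-impact.
#'
#' @param table Output of [select_high_impact()].
#' @param n_bins Number of log-spaced frequency bins (default 8).
#' @return list(bins (data.frame bin_lo, bin_hi, n, pct_selected,
#'   median_impact), correlation_p).
#' @export
frequency_impact_summary <- function(table, n_bins = 8) {
  if (!any(table$selected)) stop("no flagged gene events", call. = FALSE)
  f <- table$frequency
  rng <- range(f)
  brks <- exp(seq(log(rng[1L]) - 1e-9, log(rng[2L]) + 1e-9,
                  length.out = n_bins + 1L))
  bin <- cut(f, brks, include.lowest = TRUE)
  rows <- lapply(seq_len(n_bins), function(b) {
    idx <- which(as.integer(bin) == b)
    data.frame(bin_lo = brks[b], bin_hi = brks[b + 1L], n = length(idx),
               pct_selected = if (length(idx))
                 100 * mean(table$selected[idx]) else NA_real_,
               median_impact = if (any(table$selected[idx]))
                 stats::median(table$mean_impact[idx][table$selected[idx]])
               else NA_real_)
  })
  ct <- suppressWarnings(stats::cor.test(log(f), as.numeric(table$selected),
                                         alternative = "greater"))
  list(bins = do.call(rbind, rows), correlation_p = ct$p.value)
}
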