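test_that("CNA calling respects the threshold boundary and rarity cutoff", {
  cn <- matrix(0, 2, 300, dimnames = list(c("g1", "g2"), paste0("p", 1:300)))
  cn["g1", 1] <- 0.75
  cn["g1", 2] <- 0.7499
  cn["g2", 1:6] <- -1
  calls <- call_cnas(cn)
  expect_equal(calls$calls["g1", 1], 1L)
  expect_equal(calls$calls["g1", 2], 0L)
  f1 <- calls$frequency[calls$frequency$gene == "g1" &
                          calls$frequency$event == "amp", ]
  expect_equal(f1$frequency, 1 / 300)
  expect_identical(f1$rarity, "rare")
  f2 <- calls$frequency[calls$frequency$gene == "g2", ]
  expect_identical(f2$rarity, "frequent")

  none <- call_cnas(cn * 0)
  expect_equal(sum(none$calls != 0), 0L)
  expect_equal(nrow(none$frequency), 0L)
})

test_that("mean signature impact averages standardized entries", {
  genes <- c("a", "b", "s1", "s2")
  std <- matrix(0, 4, 4, dimnames = list(genes, genes))
  std["a", "s1"] <- 10; std["a", "s2"] <- 30
  imp <- structure(list(raw = std, standardized = std, genes = genes,
                        signed = FALSE, iterations = 1L, method = "direct",
                        tol = NA), class = "impact_matrix")
  cn <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(genes, "p1"))
  calls <- call_cnas(cn)
  tab <- mean_signature_impact(imp, c("s1", "s2"), calls)
  expect_equal(tab$mean_impact[tab$gene == "a"], 20)
  expect_equal(tab$mean_impact[tab$gene == "b"], 0)
  expect_error(mean_signature_impact(imp, character(0), calls), "empty")
})

test_that("cumulative-impact selection drops the low-impact head", {
  tab <- data.frame(gene = paste0("g", 1:4), event = "amp",
                    frequency = 0.1, rarity = "frequent",
                    mean_impact = c(0.1, 0.2, 0.3, 5))
  out <- select_high_impact(tab, cumulative_cutoff = 1)
  expect_identical(out$gene[out$selected], "g4")
  zero <- tab; zero$mean_impact <- 0
  expect_false(any(select_high_impact(zero)$selected))
  one <- tab[4, ]; one$mean_impact <- 2
  expect_true(select_high_impact(one)$selected)
})

test_that("random-network significance reproduces exact small-sample values", {
  truev <- c(g1 = 5, g2 = 1)
  rand <- rbind(g1 = 5 - (1:10) / 10, g2 = rep(1, 10))
  res <- random_network_significance(truev, rand)
  expect_equal(res$p[res$gene == "g1"], 1 / 1024)   # 10 positive differences
  expect_equal(res$p[res$gene == "g2"], 1)          # all-zero differences
  expect_true(all(res$q >= res$p & res$q <= 1))
  expect_error(random_network_significance(truev, rand[, 1:4]), "at least 5")

  # Benjamini-Hochberg on a fixed vector
  expect_equal(stats::p.adjust(c(0.001, 0.5), method = "BH"),
               c(0.002, 0.5))
})

test_that("patient survival scores multiply impact and direction signs", {
  genes <- c("g", "s_neg", "s_pos")
  std <- matrix(0, 3, 3, dimnames = list(genes, genes))
  std["g", "s_neg"] <- -40    # inhibitory impact on both signature genes
  std["g", "s_pos"] <- -40
  si <- structure(list(raw = std, standardized = std, genes = genes,
                       signed = TRUE, iterations = 1L, method = "direct",
                       tol = NA), class = "impact_matrix")
  sig <- structure(data.frame(gene = c("s_neg", "s_pos"),
                              direction = c(-1L, 1L), cluster = 1:2,
                              cluster_p = NA_real_),
                   class = c("signature_set", "data.frame"))
  calls <- stats::setNames(c(1L, 0L, 0L), genes)

  # inhibitory (-) x direction(-1) and (-) x (+1) average to zero here
  ps <- patient_survival_score(si, sig, calls)
  expect_equal(ps$score, 0)
  # against only the negatively associated gene the contribution is positive
  sig1 <- sig[sig$gene == "s_neg", ]
  expect_gt(patient_survival_score(si, sig1, calls)$score, 0)
  # and negative against the positively associated gene
  sig2 <- sig[sig$gene == "s_pos", ]
  expect_lt(patient_survival_score(si, sig2, calls)$score, 0)

  # no called CNAs -> unclassifiable
  none <- patient_survival_score(si, sig, calls * 0L)
  expect_true(is.na(none$score))
  expect_equal(none$n_cnas, 0L)
})

test_that("rare and frequent contributions partition the all-variant score", {
  genes <- c("g_freq", "g_rare", "s")
  std <- matrix(0, 3, 3, dimnames = list(genes, genes))
  std["g_freq", "s"] <- 30
  std["g_rare", "s"] <- -20
  si <- structure(list(raw = std, standardized = std, genes = genes,
                       signed = TRUE, iterations = 1L, method = "direct",
                       tol = NA), class = "impact_matrix")
  sig <- structure(data.frame(gene = "s", direction = 1L, cluster = 1L,
                              cluster_p = NA_real_),
                   class = c("signature_set", "data.frame"))
  calls <- stats::setNames(c(1L, -1L, 0L), genes)
  freq <- data.frame(gene = c("g_freq", "g_rare"), event = c("amp", "del"),
                     frequency = c(0.2, 0.005),
                     rarity = c("frequent", "rare"))
  all_v <- patient_survival_score(si, sig, calls, "all", freq)
  fr <- patient_survival_score(si, sig, calls, "frequent_only", freq)
  ra <- patient_survival_score(si, sig, calls, "rare_only", freq)
  expect_equal(all_v$score,
               (fr$score * fr$n_cnas + ra$score * ra$n_cnas) /
                 (fr$n_cnas + ra$n_cnas))
  expect_equal(fr$n_cnas, 1L)
  expect_equal(ra$n_cnas, 1L)
})

test_that("KM stratification separates classes and respects the null", {
  set.seed(1)
  n <- 80
  cls <- rep(c("positive", "negative"), each = n / 2)
  scores <- data.frame(patient = paste0("p", 1:n),
                       score = ifelse(cls == "positive", 1, -1),
                       class = cls, n_cnas = 1L)
  strong <- make_clinical(scores$patient,
                          ifelse(cls == "positive",
                                 stats::rlnorm(n, log(900), 0.3),
                                 stats::rlnorm(n, log(250), 0.3)))
  km <- km_stratify(scores, strong, n_perm = 500, seed = 2)
  expect_lt(km$p_value, 0.01)
  expect_gt(km$statistic, 0)

  null <- make_clinical(scores$patient, stats::rlnorm(n, log(500), 0.3))
  km0 <- km_stratify(scores, null, n_perm = 500, seed = 3)
  expect_gt(km0$p_value, 0.05)

  onecls <- scores; onecls$class <- "positive"
  expect_warning(kme <- km_stratify(onecls, strong, n_perm = 10), "empty")
  expect_true(is.na(kme$p_value))
})

test_that("frequency-impact summary bins and tests the trend", {
  set.seed(2)
  n <- 60
  freq <- exp(seq(log(0.003), log(0.3), length.out = n))
  tab <- data.frame(gene = paste0("g", 1:n), event = "amp",
                    frequency = freq, rarity = ifelse(freq < 0.01,
                                                      "rare", "frequent"),
                    mean_impact = 0.05 + 3 * freq + runif(n, 0, 0.05))
  out <- select_high_impact(tab, cumulative_cutoff = 1)
  s <- frequency_impact_summary(out, n_bins = 6)
  expect_true(all(s$bins$pct_selected >= 0 & s$bins$pct_selected <= 100,
                  na.rm = TRUE))
  expect_lt(s$correlation_p, 0.05)

  single <- out[out$selected, ][1:3, ]
  single$frequency <- 0.1
  s1 <- frequency_impact_summary(single, n_bins = 1)
  expect_equal(s1$bins$pct_selected, 100)
  expect_error(frequency_impact_summary(out[!out$selected, ], 3), "flagged")
})
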