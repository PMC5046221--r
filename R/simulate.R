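#' Simulation configuration
#'
#' Collects the knobs of the synthetic-cohort generator with defaults chosen
#' to emulate the statistical structure the pipeline assumes: a sparse,
#' hub-containing transcriptional network with a large excess of activating
#' edges, cis copy-number effects for a fraction of genes, three-level CNA
#' log-ratios with frequent and rare events, expression as the fixed point of
#' the simultaneous linear model plus Gaussian noise, and log-linear survival
#' driven by a planted signature gene set.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (cell lines or patients).
#' @param regulators_per_gene Mean number of trans regulators per target
#'   (Poisson in-degree).
#' @param cis_fraction Fraction of genes with a direct (positive) copy-number
#'   effect on their own expression.
#' @param noise_sd Standard deviation of the per-gene Gaussian expression
#'   noise. The default gives a mean per-gene explained variance around 0.7
#'   under the default network.
#' @param cna_rate_frequent,cna_rate_rare Per-sample probability of a CNA at
#'   a frequently / rarely altered gene (half of the genes each).
#' @param cna_magnitude Absolute CNA log-ratio; CNAs are -m, 0 or +m.
#' @param positive_fraction Fraction of trans edges that are activating
#'   (positive coefficient).
#' @param signature_size Number of planted survival signature genes.
#' @param survival_effect Log-linear effect size of the signature on survival
#'   time.
#' @param survival_noise_sd sdlog of the multiplicative lognormal survival
#'   noise.
#' @param n_chromosomes Chromosomes over which genes are spread.
#' @param spectral_target Upper bound imposed on the spectral radius of the
#'   absolute coefficient matrix (trans coefficients are rescaled if needed)
#'   so the fixed point exists and flow sums converge.
#' @param trans_coef_range Absolute magnitude range of trans coefficients.
#' @param seed Integer seed recorded in every output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100, n_samples = 200, regulators_per_gene = 2,
                       cis_fraction = 0.5, noise_sd = 0.3,
                       cna_rate_frequent = 0.2, cna_rate_rare = 0.005,
                       cna_magnitude = 1.0, positive_fraction = 0.88,
                       signature_size = 5, survival_effect = 0.5,
                       survival_noise_sd = 0.25, n_chromosomes = 20,
                       spectral_target = 0.85, trans_coef_range = c(0.35, 0.55),
                       seed = 1L) {
  rates <- c(cis_fraction, cna_rate_frequent, cna_rate_rare, positive_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a ground-truth regulatory network
#'
#' Generates a sparse directed network with heavy-tailed out-degrees (a few
#' hub regulators), trans coefficients of both signs with an activator
#' excess, and non-negative cis copy-number coefficients for a fraction of
#' genes. Genes are placed on chromosomes and trans regulators are never
#' drawn from a target's local chromosomal neighbourhood (within 50 gene
#' ranks), mirroring the model class that the inference stage estimates after
#' local-predictor removal. The absolute coefficient matrix is rescaled, if
#' necessary, so its spectral radius stays below `config$spectral_target`.
#'
#' @param config A [sim_config()].
#' @param dag If TRUE, restrict trans edges to a feed-forward (acyclic)
#'   ordering; by default feedback cycles are allowed.
#' @param fixed_in_degree If TRUE, every gene gets exactly
#'   `regulators_per_gene` trans regulators instead of a Poisson-distributed
#'   number with that mean.
#' @return An object of class `gt_network` with elements `genes`, `cis`
#'   (named vector), `edges` (data.frame regulator/target/coefficient), `A`
#'   (sparse coefficient matrix, rows = regulators, columns = targets),
#'   `annotation`, `spectral_radius`, `config`.
#' @export
simulate_network <- function(config = sim_config(), dag = FALSE,
                             fixed_in_degree = FALSE) {
  n <- config$n_genes
  if (n < 10) stop("n_genes must be >= 10", call. = FALSE)
  if (config$regulators_per_gene >= n)
    stop("regulators_per_gene must be smaller than n_genes", call. = FALSE)
  set.seed(derive_seed(config$seed, 1L))
  genes <- sprintf("g%04d", seq_len(n))

  chrom <- rep_len(paste0("c", seq_len(config$n_chromosomes)), n)
  start <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- sort(sample.int(5e7, length(i)))
  }
  annotation <- make_annotation(genes, chrom, start, start + 10000L)

  cis <- numeric(n)
  n_cis <- round(config$cis_fraction * n)
  if (n_cis > 0) cis[sample.int(n, n_cis)] <- stats::runif(n_cis, 0.8, 1.2)
  names(cis) <- genes

  # heavy-tailed regulator attractiveness -> hub structure
  w <- stats::rlnorm(n, 0, 1.3)
  reg <- integer(0); tgt <- integer(0)
  if (config$regulators_per_gene > 0) {
    for (i in seq_len(n)) {
      k <- if (fixed_in_degree) as.integer(config$regulators_per_gene) else
        stats::rpois(1L, config$regulators_per_gene)
      if (k == 0L) next
      local <- annotation$chromosome == annotation$chromosome[i] &
        abs(annotation$order_index - annotation$order_index[i]) <= 50
      elig <- which(!local & seq_len(n) != i)
      if (dag) elig <- elig[elig < i]
      if (!length(elig)) next
      k <- min(k, length(elig))
      j <- sample(elig, k, prob = w[elig])
      reg <- c(reg, j); tgt <- c(tgt, rep.int(i, k))
    }
  }
  coefs <- numeric(length(reg))
  if (length(reg)) {
    sgn <- ifelse(stats::runif(length(reg)) < config$positive_fraction, 1, -1)
    coefs <- sgn * stats::runif(length(reg), config$trans_coef_range[1L],
                                config$trans_coef_range[2L])
  }
  A <- Matrix::sparseMatrix(i = reg, j = tgt, x = coefs, dims = c(n, n),
                            dimnames = list(genes, genes))
  rho <- spectral_radius(abs(A))
  if (rho >= config$spectral_target && rho > 0) {
    A <- A * (config$spectral_target / rho * 0.999)
    coefs <- A@x[]
    rho <- spectral_radius(abs(A))
  }
  edges <- data.frame(regulator = genes[reg], target = genes[tgt],
                      coefficient = as.numeric(A[cbind(reg, tgt)]),
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, cis = cis, edges = edges, A = A,
                 annotation = annotation, spectral_radius = rho,
                 config = config, dag = dag),
            class = "gt_network")
}

spectral_radius <- function(M) {
  if (all(M == 0)) return(0)
  max(Mod(eigen(as.matrix(M), only.values = TRUE)$values))
}

#' @export
print.gt_network <- function(x, ...) {
  cat("Ground-truth regulatory network:", length(x$genes), "genes,",
      nrow(x$edges), "trans edges,", sum(x$cis > 0), "cis effects\n")
  cat("spectral radius of |A|:", format(x$spectral_radius, digits = 3), "\n")
  invisible(x)
}

#' Simulate an expression / copy-number cohort
#'
#' CNA log-ratios are drawn per gene and sample as 0 with probability
#' 1 - rate and otherwise +/- `cna_magnitude` with equal probability; the
#' first half of the genes uses `cna_rate_frequent`, the second half
#' `cna_rate_rare`. Expression is the fixed point of the simultaneous linear
#' model e = A'e + cis*c + eps with eps ~ N(0, noise_sd^2), solved exactly by
#' matrix inversion (feedback cycles allowed).
#'
#' @param net A `gt_network`.
#' @param config A [sim_config()]; `n_samples`, `noise_sd`, the CNA rates and
#'   the seed are used.
#' @param sample_prefix Prefix for generated sample ids.
#' @return list(expression, copy_number): two genes-by-samples matrices
#'   row-aligned with `net$genes`.
#' @export
simulate_cohort <- function(net, config = net$config, sample_prefix = "s") {
  n <- length(net$genes); D <- config$n_samples
  if (spectral_radius(abs(net$A)) >= 1)
    stop("non-convergent fixed point: spectral radius >= 1", call. = FALSE)
  set.seed(derive_seed(config$seed, 2L))
  samples <- sprintf("%s%04d", sample_prefix, seq_len(D))
  rate <- ifelse(seq_len(n) <= n / 2, config$cna_rate_frequent,
                 config$cna_rate_rare)
  cn <- matrix(0, n, D, dimnames = list(net$genes, samples))
  hit <- matrix(stats::runif(n * D), n, D) < rate
  cn[hit] <- sample(c(-1, 1), sum(hit), replace = TRUE) * config$cna_magnitude
  eps <- matrix(stats::rnorm(n * D, 0, config$noise_sd), n, D)
  Minv <- solve(diag(n) - Matrix::t(net$A))
  expr <- as.matrix(Minv %*% (net$cis * cn + eps))
  dimnames(expr) <- dimnames(cn)
  list(expression = expr, copy_number = cn)
}

#' Simulate survival times driven by a planted signature
#'
#' Survival time is `baseline * exp(effect * s)` times multiplicative
#' lognormal noise, where s is the signature score `sum_g sign_g * z_g`
#' (z_g the standardized expression of signature gene g) normalized to unit
#' cohort variance, so `survival_effect` is the log-scale standard deviation
#' of the survival signal whatever the signature's size and co-expression.
#' All patients are uncensored (status "dead"), matching the downstream
#' random-forest stage which uses uncensored data only.
#'
#' @param expression Genes-by-samples matrix.
#' @param signature Named numeric vector of +1/-1 directions (names = genes),
#'   or a data.frame with columns gene_id and direction.
#' @param config A [sim_config()]; `survival_effect`, `survival_noise_sd` and
#'   the seed are used.
#' @param baseline Baseline survival time in days.
#' @return Clinical data.frame (sample_id, survival_time, status, follow_up).
#' @export
simulate_survival <- function(expression, signature, config = sim_config(),
                              baseline = 365) {
  if (is.data.frame(signature))
    signature <- stats::setNames(signature$direction, signature$gene_id)
  if (length(signature) == 0L) stop("empty signature", call. = FALSE)
  if (!all(names(signature) %in% rownames(expression)))
    stop("signature genes missing from expression matrix", call. = FALSE)
  set.seed(derive_seed(config$seed, 3L))
  z <- t(scale(t(expression[names(signature), , drop = FALSE])))
  z[is.na(z)] <- 0
  lp <- as.numeric(crossprod(z, signature))
  # normalize to unit variance so survival_effect is the sdlog of the
  # signal component regardless of signature size and co-expression
  if (stats::sd(lp) > 0) lp <- lp / stats::sd(lp)
  time <- baseline * exp(config$survival_effect * lp) *
    exp(stats::rnorm(ncol(expression), 0, config$survival_noise_sd))
  data.frame(sample_id = colnames(expression), survival_time = time,
             status = "dead", follow_up = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate knock-down / overexpression perturbation experiments
#'
#' The ground-truth response of all genes to perturbing gene j is the j-th
#' column of (I - A')^-1 - I (the exact propagation of a unit change of e_j
#' through the simultaneous linear system). Each experiment perturbs with a
#' random sign (knock-down or overexpression), adds Gaussian experiment noise
#' to the responses, and reports the top_k/2 most up- and top_k/2 most
#' down-regulated responder genes.
#'
#' @param net A `gt_network`.
#' @param genes Genes to perturb (default: all network genes).
#' @param n_experiments_per_gene Experiments per perturbed gene.
#' @param top_k Total responders reported per experiment (must be even).
#' @param noise_sd SD of per-experiment response noise.
#' @param seed Integer seed.
#' @return data.frame with columns perturbed_gene, experiment, response_gene,
#'   direction ("up"/"down"), the format consumed by
#'   [forward_reverse_validation()].
#' @export
simulate_perturbations <- function(net, genes = net$genes,
                                   n_experiments_per_gene = 5, top_k = 10,
                                   noise_sd = 0.05, seed = 1L) {
  if (top_k %% 2 != 0) stop("top_k must be even", call. = FALSE)
  if (!all(genes %in% net$genes))
    stop("perturbed gene(s) not in network: ",
         paste(setdiff(genes, net$genes), collapse = ", "), call. = FALSE)
  n <- length(net$genes)
  R <- solve(diag(n) - Matrix::t(net$A)) - diag(n)  # column j = response to j
  dimnames(R) <- list(net$genes, net$genes)
  set.seed(derive_seed(seed, 4L))
  half <- top_k / 2L
  out <- vector("list", length(genes) * n_experiments_per_gene)
  k <- 0L
  for (g in genes) {
    base <- as.numeric(R[, g])
    for (ex in seq_len(n_experiments_per_gene)) {
      sgn <- sample(c(-1, 1), 1L)
      resp <- sgn * base + stats::rnorm(n, 0, noise_sd)
      resp[match(g, net$genes)] <- NA
      ord <- order(resp, decreasing = TRUE, na.last = NA)
      up <- ord[seq_len(half)]
      dn <- rev(ord)[seq_len(half)]
      k <- k + 1L
      out[[k]] <- data.frame(
        perturbed_gene = g, experiment = paste0(g, "_e", ex),
        response_gene = net$genes[c(up, dn)],
        direction = rep(c("up", "down"), each = half),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate a complete study (network, cohort, survival, signature)
#'
#' Convenience wrapper used for end-to-end validation: simulates a network
#' and cohort, plants a survival signature among the genes most strongly
#' reachable from cis copy-number effects (so that CNAs can actually move the
#' signature's expression), and simulates survival from it. Directions
#' alternate between +1 and -1.
#'
#' @param config A [sim_config()].
#' @param dag Passed to [simulate_network()].
#' @return list(net, expression, copy_number, clinical, signature,
#'   annotation, config); `signature` is a named +1/-1 vector.
#' @export
simulate_study <- function(config = sim_config(), dag = FALSE) {
  net <- simulate_network(config, dag = dag)
  coh <- simulate_cohort(net, config)
  n <- length(net$genes)
  # upstream CNA influence: |(I - A')^-1| applied to expected cis CNA input
  M <- abs(solve(diag(n) - Matrix::t(net$A)))
  rate <- ifelse(seq_len(n) <= n / 2, config$cna_rate_frequent,
                 config$cna_rate_rare)
  influence <- as.numeric(M %*% (net$cis * rate * config$cna_magnitude))
  # signature genes: strongly CNA-influenced but mutually weakly correlated,
  # so they represent distinct prognostic axes rather than one global
  # co-expression factor
  ord <- order(influence, decreasing = TRUE)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= config$signature_size) break
    r <- if (length(sel))
      suppressWarnings(stats::cor(coh$expression[i, ],
                                  t(coh$expression[sel, , drop = FALSE])))
    else 0
    if (all(is.na(r)) || max(abs(r), na.rm = TRUE) < 0.4)
      sel <- c(sel, i)
  }
  if (length(sel) < config$signature_size)
    sel <- union(sel, ord)[seq_len(config$signature_size)]
  sig_genes <- net$genes[sel]
  # balanced directions: half the (mutually weakly correlated) signature
  # genes are protective, half deleterious, so survival is not a global
  # expression-load factor
  signature <- stats::setNames(rep_len(c(1, -1), length(sig_genes)),
                               sig_genes)
  clinical <- simulate_survival(coh$expression, signature, config)
  list(net = net, expression = coh$expression, copy_number = coh$copy_number,
       clinical = clinical, signature = signature,
       annotation = net$annotation, config = config)
}
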