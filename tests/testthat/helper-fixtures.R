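# Shared fixtures built in code.

# A fitted-network shim holding known coefficients, for exercising the
# impact stage without running inference.
make_network_shim <- function(genes, edges = NULL, cis = NULL) {
  cis <- cis %||% stats::setNames(numeric(length(genes)), genes)
  consensus <- list()
  for (g in genes) {
    sub <- if (is.null(edges)) NULL else edges[edges$target == g, , drop = FALSE]
    trans <- if (!is.null(sub) && nrow(sub))
      stats::setNames(sub$coefficient, sub$regulator) else
        stats::setNames(numeric(0), character(0))
    consensus[[g]] <- structure(list(
      target = g, lambda = 0, cis_coef = unname(cis[g]), cis_pvalue = 0,
      trans_coefs = trans,
      trans_pvalues = stats::setNames(rep(0, length(trans)), names(trans)),
      rmse = 0, n_samples = 10L), class = "gene_model")
  }
  net <- structure(list(consensus = consensus, instances = list(),
                        genes = genes, failures = list(), alpha = 5e-5,
                        n_instances = 0L, window_genes = 50, seed = 1L),
                   class = "cna_network")
  net$edges <- cnaimpact:::edge_table(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ground-truth shim from a gt_network (true coefficients as consensus).
shim_from_gt <- function(gt) {
  ed <- gt$edges
  make_network_shim(gt$genes, edges = ed, cis = gt$cis)
}

# Tiny clinical table from times.
make_clinical <- function(ids, times, status = "dead") {
  data.frame(sample_id = ids, survival_time = times, status = status,
             follow_up = NA_real_, stringsAsFactors = FALSE)
}
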