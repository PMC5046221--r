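# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a base seed and one or two indices.
# Kept below 2^31 so set.seed() always accepts it.
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i) + 104729 * as.numeric(j)) %%
               2147483647)
}

# Normalize chromosome labels so "chr1", "Chr1" and "1" compare equal.
normalize_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (is.null(rownames(x)))
    stop(sprintf("'%s' must have gene ids as rownames", name), call. = FALSE)
  invisible(x)
}
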