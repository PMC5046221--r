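#' Read a genes-by-samples matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; values are tab-separated log-ratios with "." as the decimal
#' mark. The returned matrix has gene ids as rownames and sample ids as
#' colnames. Missing entries are not allowed: genes without measurements
#' should be absent and later zero-filled by [harmonize_universe()].
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (genes x samples).
#' @seealso [write_matrix_tsv()], [harmonize_universe()]
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in matrix ", path, call. = FALSE)
  rownames(m) <- ids
  m
}

#' Write a genes-by-samples matrix to TSV
#'
#' Inverse of [read_matrix_tsv()]; values are written at full precision so a
#' write/read round trip preserves them exactly.
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  stop_if_not_matrix(m, "m")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read copy-number segments (SEG-like TSV)
#'
#' Columns: sample, chromosome, start, end, log_ratio. Coordinates are
#' 0-based half-open. Records with end <= start are rejected with their row
#' index; overlapping records within one sample are rejected.
#'
#' @param path Path to a SEG-like TSV with a header row.
#' @return data.frame with columns sample, chromosome, start, end, log_ratio.
#' @export
read_segments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:5] <- c("sample", "chromosome", "start", "end", "log_ratio")
  validate_segments(df)
  df
}

validate_segments <- function(df) {
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("malformed segment record(s) (end <= start) at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  # overlap check per sample/chromosome
  key <- split(seq_len(nrow(df)), list(df$sample, normalize_chrom(df$chromosome)),
               drop = TRUE)
  for (idx in key) {
    if (length(idx) < 2L) next
    o <- idx[order(df$start[idx])]
    if (any(df$start[o][-1L] < df$end[o][-length(o)]))
      stop("overlapping segments within sample '", df$sample[o[1L]],
           "' on chromosome ", df$chromosome[o[1L]], call. = FALSE)
  }
  invisible(df)
}

#' Read gene annotation (BED-like TSV)
#'
#' Columns: chromosome, start, end, gene_id (0-based half-open). Adds an
#' `order_index` column: the rank of each gene by start position within its
#' chromosome, used by the local-predictor filter
#' ([remove_local_predictors()]).
#'
#' @param path Path to a BED-like TSV with a header row.
#' @return data.frame with columns gene_id, chromosome, start, end, order_index.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chromosome", "start", "end", "gene_id")
  make_annotation(df$gene_id, df$chromosome, df$start, df$end)
}

#' Construct a gene annotation table
#'
#' @param gene_id Character vector of unique gene ids.
#' @param chromosome Chromosome label per gene ("chr" prefixes are normalized).
#' @param start,end Integer base-pair coordinates, 0-based half-open.
#' @return data.frame with gene_id, chromosome, start, end and order_index
#'   (rank of start within chromosome).
#' @export
make_annotation <- function(gene_id, chromosome, start, end) {
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids in annotation", call. = FALSE)
  if (any(end <= start))
    stop("annotation records with end <= start", call. = FALSE)
  df <- data.frame(gene_id = as.character(gene_id),
                   chromosome = normalize_chrom(chromosome),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  df$order_index <- stats::ave(df$start, df$chromosome,
                               FUN = function(s) rank(s, ties.method = "first"))
  df$order_index <- as.integer(df$order_index)
  df
}

#' Read a clinical table
#'
#' Columns: sample_id, time_days, status ("dead"/"alive"), and optionally
#' follow_up_days for censored patients. Rows without a survival time are
#' dropped with a message reporting the count.
#'
#' @param path Path to a TSV file with a header row.
#' @return data.frame with sample_id, survival_time, status, follow_up.
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("sample_id", "survival_time", "status")
  if (!"follow_up" %in% names(df)) df$follow_up <- NA_real_
  miss <- is.na(df$survival_time)
  if (any(miss)) {
    message("dropping ", sum(miss), " clinical row(s) without survival time")
    df <- df[!miss, , drop = FALSE]
  }
  if (!all(df$status %in% c("dead", "alive")))
    stop("clinical status must be 'dead' or 'alive'", call. = FALSE)
  if (any(df$survival_time < 0))
    stop("negative survival times", call. = FALSE)
  df[, c("sample_id", "survival_time", "status", "follow_up")]
}

#' Map copy-number segments to genes
#'
#' A gene overlapped by exactly one segment receives that segment's log-ratio;
#' a gene spanning several segments (segment break inside the gene) receives
#' the unweighted mean of the overlapping segments' log-ratios; a gene covered
#' by no segment is assumed unaltered and set to zero. Overlap is >= 1 shared
#' base pair under 0-based half-open coordinates.
#'
#' @param segments data.frame as returned by [read_segments()] (one sample, or
#'   several samples in long format).
#' @param annotation data.frame as returned by [make_annotation()].
#' @return Named numeric matrix genes x samples of per-gene copy-number
#'   log-ratios (a single-sample input yields a one-column matrix).
#' @export
map_segments_to_genes <- function(segments, annotation) {
  validate_segments(segments)
  segments$chromosome <- normalize_chrom(segments$chromosome)
  known <- segments$chromosome %in% unique(annotation$chromosome)
  if (!all(known)) {
    warning("ignoring ", sum(!known),
            " segment record(s) on chromosome(s) absent from the annotation: ",
            paste(unique(segments$chromosome[!known]), collapse = ", "))
    segments <- segments[known, , drop = FALSE]
  }
  samples <- unique(segments$sample)
  out <- matrix(0, nrow(annotation), max(length(samples), 1L),
                dimnames = list(annotation$gene_id,
                                if (length(samples)) samples else "sample"))
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    for (chr in unique(seg$chromosome)) {
      sc <- seg[seg$chromosome == chr, , drop = FALSE]
      gi <- which(annotation$chromosome == chr)
      for (g in gi) {
        hit <- sc$start < annotation$end[g] & sc$end > annotation$start[g]
        if (any(hit)) out[g, s] <- mean(sc$log_ratio[hit])
      }
    }
  }
  out
}

#' Harmonize matrices to a common gene universe
#'
#' Every output matrix has exactly the reference genes, in reference order.
#' Genes absent from an input are filled with rows of zeros (an artificial
#' zero measurement carries no information for the linear models downstream).
#'
#' @param matrices A single genes-by-samples matrix or a list of them.
#' @param reference_gene_ids Character vector defining the target gene
#'   universe and order; must be non-empty.
#' @return A matrix, or list of matrices, with rows equal to
#'   `reference_gene_ids`.
#' @export
harmonize_universe <- function(matrices, reference_gene_ids) {
  if (length(reference_gene_ids) == 0L)
    stop("reference gene list is empty", call. = FALSE)
  one <- function(m) {
    stop_if_not_matrix(m, "matrices")
    if (anyDuplicated(rownames(m)))
      stop("duplicate gene ids in input matrix: ",
           paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
           call. = FALSE)
    out <- matrix(0, length(reference_gene_ids), ncol(m),
                  dimnames = list(reference_gene_ids, colnames(m)))
    common <- intersect(reference_gene_ids, rownames(m))
    out[common, ] <- m[common, , drop = FALSE]
    out
  }
  if (is.matrix(matrices)) one(matrices) else lapply(matrices, one)
}

#' Write a sparse gene-by-gene matrix as MatrixMarket plus gene sidecar
#'
#' @param m A (sparse) matrix with gene dimnames.
#' @param path Output path for the MTX file; a sidecar TSV `<path>.genes.tsv`
#'   with columns index, gene_id is written next to it.
#' @export
write_sparse_mtx <- function(m, path) {
  sm <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    "CsparseMatrix")
  Matrix::writeMM(sm, path)
  utils::write.table(
    data.frame(index = seq_len(nrow(sm)), gene_id = rownames(m)),
    paste0(path, ".genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse matrix written by [write_sparse_mtx()]
#' @param path Path to the MTX file (sidecar `<path>.genes.tsv` must exist).
#' @return A sparse Matrix with gene dimnames restored.
#' @export
read_sparse_mtx <- function(path) {
  m <- Matrix::readMM(path)
  genes <- utils::read.table(paste0(path, ".genes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)$gene_id
  dimnames(m) <- list(genes, genes)
  methods::as(m, "CsparseMatrix")
}
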