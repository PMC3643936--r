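#' Treatment significance-call matrix
#'
#' Binary gene x treatment matrix: entry 1 means the gene was called
#' significantly regulated in that treatment (the gene-specific error model
#' that produces the calls is upstream of this package; calls are the input).
#'
#' @param calls numeric/logical matrix or data frame, genes in rows.
#' @param genes optional gene names (defaults to rownames).
#' @param treatments optional treatment names (defaults to colnames).
#' @return Object of class `congru_calls` wrapping a 0/1 integer matrix.
#' @export
treatment_calls <- function(calls, genes = rownames(calls), treatments = colnames(calls)) {
  m <- as.matrix(calls)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(treatments)) treatments <- paste0("t", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("calls must be 0/1")
  dimnames(m) <- list(genes, treatments)
  structure(list(calls = m), class = "congru_calls")
}

#' @export
print.congru_calls <- function(x, ...) {
  cat(sprintf("<congru_calls> %d genes x %d treatments, %d calls\n",
              nrow(x$calls), ncol(x$calls), sum(x$calls)))
  invisible(x)
}

#' Read a treatment-call matrix from TSV
#'
#' Genes in rows, treatments in columns, 0/1 entries, first column = gene id.
#'
#' @param path file path.
#' @return A `congru_calls` object.
#' @export
read_treatment_calls <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  treatment_calls(tab)
}

#' Derive significance calls from a P-value matrix
#'
#' @param p numeric matrix of per-treatment P values (genes x treatments).
#' @param threshold call cutoff; entries with `p < threshold` are called.
#' @return A `congru_calls` object.
#' @export
calls_from_pvalues <- function(p, threshold = 0.01) {
  treatment_calls((as.matrix(p) < threshold) * 1L,
                  genes = rownames(p), treatments = colnames(p))
}

#' Co-regulation weight for a gene pair
#'
#' Frequency with which two genes are co-regulated across treatments:
#' `c_both / (c_both + c_a_only + c_b_only)`, where `c_both` counts treatments
#' in which both genes are called and the exclusive counts treatments where
#' only one of them is.  Ranges over (0, 1]; 1 means the genes are never
#' regulated apart.
#'
#' @param c_both treatments where both genes are called (must be >= 1; pairs
#'   never co-called get no edge).
#' @param c_a_only,c_b_only treatments where exactly one gene is called.
#' @return Weight in (0, 1].
#' @export
coregulation_weight <- function(c_both, c_a_only = 0, c_b_only = 0) {
  if (any(c(c_both, c_a_only, c_b_only) < 0)) stop("counts must be non-negative")
  if (any(c_both < 1)) stop("c_both must be >= 1 (pairs never co-called get no edge)")
  c_both / (c_both + c_a_only + c_b_only)
}

#' Build the weighted co-regulation network from treatment calls
#'
#' Connects every pair of genes co-called in at least one treatment, weighted
#' by [coregulation_weight()].  The continuous weight is stored on the
#' network; the integer view used for partitioning is `round(scale * weight)`
#' (half-up), with edges rounding to 0 dropped from that view only (see
#' [partition_weights()]).
#'
#' @param calls a `congru_calls` object.
#' @param layer layer label.
#' @return A weighted `congru_network` whose nodes are all genes of `calls`.
#' @export
build_coregulation_network <- function(calls, layer = "coreg") {
  m <- calls$calls
  if (ncol(m) < 1L) stop("need at least one treatment")
  genes <- rownames(m)
  M <- Matrix::Matrix(m, sparse = TRUE)
  both <- Matrix::tcrossprod(M)            # c_both for every pair
  tot <- Matrix::rowSums(M)                # per-gene call totals
  cb <- Matrix::summary(both)
  cb <- cb[cb$i < cb$j & cb$x >= 1, , drop = FALSE]
  if (nrow(cb) == 0L)
    return(network(NULL, layer = layer, nodes = genes, weighted = TRUE))
  c_both <- cb$x
  # c_a_only + c_b_only = tot_a + tot_b - 2 c_both
  w <- c_both / (tot[cb$i] + tot[cb$j] - c_both)
  network(data.frame(from = genes[cb$i], to = genes[cb$j], weight = as.numeric(w),
                     stringsAsFactors = FALSE),
          layer = layer, nodes = genes, weighted = TRUE)
}
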