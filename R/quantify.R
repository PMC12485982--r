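## Quantification: element x sample count matrix, median-of-ratios size
## factors, and log2 normalization.

#' Build an element-by-sample count matrix of 5' read ends
#'
#' Counts reads whose 5' ends align within each element's span (both
#' strands). Overlapping elements each count shared reads (no
#' disambiguation is attempted).
#'
#' @param tracks named list of 5' `signal_track`s, one per sample; names
#'   are sample ids and must be unique
#' @param elements element table with element_id, chrom, start, end
#' @return integer matrix, rows = element ids, columns = sample ids
#' @export
build_count_matrix <- function(tracks, elements) {
  stopifnot(length(tracks) >= 1L)
  if (is.null(names(tracks)) || anyDuplicated(names(tracks)))
    stop_procapr("tracks must be a named list with unique sample ids")
  el <- as.data.table(elements)
  stopifnot(!anyDuplicated(el$element_id))
  mat <- vapply(tracks, function(t)
    count_in_intervals(t, el)[el$element_id], numeric(nrow(el)))
  mat <- matrix(mat, nrow = nrow(el),
                dimnames = list(el$element_id, names(tracks)))
  mat
}

#' Median-of-ratios size factors
#'
#' The DESeq-style estimator: a pseudo-reference per element is the
#' geometric mean of its counts across samples, computed over elements
#' with strictly positive counts in every sample; each sample's size
#' factor is the median of its count-to-reference ratios over those
#' elements, rescaled so the size factors have geometric mean 1.
#'
#' @param counts count matrix (elements x samples)
#' @return named numeric vector of size factors (geometric mean 1)
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop_procapr("cannot compute size factors: no element has positive ",
                 "counts in all samples")
  lc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lc)                      # log geometric mean
  s <- apply(lc, 2L, function(col) exp(median(col - ref)))
  s <- s / exp(mean(log(s)))               # geometric mean 1
  s
}

#' Normalize a count matrix
#'
#' Divides by size factors and applies a log2(x + 1) transform. The
#' shifted-log transform stands in for a variance-stabilizing transform
#' for downstream correlation, clustering and PCA; both the log values
#' and the plain normalized counts are returned.
#'
#' @param counts count matrix (elements x samples)
#' @param s size factors from [size_factors()]; computed if missing
#' @return object of class `procap_norm`: list with `log2` (log2(count/s
#'   + 1) matrix), `norm` (count/s matrix) and `size_factors`
#' @export
normalize_counts <- function(counts, s = NULL) {
  counts <- as.matrix(counts)
  if (is.null(s)) s <- size_factors(counts)
  stopifnot(length(s) == ncol(counts))
  if (any(s <= 0)) stop_procapr("size factors must be positive")
  norm <- sweep(counts, 2L, s, `/`)
  structure(list(log2 = log2(norm + 1), norm = norm, size_factors = s),
            class = "procap_norm")
}

#' Normalize query samples against a reference cohort
#'
#' Computes per-query size factors as the median ratio of query counts to
#' the reference cohort's per-element geometric means (over elements with
#' strictly positive counts in every reference sample and in the query),
#' then applies the log2(x + 1) transform. This puts new samples (e.g.
#' tumour queries) on the scale of an already-normalized training cohort
#' without refitting its size factors.
#'
#' @param counts query count matrix (elements x query samples), rows
#'   aligned with `reference`
#' @param reference reference count matrix (elements x samples)
#' @return a `procap_norm` for the query samples
#' @export
normalize_against <- function(counts, reference) {
  counts <- as.matrix(counts)
  reference <- as.matrix(reference)
  stopifnot(nrow(counts) == nrow(reference))
  pos <- rowSums(reference > 0) == ncol(reference)
  if (!any(pos))
    stop_procapr("no element has positive counts in all reference samples")
  lref <- rowMeans(log(reference[pos, , drop = FALSE]))
  s <- apply(counts[pos, , drop = FALSE], 2L, function(col) {
    ok <- col > 0
    if (!any(ok))
      stop_procapr("a query sample has no counts on reference elements")
    exp(median(log(col[ok]) - lref[ok]))
  })
  normalize_counts(counts, s)
}

#' @export
print.procap_norm <- function(x, ...) {
  cat(sprintf("<procap_norm: %d elements x %d samples>\n",
              nrow(x$log2), ncol(x$log2)))
  invisible(x)
}
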