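## Initiation shape: the shape index (SI) and peaked/broad classification.
##
## Over the positions inside an element's span that carry at least one
## read on the given strand, with p_i the fraction of that strand's reads
## at position i, SI = 2 + sum_i p_i log2 p_i. SI is 2 for a point mass
## and 2 - log2(L) for a uniform distribution over L positions. Strands
## with SI > -1.5 are "peaked" (P), otherwise "broad" (B); a divergent
## element is then P-P, P-B or B-B.

#' Pool signal tracks across samples of one tissue
#'
#' Position-wise sum of raw counts; all tracks must share the end type.
#'
#' @param tracks list of `signal_track`s
#' @return the pooled `signal_track`
#' @export
pool_tissue_signal <- function(tracks) {
  merge_tracks(tracks)
}

#' Shape index of one element strand
#'
#' @param pooled a pooled 5' `signal_track` (see [pool_tissue_signal()])
#' @param element one element row (element_id, chrom, start, end)
#' @param strand `"+"` or `"-"`
#' @param min_reads strands with fewer reads within the span are filtered
#'   rather than scored (default 50)
#' @return one-row data.table: element_id, strand, n_reads, L (positions
#'   with >= 1 read), SI, label ("P" if SI > -1.5 else "B"; NA when
#'   filtered), filtered flag
#' @export
shape_index <- function(pooled, element, strand, min_reads = 50L) {
  stopifnot(strand %in% c("+", "-"))
  el <- as.data.table(element)
  stopifnot(nrow(el) == 1L)
  sel <- pooled$data[chrom == el$chrom & strand == ..s &
                       pos >= el$start & pos < el$end,
                     env = list(..s = I(strand))]
  n <- sum(sel$count)
  if (n < min_reads)
    return(data.table(element_id = el$element_id, strand = strand,
                      n_reads = n, L = nrow(sel), SI = NA_real_,
                      label = NA_character_, filtered = TRUE))
  p <- sel$count / n
  si <- 2 + sum(p * log2(p))
  data.table(element_id = el$element_id, strand = strand, n_reads = n,
             L = nrow(sel), SI = si,
             label = if (si > -1.5) "P" else "B", filtered = FALSE)
}

#' Shape indices for a set of divergent elements
#'
#' Scores both strands of every divergent element against pooled signal
#' and classifies each scorable element as P-P, P-B or B-B. Elements with
#' fewer than `min_reads` reads on either strand are filtered out of the
#' classification (reported with `filtered = TRUE`).
#'
#' @param pooled a pooled 5' `signal_track`
#' @param elements element table; only rows with directionality
#'   "divergent" are scored
#' @param min_reads per-strand read minimum (default 50)
#' @return list with `strands` (per element x strand table from
#'   [shape_index()]) and `elements` (element_id, category, filtered)
#' @export
shape_classify <- function(pooled, elements, min_reads = 50L) {
  el <- as.data.table(elements)
  el <- el[directionality == "divergent"]
  strands <- rbindlist(lapply(seq_len(nrow(el)), function(i) {
    rbind(shape_index(pooled, el[i], "+", min_reads),
          shape_index(pooled, el[i], "-", min_reads))
  }))
  per_el <- strands[, .(
    category = if (any(filtered)) NA_character_
               else classify_element_shape(label),
    filtered = any(filtered)), by = element_id]
  list(strands = strands, elements = per_el)
}

#' Combine two strand shape labels into an element category
#'
#' @param labels character vector of two labels from `{"P", "B"}` (order
#'   irrelevant)
#' @return `"P-P"`, `"P-B"` or `"B-B"`
#' @export
classify_element_shape <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) != 2L || anyNA(labels) ||
      !all(labels %in% c("P", "B")))
    stop_procapr("need exactly two strand labels from {P, B}")
  paste(sort(labels, decreasing = TRUE), collapse = "-")
}
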