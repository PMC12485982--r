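## TRE classification: divergent/unidirectional pairing of strand peaks
## and annotation of proximity (to gene TSSs) and genomic context.

#' Naive sliding-window peak caller (fixture tool)
#'
#' A deliberately simple caller used to turn synthetic signal into peaks
#' for testing the downstream classification; real analyses should ingest
#' externally called peaks (e.g. from a dedicated nascent-TSS caller) via
#' BED. Maximal runs of window start positions whose `window`-wide sum of
#' counts reaches `min_count` are reported as peaks; the peak interval is
#' the union of those windows, the summit is the position of maximum
#' count (leftmost on ties).
#'
#' @param track a `signal_track`
#' @param min_count minimum read count within a window (>= 1)
#' @param window window width in bases (>= 1)
#' @return data.table of peaks: chrom, strand, start, end, summit, count
#' @export
naive_peak_call <- function(track, min_count = 5L, window = 100L) {
  stopifnot(inherits(track, "signal_track"), min_count >= 1L, window >= 1L)
  dat <- track$data
  if (nrow(dat) == 0L)
    return(data.table(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      summit = integer(), count = numeric()))
  out <- list()
  for (key in split(dat, by = c("chrom", "strand"))) {
    if (nrow(key) == 0L) next
    key <- key[order(pos)]
    lo <- min(key$pos)
    hi <- max(key$pos)
    dense <- numeric(hi - lo + 1L)
    dense[key$pos - lo + 1L] <- key$count
    ## windowed sums over [i, i + window)
    cs <- cumsum(c(0, dense))
    n_win <- length(dense)
    idx <- seq_len(n_win)
    upper <- pmin(idx + window - 1L, n_win)
    wsum <- cs[upper + 1L] - cs[idx]
    hit <- wsum >= min_count
    if (!any(hit)) next
    r <- rle(hit)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (j in which(r$values)) {
      a <- starts_i[j]
      b <- min(ends_i[j] + window - 1L, n_win)
      seg <- dense[a:b]
      smt <- a + which.max(seg) - 1L
      out[[length(out) + 1L]] <- data.table(
        chrom = key$chrom[1L], strand = key$strand[1L],
        start = lo + a - 1L, end = lo + b,
        summit = lo + smt - 1L, count = sum(seg))
    }
  }
  if (!length(out))
    return(data.table(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      summit = integer(), count = numeric()))
  res <- rbindlist(out)
  res[order(chrom, strand, start)]
}

#' Pair opposite-strand peaks into divergent elements
#'
#' Divergent TREs are defined by a pair of peaks on opposite DNA strands
#' whose summits lie within `max_gap` bases of each other. Matching is
#' greedy nearest-summit-first: among all remaining cross-strand pairs on
#' the same chromosome with summit distance <= `max_gap`, the closest pair
#' is taken (ties broken by leftmost plus summit, then leftmost minus
#' summit) and both peaks are removed. Matched pairs become divergent
#' elements whose span is the union of the two peak intervals; unmatched
#' peaks become unidirectional elements.
#'
#' @param plus_peaks,minus_peaks peak tables (chrom, strand, start, end,
#'   summit, count) as produced by [naive_peak_call()] or read from BED
#' @param max_gap maximum summit-to-summit distance in bases (default 300)
#' @return data.table of elements: element_id, chrom, start, end,
#'   directionality, plus_summit, minus_summit, plus_count, minus_count
#' @export
pair_divergent <- function(plus_peaks, minus_peaks, max_gap = 300L) {
  stopifnot(max_gap >= 0)
  pp <- as.data.table(plus_peaks)
  mp <- as.data.table(minus_peaks)
  for (tb in list(pp, mp)) {
    if (nrow(tb) && anyDuplicated(tb[, .(chrom, start, end, summit)]))
      stop_procapr("duplicate peaks on one strand; deduplicate first")
  }
  pp <- pp[order(chrom, summit, start)]
  mp <- mp[order(chrom, summit, start)]
  pairs <- NULL
  if (nrow(pp) && nrow(mp)) {
    cand <- pp[, .(chrom, p_idx = .I, p_summit = summit)][
      mp[, .(chrom, m_idx = .I, m_summit = summit)],
      on = "chrom", allow.cartesian = TRUE, nomatch = NULL]
    cand[, distance := abs(p_summit - m_summit)]
    cand <- cand[distance <= max_gap]
    ## greedy nearest-first with deterministic tie-break
    setorder(cand, distance, p_summit, m_summit)
    p_used <- rep(FALSE, nrow(pp))
    m_used <- rep(FALSE, nrow(mp))
    keep <- logical(nrow(cand))
    if (nrow(cand)) {
      for (i in seq_len(nrow(cand))) {
        pi <- cand$p_idx[i]; mi <- cand$m_idx[i]
        if (!p_used[pi] && !m_used[mi]) {
          keep[i] <- TRUE
          p_used[pi] <- TRUE
          m_used[mi] <- TRUE
        }
      }
    }
    pairs <- cand[keep]
  } else {
    p_used <- rep(FALSE, nrow(pp))
    m_used <- rep(FALSE, nrow(mp))
  }
  res <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    res[[1L]] <- data.table(
      chrom = pairs$chrom,
      start = pmin(pp$start[pairs$p_idx], mp$start[pairs$m_idx]),
      end = pmax(pp$end[pairs$p_idx], mp$end[pairs$m_idx]),
      directionality = "divergent",
      plus_summit = pp$summit[pairs$p_idx],
      minus_summit = mp$summit[pairs$m_idx],
      plus_count = pp$count[pairs$p_idx],
      minus_count = mp$count[pairs$m_idx])
  }
  if (any(!p_used)) {
    up <- pp[!p_used]
    res[[length(res) + 1L]] <- data.table(
      chrom = up$chrom, start = up$start, end = up$end,
      directionality = "unidirectional",
      plus_summit = up$summit, minus_summit = NA_integer_,
      plus_count = up$count, minus_count = NA_real_)
  }
  if (any(!m_used)) {
    um <- mp[!m_used]
    res[[length(res) + 1L]] <- data.table(
      chrom = um$chrom, start = um$start, end = um$end,
      directionality = "unidirectional",
      plus_summit = NA_integer_, minus_summit = um$summit,
      plus_count = NA_real_, minus_count = um$count)
  }
  if (!length(res))
    return(data.table(element_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      directionality = character(),
                      plus_summit = integer(), minus_summit = integer(),
                      plus_count = numeric(), minus_count = numeric()))
  el <- rbindlist(res)
  setorder(el, chrom, start, end)
  el[, element_id := sprintf("el_%05d", .I)]
  setcolorder(el, "element_id")
  el[]
}

#' Annotate elements as promoter-proximal or distal
#'
#' An element is proximal when the midpoint of its span lies within
#' `cutoff` bases (inclusive) of any annotated gene TSS, and distal
#' otherwise. Elements on chromosomes without genes are distal.
#'
#' @param elements element table (needs chrom, start, end)
#' @param genes gene annotation table (see [gene_annotation()])
#' @param cutoff unsigned distance threshold in bases (default 500)
#' @return the element table with a `proximity` column
#' @export
annotate_proximity <- function(elements, genes, cutoff = 500L) {
  stopifnot(nrow(genes) > 0)
  el <- as.data.table(elements)
  mid <- (el$start + el$end) %/% 2L
  g <- as.data.table(genes)
  dist_min <- vapply(seq_len(nrow(el)), function(i) {
    tsss <- g[chrom == el$chrom[i], tss]
    if (!length(tsss)) return(Inf)
    min(abs(tsss - mid[i]))
  }, numeric(1L))
  el[, proximity := ifelse(dist_min <= cutoff, "proximal", "distal")]
  el[]
}

#' Annotate elements as intergenic or intragenic
#'
#' Intragenic means the element span overlaps any gene interval by at
#' least 1 bp (half-open overlap).
#'
#' @inheritParams annotate_proximity
#' @return the element table with a `context` column
#' @export
annotate_context <- function(elements, genes) {
  stopifnot(nrow(genes) > 0)
  el <- as.data.table(elements)
  g <- as.data.table(genes)
  hit <- vapply(seq_len(nrow(el)), function(i) {
    gg <- g[chrom == el$chrom[i]]
    any(gg$start < el$end[i] & gg$end > el$start[i])
  }, logical(1L))
  el[, context := ifelse(hit, "intragenic", "intergenic")]
  el[]
}
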