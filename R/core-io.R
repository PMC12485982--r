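## Core data containers and readers/writers.
##
## Conventions: all coordinates 0-based half-open; per-base read-end counts
## are stored sparsely as a data.table keyed by (chrom, strand, pos); minus
## strand counts are non-negative magnitudes (signed minus-strand bedGraph
## dialects are folded to absolute values on read).

#' Create an empty signal track
#'
#' A signal track holds sparse per-base counts of read 5' (or 3') ends,
#' keyed by chromosome, strand and position. It is the atomic PRO-cap
#' observable: every downstream computation (counting, QC, shape, pausing)
#' consumes signal tracks.
#'
#' @param end_type which read end the track records: `"five_prime"` or
#'   `"three_prime"`.
#' @return an object of class `signal_track` with fields `end_type`,
#'   `data` (data.table with columns chrom, strand, pos, count) and
#'   `library_size` (sum of all counts).
#' @export
signal_track <- function(end_type = c("five_prime", "three_prime")) {
  end_type <- match.arg(end_type)
  dt <- data.table(chrom = character(), strand = character(),
                   pos = integer(), count = numeric())
  setkey(dt, chrom, strand, pos)
  structure(list(end_type = end_type, data = dt, library_size = 0),
            class = "signal_track")
}

## build a track from a (chrom, strand, pos[, count]) table, aggregating
## duplicate positions
track_from_dt <- function(dt, end_type = "five_prime") {
  t <- signal_track(end_type)
  if (nrow(dt) == 0L) return(t)
  if (!"count" %in% names(dt)) dt[, count := 1]
  agg <- dt[, .(count = sum(count)), by = .(chrom, strand, pos)]
  agg[, pos := as.integer(pos)]
  setkey(agg, chrom, strand, pos)
  t$data <- agg
  t$library_size <- sum(agg$count)
  t
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track %s: %d positions, library size %s>\n",
              x$end_type, nrow(x$data),
              format(x$library_size, big.mark = ",")))
  invisible(x)
}

#' Merge signal tracks by position-wise summation
#'
#' @param ... signal tracks of the same end type (or a single list of them)
#' @return a merged `signal_track`
#' @export
merge_tracks <- function(...) {
  tracks <- list(...)
  if (length(tracks) == 1L && !inherits(tracks[[1L]], "signal_track"))
    tracks <- tracks[[1L]]
  stopifnot(length(tracks) >= 1L)
  ends <- vapply(tracks, function(t) t$end_type, character(1L))
  if (length(unique(ends)) != 1L)
    stop_procapr("cannot merge tracks with different end types: ",
                 paste(unique(ends), collapse = ", "))
  dt <- rbindlist(lapply(tracks, function(t) t$data))
  track_from_dt(dt, ends[1L])
}

#' Read a 4-column bedGraph file into a signal track
#'
#' Interval values are expanded to per-base counts. Values must be
#' integers; on the minus strand, the common signed dialect (negative
#' values for minus-strand coverage) is accepted and folded to magnitudes
#' with a message.
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#'   Lines starting with `track` or `#` are skipped.
#' @param end_type `"five_prime"` or `"three_prime"`
#' @param strand `"+"` or `"-"`; bedGraph is unstranded, so the strand the
#'   file represents must be stated.
#' @return a `signal_track` holding this strand's counts (merge strands
#'   with [merge_tracks()])
#' @export
read_bedgraph <- function(path, end_type = c("five_prime", "three_prime"),
                          strand) {
  end_type <- match.arg(end_type)
  stopifnot(strand %in% c("+", "-"))
  strand_chr <- strand
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) return(signal_track(end_type))
  ln_no <- which(keep)
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop_procapr("malformed bedGraph line ", ln_no[bad[1L]], " in ", path,
                 ": expected 4 fields")
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  value <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad))
    stop_procapr("malformed bedGraph line ", ln_no[bad[1L]], " in ", path)
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop_procapr("invalid interval (need 0 <= start < end) at line ",
                 ln_no[bad[1L]], " in ", path)
  bad <- which(value != round(value))
  if (length(bad))
    stop_procapr("non-integer count at line ", ln_no[bad[1L]], " in ",
                 path)
  if (any(value < 0)) {
    if (strand_chr != "-")
      stop_procapr("negative count on plus-strand bedGraph at line ",
                   ln_no[which(value < 0)[1L]], " in ", path)
    message("read_bedgraph: signed minus-strand dialect detected in ",
            path, "; taking absolute values")
    value <- abs(value)
  }
  dt <- data.table(chrom = m[, 1L], start = as.integer(start),
                   end = as.integer(end), value = value)
  dt <- dt[value > 0]
  if (nrow(dt) == 0L) return(signal_track(end_type))
  w <- dt$end - dt$start
  expanded <- dt[rep(seq_len(.N), w)]
  expanded[, pos := as.integer(start + sequence(w) - 1L)]
  out <- expanded[, .(chrom, pos, count = value)]
  out[, strand := strand_chr]
  track_from_dt(out, end_type)
}

#' Write one chromosome/strand of a signal track as bedGraph
#'
#' Runs of adjacent positions with equal counts are collapsed into single
#' intervals, so `read_bedgraph(write_bedgraph(t))` round-trips exactly.
#'
#' @param track a `signal_track`
#' @param chrom chromosome to export
#' @param strand strand to export (`"+"` or `"-"`)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(track, chrom, strand, path) {
  stopifnot(inherits(track, "signal_track"), strand %in% c("+", "-"))
  chrom_q <- chrom
  strand_q <- strand
  sel <- track$data[.(chrom_q, strand_q), nomatch = NULL]
  if (nrow(sel) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  sel <- sel[order(pos)]
  brk <- c(TRUE, diff(sel$pos) != 1L | diff(sel$count) != 0)
  grp <- cumsum(brk)
  out <- sel[, .(start = pos[1L], end = pos[.N] + 1L, count = count[1L]),
             by = .(g = grp)]
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, out$start, out$end,
                     format(out$count, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Count read ends falling inside a genomic interval
#'
#' Containment is 0-based half-open: a read end at position p is counted
#' when `start <= p < end`.
#'
#' @param track a `signal_track`
#' @param chrom,start,end the interval (0-based half-open)
#' @param strand_mode `"both"`, `"plus"` or `"minus"`
#' @param warn_missing warn when `chrom` is absent from the track
#'   (samples may lack scaffolds); the count is then 0
#' @return the summed count (numeric scalar)
#' @export
count_in_interval <- function(track, chrom, start, end,
                              strand_mode = c("both", "plus", "minus"),
                              warn_missing = TRUE) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(track, "signal_track"), start >= 0, start < end)
  if (!chrom %in% unique(track$data$chrom)) {
    if (warn_missing)
      warning("chromosome '", chrom, "' not present in track; returning 0",
              call. = FALSE)
    return(0)
  }
  strands <- switch(strand_mode, both = c("+", "-"), plus = "+",
                    minus = "-")
  sel <- track$data[chrom == ..chrom_arg & strand %in% ..strands_arg &
                      pos >= ..start_arg & pos < ..end_arg,
                    env = list(..chrom_arg = I(chrom),
                               ..strands_arg = I(strands),
                               ..start_arg = start, ..end_arg = end)]
  sum(sel$count)
}

## Vectorized interval counting used to build count matrices: intervals is
## a data.table with (element_id, chrom, start, end); returns a named
## numeric vector over element_id. strand_mode as in count_in_interval.
count_in_intervals <- function(track, intervals,
                               strand_mode = c("both", "plus", "minus")) {
  strand_mode <- match.arg(strand_mode)
  strands <- switch(strand_mode, both = c("+", "-"), plus = "+",
                    minus = "-")
  dat <- track$data[strand %in% strands]
  iv <- as.data.table(intervals)[, .(element_id, chrom,
                                     start = as.integer(start),
                                     end = as.integer(end))]
  res <- dat[iv, on = .(chrom, pos >= start, pos < end),
             .(n = sum(x.count)), by = .EACHI, allow.cartesian = TRUE]
  out <- res$n
  out[is.na(out)] <- 0
  stats::setNames(out, iv$element_id)
}

#' Average signal profile around a set of anchor points
#'
#' Extracts a window of `2 * flank + 1` positions centred on each anchor,
#' reverses windows of minus-strand anchors so that downstream of the
#' anchor is always rightward, and averages position-wise across anchors.
#' Signal from all strands of all supplied tracks is summed.
#'
#' @param tracks a `signal_track` or list of them
#' @param anchors data.frame with columns `chrom`, `center` and optionally
#'   `strand` (`"+"`, `"-"` or `"."`; default `"."` treated as `"+"`
#'   orientation)
#' @param flank number of bases either side of the anchor (> 0)
#' @return numeric vector of length `2 * flank + 1`, names giving the
#'   offset from the anchor
#' @export
metaplot <- function(tracks, anchors, flank) {
  if (inherits(tracks, "signal_track")) tracks <- list(tracks)
  stopifnot(flank > 0)
  anchors <- as.data.frame(anchors)
  if (nrow(anchors) == 0L) stop_procapr("metaplot requires >= 1 anchor")
  if (is.null(anchors$strand)) anchors$strand <- "."
  dat <- rbindlist(lapply(tracks, function(t) t$data))
  dat <- dat[, .(count = sum(count)), by = .(chrom, pos)]
  setkey(dat, chrom, pos)
  width <- 2L * flank + 1L
  acc <- numeric(width)
  for (i in seq_len(nrow(anchors))) {
    ctr <- anchors$center[i]
    win <- dat[.(anchors$chrom[i]), nomatch = NULL][
      pos >= ctr - flank & pos <= ctr + flank]
    prof <- numeric(width)
    if (nrow(win)) prof[win$pos - ctr + flank + 1L] <- win$count
    if (anchors$strand[i] == "-") prof <- rev(prof)
    acc <- acc + prof
  }
  out <- acc / nrow(anchors)
  names(out) <- as.character(seq(-flank, flank))
  out
}

#' Assemble a gene annotation table
#'
#' @param gene_id unique gene identifiers
#' @param chrom,start,end gene intervals (0-based half-open)
#' @param strand `"+"` or `"-"` per gene
#' @return data.table with columns gene_id, chrom, start, end, strand and
#'   derived columns `tss` and `tts` (0-based positions of the
#'   transcription start and termination sites: start for `+` genes,
#'   `end - 1` for `-` genes, and vice versa)
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  stopifnot(!anyDuplicated(gene_id), all(strand %in% c("+", "-")),
            all(start >= 0), all(start < end))
  g <- data.table(gene_id = as.character(gene_id), chrom = chrom,
                  start = as.integer(start), end = as.integer(end),
                  strand = strand)
  g[, tss := ifelse(strand == "+", start, end - 1L)]
  g[, tts := ifelse(strand == "+", end - 1L, start)]
  g[]
}

#' Read gene annotations from a BED6 file
#'
#' Uses the first six BED columns (chrom, start, end, name, score,
#' strand); name becomes the gene id.
#'
#' @param path BED file
#' @return a gene annotation table (see [gene_annotation()])
#' @export
read_genes_bed <- function(path) {
  dt <- fread(path, header = FALSE)
  if (ncol(dt) < 6L)
    stop_procapr("gene BED requires >= 6 columns (strand needed)")
  gene_annotation(dt[[4L]], dt[[1L]], dt[[2L]], dt[[3L]], dt[[6L]])
}

#' Read a sample-to-tissue design table
#'
#' @param path TSV with header columns `sample_id` and `tissue`
#' @return data.table with those two character columns
#' @export
read_design <- function(path) {
  dt <- fread(path, colClasses = "character")
  if (!all(c("sample_id", "tissue") %in% names(dt)))
    stop_procapr("design table needs 'sample_id' and 'tissue' columns")
  if (anyDuplicated(dt$sample_id))
    stop_procapr("duplicate sample_id in design table")
  dt[, .(sample_id, tissue)]
}

#' Read a table of matched read 5'/3' end positions
#'
#' @param path TSV with header columns chrom, strand, five_prime_pos,
#'   three_prime_pos (0-based positions)
#' @return data.table of read pairs
#' @export
read_pairs <- function(path) {
  dt <- fread(path)
  need <- c("chrom", "strand", "five_prime_pos", "three_prime_pos")
  if (!all(need %in% names(dt)))
    stop_procapr("read-pair table needs columns: ",
                 paste(need, collapse = ", "))
  stopifnot(all(dt$strand %in% c("+", "-")),
            all(dt$five_prime_pos >= 0), all(dt$three_prime_pos >= 0))
  dt[, need, with = FALSE]
}

#' Write elements as BED6+ with annotation columns
#'
#' @param elements element table from [pair_divergent()] and annotators
#' @param path output file
#' @return `path`, invisibly
#' @export
write_elements_bed <- function(elements, path) {
  el <- as.data.table(elements)
  extra <- intersect(c("directionality", "proximity", "context"),
                     names(el))
  out <- el[, .(chrom, start, end, name = element_id, score = 0L,
                strand = ".")]
  for (cc in extra) out[[cc]] <- el[[cc]]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
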