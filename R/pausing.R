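## Single-molecule RNAPII pause distances.
##
## Each read pair gives the distance from the initiation site (5' end) to
## the polymerase pause position (3' end): three_prime - five_prime on the
## plus strand, five_prime - three_prime on the minus strand. Reads are
## assigned to the element containing their 5' end; negative distances are
## malformed and discarded (tallied).

#' Compute per-element pause-distance distributions
#'
#' @param pairs read-pair table (chrom, strand, five_prime_pos,
#'   three_prime_pos), e.g. from [read_pairs()]
#' @param elements element table (element_id, chrom, start, end); when an
#'   element overlap is ambiguous the first containing element in table
#'   order wins
#' @return list with `distances` (data.table element_id, distance),
#'   `summary` (element_id, n, median — lower median), and `tally`
#'   (assigned, unassigned, malformed; assigned + unassigned + malformed
#'   = input rows)
#' @export
pause_distances <- function(pairs, elements) {
  pr <- as.data.table(pairs)
  stopifnot(all(pr$strand %in% c("+", "-")))
  el <- as.data.table(elements)[, .(element_id, chrom, start, end)]
  pr <- copy(pr)
  pr[, distance := ifelse(strand == "+",
                          three_prime_pos - five_prime_pos,
                          five_prime_pos - three_prime_pos)]
  n_total <- nrow(pr)
  malformed <- pr$distance < 0
  n_malformed <- sum(malformed)
  ok <- pr[!malformed]
  ## assign by 5'-end containment; first containing element wins
  el <- copy(el)
  el[, idx := .I]
  ok[, read_id := .I]
  ov <- el[ok, on = .(chrom, start <= five_prime_pos,
                      end > five_prime_pos),
           .(element_id = x.element_id, idx = x.idx,
             read_id = i.read_id, distance = i.distance),
           nomatch = NULL, allow.cartesian = TRUE]
  ov <- ov[order(read_id, idx)]
  ov <- ov[!duplicated(read_id)]
  n_assigned <- nrow(ov)
  n_unassigned <- nrow(ok) - n_assigned
  dist_tab <- ov[, .(element_id, distance)]
  summ <- dist_tab[, .(n = .N, median = lower_median(distance)),
                   by = element_id]
  setorder(summ, element_id)
  list(distances = dist_tab, summary = summ,
       tally = c(assigned = n_assigned, unassigned = n_unassigned,
                 malformed = n_malformed))
}

#' Classify elements into early/intermediate/late pausing
#'
#' Tertile mode (default) splits the per-element median pause distances at
#' their empirical 1/3 and 2/3 boundaries; elements at or below the first
#' cut are "early", above the second "late", the rest "intermediate".
#' Because pause medians are discrete and often heavily tied, each
#' boundary is snapped to the distinct median value whose cumulative
#' element count is closest to n/3 (respectively 2n/3), so a group of
#' equal medians is never split across classes; for continuous data this
#' reduces to ordinary tertiles. When the two boundaries coincide (e.g.
#' all medians equal) every element is "intermediate". Fixed mode uses
#' user-supplied cuts instead.
#'
#' @param summary the `summary` table from [pause_distances()]
#' @param mode `"tertile"` or `"fixed"`
#' @param fixed_cuts numeric length-2 vector (low, high) for fixed mode
#' @param min_reads elements with fewer reads are dropped (default 20)
#' @return the summary table (filtered to `n >= min_reads`) with a
#'   `class` column in {early, intermediate, late}
#' @export
classify_pausing <- function(summary, mode = c("tertile", "fixed"),
                             fixed_cuts = NULL, min_reads = 20L) {
  mode <- match.arg(mode)
  s <- as.data.table(summary)[n >= min_reads]
  if (mode == "tertile") {
    if (nrow(s) < 3L)
      stop_procapr("tertile mode needs >= 3 elements with n >= ",
                   min_reads, "; use mode = 'fixed'")
    vals <- sort(unique(s$median))
    cum <- cumsum(as.vector(table(factor(s$median, levels = vals))))
    n_el <- nrow(s)
    cuts <- c(vals[which.min(abs(cum - n_el / 3))],
              vals[which.min(abs(cum - 2 * n_el / 3))])
  } else {
    if (is.null(fixed_cuts) || length(fixed_cuts) != 2L)
      stop_procapr("fixed mode needs fixed_cuts = c(low, high)")
    cuts <- sort(fixed_cuts)
  }
  if (cuts[1L] == cuts[2L]) {
    s[, class := "intermediate"]
  } else {
    s[, class := ifelse(median <= cuts[1L], "early",
                        ifelse(median > cuts[2L], "late",
                               "intermediate"))]
  }
  attr(s, "cuts") <- cuts
  s[]
}

#' Compare two pause-distance samples by difference of medians
#'
#' Location-shift summary for perturbation comparisons (e.g. factor
#' depletion): difference of lower medians with a percentile bootstrap
#' confidence interval.
#'
#' @param d1,d2 numeric vectors of pause distances (condition 1 and 2)
#' @param n_boot bootstrap resamples (default 1000)
#' @param conf confidence level (default 0.95)
#' @param seed integer seed for the resampling
#' @return list with `diff` (median(d2) - median(d1)), `ci` (two-sided
#'   percentile interval), `n` (sample sizes)
#' @export
compare_pause_sets <- function(d1, d2, n_boot = 1000L, conf = 0.95,
                               seed = 1L) {
  stopifnot(length(d1) >= 2L, length(d2) >= 2L)
  obs <- lower_median(d2) - lower_median(d1)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    lower_median(sample(d2, length(d2), replace = TRUE)) -
      lower_median(sample(d1, length(d1), replace = TRUE))
  }, numeric(1L)))
  alpha <- (1 - conf) / 2
  list(diff = obs,
       ci = unname(quantile(boots, c(alpha, 1 - alpha))),
       n = c(n1 = length(d1), n2 = length(d2)))
}
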