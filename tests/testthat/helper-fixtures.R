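## Shared fixtures built in code.

library(data.table)

## build a signal track from position/count vectors
make_track <- function(chrom, strand, pos, count = 1,
                       end_type = "five_prime") {
  dt <- data.table(chrom = chrom, strand = strand, pos = as.integer(pos),
                   count = count)
  procapr:::track_from_dt(dt, end_type)
}

## a one-row element table
make_element <- function(id = "el1", chrom = "chr1", start = 0L,
                         end = 1000L, directionality = "divergent") {
  data.table(element_id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), directionality = directionality)
}

## peaks table row(s)
make_peaks <- function(chrom, strand, summit, start = summit - 50L,
                       end = summit + 50L, count = 100) {
  data.table(chrom = chrom, strand = strand, start = as.integer(start),
             end = as.integer(end), summit = as.integer(summit),
             count = count)
}

## brute-force oracle for divergent pairing: enumerate all matchings of
## cross-strand peak pairs within max_gap, keep maximal matchings only,
## and return the one whose sorted distance vector is lexicographically
## smallest. Independent of the greedy implementation.
brute_force_pairing <- function(plus_summits, minus_summits,
                                max_gap = 300) {
  edges <- list()
  for (i in seq_along(plus_summits)) {
    for (j in seq_along(minus_summits)) {
      d <- abs(plus_summits[i] - minus_summits[j])
      if (d <= max_gap)
        edges[[length(edges) + 1L]] <- c(i = i, j = j, d = d)
    }
  }
  if (!length(edges)) return(list(n_pairs = 0L, dists = numeric()))
  best <- NULL
  lex_less <- function(a, b) {
    ## element-wise lexicographic comparison of sorted distance vectors;
    ## on an equal prefix the shorter vector wins (mirrors that taking
    ## the globally closest pair first can block further pairings)
    for (k in seq_len(min(length(a), length(b)))) {
      if (a[k] < b[k]) return(TRUE)
      if (a[k] > b[k]) return(FALSE)
    }
    length(a) < length(b)
  }
  n_e <- length(edges)
  recurse <- function(k, used_i, used_j, dists) {
    if (k > n_e) {
      ## maximality: no edge with both endpoints free
      for (e in edges)
        if (!(e["i"] %in% used_i) && !(e["j"] %in% used_j)) return()
      ds <- sort(dists)
      if (is.null(best) || lex_less(ds, best$dists))
        best <<- list(n_pairs = length(ds), dists = ds)
      return()
    }
    e <- edges[[k]]
    if (!(e["i"] %in% used_i) && !(e["j"] %in% used_j))
      recurse(k + 1L, c(used_i, e["i"]), c(used_j, e["j"]),
              c(dists, e["d"]))
    recurse(k + 1L, used_i, used_j, dists)
  }
  recurse(1L, integer(), integer(), numeric())
  best
}

## independent lower-median oracle (plain sort + index)
lower_median_oracle <- function(x) sort(x)[ceiling(length(x) / 2)]

## shared small simulated dataset reused by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(truth_config(seed = 42))
    cache
  }
})
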