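# Independent brute-force reference implementations used to cross-check
# the package's vectorized computations on small inputs.

# plain double loop over cells: area-weighted mean per basin
oracle_basin_mean <- function(values, assignment, cell_area, ids) {
  out <- setNames(rep(NA_real_, length(ids)), as.character(ids))
  for (b in ids) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(values))) for (j in seq_len(ncol(values))) {
      if (assignment[i, j] == b && !is.na(values[i, j])) {
        num <- num + values[i, j] * cell_area[i, j]
        den <- den + cell_area[i, j]
      }
    }
    if (den > 0) out[as.character(b)] <- num / den
  }
  out
}

oracle_basin_sum <- function(values, assignment, ids) {
  out <- setNames(rep(NA_real_, length(ids)), as.character(ids))
  for (b in ids) {
    acc <- NA_real_
    for (i in seq_len(nrow(values))) for (j in seq_len(ncol(values))) {
      if (assignment[i, j] == b && !is.na(values[i, j]))
        acc <- sum(c(acc, values[i, j]), na.rm = TRUE)
    }
    out[as.character(b)] <- acc
  }
  out
}

# sort-based percentile oracle: assign each tied group the bin of the
# midpoint of its cumulative-area span
oracle_percentile <- function(v, a, bins = 100) {
  o <- order(v)
  tot <- sum(a)
  p <- numeric(length(v))
  cum <- 0
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
    grp <- o[i:j]
    span <- sum(a[grp])
    mid <- cum + span / 2
    p[grp] <- ceiling(bins * mid / tot) / bins
    cum <- cum + span
    i <- j + 1
  }
  p
}

# recursive-mean Head/Tail Breaks reference, written as plain recursion
oracle_htb_breaks <- function(v, depth) {
  if (depth == 0 || length(v) == 0) return(numeric(0))
  m <- mean(v)
  head_v <- v[v > m]
  if (length(head_v) < 2 || length(unique(head_v)) == 1) return(m)
  c(m, oracle_htb_breaks(head_v, depth - 1))
}

oracle_htb_class <- function(v, breaks) {
  vapply(v, function(x) 1L + sum(x > breaks), integer(1))
}

# loop-based overlap-weighted national score
oracle_iwrm <- function(overlap, scores) {
  ids <- sort(unique(overlap$basin_id))
  out <- setNames(rep(NA_real_, length(ids)), as.character(ids))
  for (b in ids) {
    rows <- overlap[overlap$basin_id == b, ]
    num <- 0; den <- 0
    for (r in seq_len(nrow(rows))) {
      s <- scores$score[scores$nation_id == rows$nation_id[r]]
      num <- num + rows$fraction[r] * s
      den <- den + rows$fraction[r]
    }
    out[as.character(b)] <- num / den
  }
  out
}
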