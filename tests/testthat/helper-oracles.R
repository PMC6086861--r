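# Brute-force reference implementations used to cross-check the graph layer.
# These are deliberately written as plain loops over the definitions, fully
# independent of the package's (igraph / matrix-algebra) code paths.

# all-pairs shortest paths on reciprocal-weight lengths, Floyd-Warshall
oracle_distances <- function(w) {
  r <- nrow(w)
  d <- matrix(Inf, r, r)
  diag(d) <- 0
  for (i in seq_len(r)) for (j in seq_len(r))
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  for (k in seq_len(r)) for (i in seq_len(r)) for (j in seq_len(r))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Onnela clustering by explicit triangle enumeration
oracle_clustering <- function(w) {
  r <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, r))
  wh <- (w / mx)^(1 / 3)
  out <- numeric(r)
  for (i in seq_len(r)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(r)) for (h in seq_len(r))
      if (j != i && h != i && j != h)
        acc <- acc + wh[i, j] * wh[j, h] * wh[h, i]
    out[i] <- acc / (k * (k - 1))
  }
  out
}

oracle_closeness <- function(d) {
  r <- nrow(d)
  sapply(seq_len(r), function(i) {
    s <- 0
    for (j in seq_len(r)) if (j != i && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    s / (r - 1)
  })
}

oracle_efficiency <- function(d) mean(oracle_closeness(d))

oracle_cpl <- function(d) {
  vals <- c()
  r <- nrow(d)
  for (i in seq_len(r)) for (j in seq_len(r))
    if (i != j && is.finite(d[i, j])) vals <- c(vals, d[i, j])
  mean(vals)
}

# random sparse symmetric weighted graph on r nodes
random_weighted_graph <- function(r, p_edge = 0.3) {
  w <- matrix(0, r, r)
  ut <- which(upper.tri(w))
  on <- ut[stats::runif(length(ut)) < p_edge]
  w[on] <- stats::runif(length(on), 0.05, 1)
  w + t(w)
}

# small two-system partition for toy block tests
toy_partition <- function(sizes = c(A = 2L, B = 2L)) {
  part <- data.frame(
    roi = sprintf("ROI%03d", seq_len(sum(sizes))),
    system = factor(rep(names(sizes), times = sizes), levels = names(sizes)),
    stringsAsFactors = FALSE)
  class(part) <- c("network_partition", "data.frame")
  part
}

# reduced-scale null/planted cohort -> per-subject block-delta matrix.
# Scrub-only processing: the generator's frames are trend-free and white, so
# temporal filtering would remove no artifact, only temporal df.
cohort_block_deltas <- function(config, planted_delta = 0) {
  co <- simulate_cohort(config, planted_delta = planted_delta)
  p <- co$partition
  subj <- co$design$subject
  blocks <- lapply(stats::setNames(subj, subj), function(sj) {
    lapply(1:2, function(s) {
      ts <- scrub(co$sessions[[paste0(sj, ".ses-", s)]],
                  min_frames = 0L)$ts
      block_summary(fc_matrix(ts), p)
    })
  })
  list(cohort = co, blocks = blocks)
}
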