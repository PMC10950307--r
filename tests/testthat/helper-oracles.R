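# Independent brute-force oracles used across the suite.

# naive double-loop response score: sum of weights of clusters with >= G
# active sources
naive_pc_response <- function(clusters, weights, activity, G) {
  total <- 0
  for (k in seq_len(nrow(clusters))) {
    n_active <- 0
    for (s in clusters[k, ]) {
      if (activity[s]) n_active <- n_active + 1
    }
    if (n_active >= G) total <- total + weights[k]
  }
  total
}

# exhaustive count of G-subsets of I elements (capacity oracle, small I)
enumerate_subsets <- function(I, G) {
  if (G == 0 || G == I) return(1L)
  ncol(combn(I, G))
}

# all valid placement-start sets for n width-5 non-touching objects on I
# inputs (1-based starts), by direct filtering of all start combinations
enumerate_placements <- function(I, n) {
  if (n == 0) return(list(integer(0)))
  starts <- combn(I - 4L, n)
  keep <- apply(starts, 2, function(s) all(diff(s) >= 6L))
  lapply(which(keep), function(j) starts[, j])
}

# closed-form final weights after one all-positive epoch: each cluster of
# each learner gains one unit per assigned pattern that covers it
expected_weights_after_epoch <- function(network, pset) {
  cfg <- network$config
  lapply(network$minicolumns, function(mc) {
    idx <- which(pset$assigned_mc == mc$id)
    w5 <- numeric(nrow(mc$l5$tree$clusters))
    w23 <- if (!is.null(mc$l23)) numeric(nrow(mc$l23$tree$clusters))
    for (i in idx) {
      ext <- extend_activity(pset$patterns[[i]], network)
      for (k in seq_len(nrow(mc$l5$tree$clusters))) {
        if (sum(ext[mc$l5$tree$clusters[k, ]]) >= cfg$G) w5[k] <- w5[k] + 1
      }
      if (!is.null(mc$l23)) {
        a <- pset$patterns[[i]]$activity
        for (k in seq_len(nrow(mc$l23$tree$clusters))) {
          if (sum(a[mc$l23$tree$clusters[k, ]]) >= cfg$G) w23[k] <- w23[k] + 1
        }
      }
    }
    list(l5 = w5, l23 = w23)
  })
}
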