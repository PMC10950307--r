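# Basal-tree construction: random synaptic clusters over a weighted source
# space. Sources are encoded as integers: 1..I are the external inputs,
# I+1 and I+2 (when present) are the two layer-2/3 object detectors (the
# solid-bar "XXXXX" detector, then the gapped "XXOXX" detector).

#' Source pool for cluster sampling
#'
#' Describes the space a cluster's synapses are drawn from. Every external
#' input occupies one sampling slot; each detector input occupies
#' `detector_weight` slots (the layer-2/3-to-layer-5 connectivity factor F),
#' so a single draw lands on a detector with probability
#' 2F / (I + 2F) when both detectors are present.
#'
#' @param I Number of external inputs.
#' @param n_detectors Number of detector sources appended after the external
#'   inputs (0 or 2).
#' @param detector_weight Sampling slots per detector source (F >= 0; may be
#'   non-integer).
#' @return A `source_pool` object.
#' @export
source_pool <- function(I, n_detectors = 0, detector_weight = 0) {
  stopifnot(I >= 1, n_detectors %in% c(0L, 2L), detector_weight >= 0)
  structure(list(
    I = as.integer(I),
    n_detectors = as.integer(n_detectors),
    detector_weight = detector_weight,
    n_sources = as.integer(I + n_detectors),
    weights = c(rep(1, I), rep(detector_weight, n_detectors))
  ), class = "source_pool")
}

#' Source labels for a pool
#'
#' @param pool A [source_pool()].
#' @return Character vector: `ext<i>` for external inputs, `det_solid` /
#'   `det_gapped` for the two detectors.
#' @export
source_labels <- function(pool) {
  lab <- paste0("ext", seq_len(pool$I))
  if (pool$n_detectors == 2) lab <- c(lab, "det_solid", "det_gapped")
  lab
}

#' Sample one synaptic cluster
#'
#' Draws `C` distinct sources. Each draw picks a source with probability
#' proportional to its slot count; a draw that repeats a source already in
#' the cluster is rejected and redrawn, which is equivalent to successive
#' weighted sampling without replacement.
#'
#' @param pool A [source_pool()].
#' @param C Cluster size (number of synapses).
#' @return Integer vector of `C` distinct source ids; treat as a set.
#' @export
sample_cluster <- function(pool, C) {
  n_pos <- sum(pool$weights > 0)
  if (C > n_pos) {
    stop("cluster size ", C, " exceeds the ", n_pos,
         " distinct sources with positive sampling weight")
  }
  sample.int(pool$n_sources, C, replace = FALSE, prob = pool$weights)
}

#' Build a basal dendritic tree
#'
#' Fills a cell's basal tree with `floor(S_max / C)` independent random
#' clusters of size `C`, so the synapse count `C * n_clusters` never exceeds
#' the per-cell budget `S_max`. Clusters own disjoint physical synapses;
#' repeated source compositions across clusters are allowed. All weights
#' start at 0.
#'
#' @param pool A [source_pool()].
#' @param C Cluster size, typically 4, 5 or 6.
#' @param S_max Maximum number of basal synapses per cell.
#' @return A `basal_tree`: list with integer matrix `clusters`
#'   (n_clusters x C, rows are source-id sets), numeric `weights`
#'   (one per cluster, all 0), `C`, `n_sources`.
#' @export
build_basal_tree <- function(pool, C, S_max = 20000) {
  stopifnot(C >= 1, S_max >= C)
  n_cl <- S_max %/% C
  pos <- which(pool$weights > 0)
  if (C > length(pos)) {
    stop("cluster size ", C, " exceeds the ", length(pos),
         " distinct sources with positive sampling weight")
  }
  w <- pool$weights[pos]
  if (all(w == w[1])) {
    # equal weights: batch-draw rows with replacement and redraw rows that
    # contain a duplicate — for equal weights this whole-row rejection law
    # coincides with per-draw rejection (uniform over distinct C-subsets)
    mat <- matrix(pos[sample.int(length(pos), n_cl * C, replace = TRUE)],
                  nrow = n_cl, ncol = C)
    repeat {
      bad <- row_has_duplicate(mat)
      if (!any(bad)) break
      nb <- sum(bad)
      mat[bad, ] <- pos[sample.int(length(pos), nb * C, replace = TRUE)]
    }
  } else {
    mat <- t(vapply(seq_len(n_cl),
                    function(i) sample_cluster(pool, C),
                    integer(C)))
  }
  structure(list(
    clusters = mat,
    weights = numeric(n_cl),
    C = as.integer(C),
    n_sources = pool$n_sources
  ), class = "basal_tree")
}

# TRUE for rows of an integer matrix holding any repeated value (C small)
row_has_duplicate <- function(mat) {
  C <- ncol(mat)
  bad <- rep(FALSE, nrow(mat))
  for (a in seq_len(C - 1)) {
    for (b in seq(a + 1, C)) {
      bad <- bad | mat[, a] == mat[, b]
    }
  }
  bad
}

#' Number of synapses in a tree
#' @param tree A `basal_tree`.
#' @return Integer, `C * n_clusters`.
#' @export
n_synapses <- function(tree) tree$C * nrow(tree$clusters)

# 0/1 cluster-membership sparse matrix (n_clusters x n_sources); cached on
# the tree by callers that score repeatedly
cluster_membership <- function(tree) {
  n_cl <- nrow(tree$clusters)
  Matrix::sparseMatrix(
    i = rep(seq_len(n_cl), times = tree$C),
    j = as.vector(tree$clusters),
    x = 1,
    dims = c(n_cl, tree$n_sources)
  )
}

#' Tabular dump of a basal tree
#'
#' One row per cluster, for debugging and serialization: cluster index,
#' the sorted source list as a semicolon-joined string, and the weight.
#'
#' @param tree A `basal_tree`.
#' @param cell_id Optional id column recycled over rows.
#' @return A data.frame with columns `cell_id` (if given), `cluster`,
#'   `sources`, `weight`.
#' @export
tree_dump <- function(tree, cell_id = NULL) {
  src <- apply(tree$clusters, 1, function(r) paste(sort(r), collapse = ";"))
  out <- data.frame(
    cluster = seq_len(nrow(tree$clusters)),
    sources = src,
    weight = tree$weights,
    stringsAsFactors = FALSE
  )
  if (!is.null(cell_id)) out <- cbind(cell_id = cell_id, out)
  out
}
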