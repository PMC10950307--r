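# Experiment configuration and network construction.
#
# Two minicolumn configurations are supported:
#   hierarchical  — each minicolumn has one L5 learner whose basal tree may
#                   sample the two prewired L2/3 object detectors (solid and
#                   gapped) at connectivity factor F, alongside the external
#                   inputs. Detector output is a fixed function of the input
#                   pattern; the detectors themselves carry no plastic state.
#   internal_rep  — each minicolumn has one L5 learner plus one L2/3 learner
#                   with its own tree over the external inputs only; the two
#                   learn in parallel via apical cross-induction.

#' Experiment configuration
#'
#' Collects every free parameter of a simulation with validation.
#'
#' @param mode `"internal_rep"` or `"hierarchical"`.
#' @param I Number of external inputs.
#' @param n_mc Number of minicolumns.
#' @param C Synaptic cluster size (4, 5 or 6 in the standard experiments;
#'   any C >= 1 is accepted).
#' @param G Active synapses required to excite a cluster; defaults to `C`
#'   ("all synapses active") and must satisfy `G <= C`.
#' @param S_max Maximum basal synapses per learner cell.
#' @param F Layer-2/3-to-layer-5 connectivity factor: sampling slots per
#'   detector source relative to one slot per external input. Only
#'   meaningful in hierarchical mode; must be 0 in internal_rep mode.
#' @param n_objects Objects per generated pattern.
#' @param patterns_per_mc Patterns assigned to each minicolumn.
#' @param n_runs Independent repetitions for experiment sweeps.
#' @param seed Master seed for experiment sweeps.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(mode = c("internal_rep", "hierarchical"),
                              I = 100, n_mc = 10, C = 4, G = C,
                              S_max = 20000, F = 0, n_objects = 5,
                              patterns_per_mc = 10, n_runs = NULL,
                              seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(n_runs)) n_runs <- if (mode == "hierarchical") 50L else 10L
  stopifnot(I >= 1, n_mc >= 1, C >= 1, S_max >= C, F >= 0,
            n_objects >= 0, patterns_per_mc >= 1, n_runs >= 1)
  if (G > C) stop("G must not exceed the cluster size C")
  if (G < 1) stop("G must be at least 1")
  if (mode == "internal_rep" && F != 0) {
    stop("internal_rep mode has no detector sources; F must be 0")
  }
  if (n_objects > 0 &&
      OBJECT_WIDTH * n_objects + (n_objects - 1) > I) {
    stop("n_objects = ", n_objects, " does not fit on ", I, " inputs")
  }
  structure(list(mode = mode, I = as.integer(I), n_mc = as.integer(n_mc),
                 C = as.integer(C), G = as.integer(G),
                 S_max = as.integer(S_max), F = as.numeric(F),
                 n_objects = as.integer(n_objects),
                 patterns_per_mc = as.integer(patterns_per_mc),
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [experiment_config()]; `overrides` (e.g.
#' parsed CLI flags) take precedence over file values.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return An `experiment_config`.
#' @export
read_config <- function(path, overrides = list()) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(experiment_config, vals)
}

new_cell <- function(layer, tree) {
  structure(list(layer = layer, tree = tree,
                 membership = cluster_membership(tree)),
            class = "learner_cell")
}

#' Build a network of minicolumns with fresh random trees
#'
#' Uses the current RNG state; set a seed beforehand for reproducibility.
#' In hierarchical mode each L5 tree samples external inputs plus the two
#' detectors at factor `config$F`; in internal-representation mode each
#' minicolumn additionally gets an independent L2/3 learner tree over the
#' external inputs only.
#'
#' @param config An [experiment_config()].
#' @return A `pc_network`: list with the config and `minicolumns`, each a
#'   list `(id, l5, l23)` of learner cells (`l23` is NULL in hierarchical
#'   mode, where the detectors are pure functions of the pattern).
#' @export
build_network <- function(config) {
  l5_pool <- if (config$mode == "hierarchical") {
    source_pool(config$I, n_detectors = 2, detector_weight = config$F)
  } else {
    source_pool(config$I)
  }
  ext_pool <- source_pool(config$I)
  minicolumns <- lapply(seq_len(config$n_mc), function(id) {
    l5 <- new_cell("L5", build_basal_tree(l5_pool, config$C, config$S_max))
    l23 <- if (config$mode == "internal_rep") {
      new_cell("L23", build_basal_tree(ext_pool, config$C, config$S_max))
    }
    list(id = id, l5 = l5, l23 = l23)
  })
  structure(list(config = config, minicolumns = minicolumns),
            class = "pc_network")
}

#' @export
print.pc_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<pc_network> %s mode: %d minicolumns, I=%d, C=%d, G=%d, S_max=%d%s\n",
              cfg$mode, cfg$n_mc, cfg$I, cfg$C, cfg$G, cfg$S_max,
              if (cfg$mode == "hierarchical") sprintf(", F=%g", cfg$F) else ""))
  tw <- sum(vapply(x$minicolumns, function(mc) {
    sum(mc$l5$tree$weights) + if (!is.null(mc$l23)) sum(mc$l23$tree$weights) else 0
  }, numeric(1)))
  cat(sprintf("  total accumulated weight: %g\n", tw))
  invisible(x)
}

#' Extend a pattern's activity over a cell's full source space
#'
#' External sources copy the pattern's activity; in hierarchical mode the
#' two detector sources take the value of [detect_object()] for their object
#' type (solid then gapped). Internal-representation cells see only the
#' external inputs.
#'
#' @param pattern An `input_pattern`.
#' @param network A `pc_network` (its mode decides whether detector slots
#'   exist).
#' @return Logical vector over source ids (length I, or I + 2 in
#'   hierarchical mode).
#' @export
extend_activity <- function(pattern, network) {
  a <- pattern$activity
  if (network$config$mode == "hierarchical") {
    a <- c(a, detect_object(pattern, "XXXXX"), detect_object(pattern, "XXOXX"))
  }
  a
}

#' Dump every tree in a network
#'
#' @param network A `pc_network`.
#' @return A data.frame (see [tree_dump()]) with one row per cluster over
#'   all learner cells; `cell_id` is `"mc<k>/L5"` or `"mc<k>/L23"`.
#' @export
network_dump <- function(network) {
  out <- lapply(network$minicolumns, function(mc) {
    d <- tree_dump(mc$l5$tree, cell_id = sprintf("mc%d/L5", mc$id))
    if (!is.null(mc$l23)) {
      d <- rbind(d, tree_dump(mc$l23$tree, cell_id = sprintf("mc%d/L23", mc$id)))
    }
    d
  })
  do.call(rbind, out)
}
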