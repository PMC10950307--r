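# Experiment orchestration: seeded sweeps over the two minicolumn
# configurations, run-level result tables and grouped summaries.
#
# Every source of randomness flows from one master seed through
# seed_ladder(): each (experiment cell, run, purpose) gets its own derived
# seed, so trees, patterns and tie-breaks are independently reproducible
# and the pattern purpose can be held fixed across sweep cells (paired
# comparisons across connectivity factors F reuse identical pattern sets).

#' Derive a deterministic seed from a master seed and labels
#'
#' A 31-multiplier polynomial string hash over the labels, folded into the
#' master seed modulo 2^31 - 1 (kept in 32-bit integer range).
#'
#' @param master_seed Integer master seed.
#' @param ... Labels (coerced to character) identifying the experiment
#'   cell, run index and purpose, e.g. `"internal", 4, 5, run, "trees"`.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
seed_ladder <- function(master_seed, ...) {
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(master_seed) %% m
  for (lab in as.character(unlist(list(...)))) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 31 + code) %% m
    }
    h <- (h * 31 + 7) %% m  # label separator
  }
  as.integer(h %% (m - 1) + 1)
}

run_once <- function(config, tree_seed, pattern_seed, tie_seed) {
  set.seed(pattern_seed)
  pset <- make_pattern_set(config)
  set.seed(tree_seed)
  network <- build_network(config)
  network <- train(network, pset)
  set.seed(tie_seed)
  evaluate(network, pset)
}

#' Internal-representation minicolumn experiment
#'
#' For each objects-per-pattern value and each run: fresh L5 and L2/3
#' trees (no detector sources), a fresh set of `n_mc * patterns_per_mc`
#' distinct solid-object patterns, one all-positive training epoch with
#' cross-induction firing both layers, then winner-take-all testing per
#' layer. Records L5, L2/3 and simultaneous accuracy per run.
#'
#' @param cluster_size Synaptic cluster size C (4, 5 or 6).
#' @param n_objects_grid Objects-per-pattern values to sweep.
#' @param n_runs Independent runs per grid value.
#' @param seed Master seed.
#' @param I,n_mc,patterns_per_mc,S_max Passed to [experiment_config()].
#' @param out_csv,summary_csv Optional paths; run rows are appended as they
#'   complete, the summary is written at the end.
#' @param verbose Emit one message per completed run.
#' @return List with data.frames `runs` (mode, C, n_objects, run, seed,
#'   accuracy_l5, accuracy_l23, accuracy_simultaneous) and `summary`
#'   (per n_objects: mean/sd/sem of each accuracy, n_runs).
#' @export
run_internal_rep_experiment <- function(cluster_size = 4,
                                        n_objects_grid = 5,
                                        n_runs = 10,
                                        seed = 1,
                                        I = 100, n_mc = 10,
                                        patterns_per_mc = 10,
                                        S_max = 20000,
                                        out_csv = NULL, summary_csv = NULL,
                                        verbose = FALSE) {
  rows <- vector("list", length(n_objects_grid) * n_runs)
  k <- 0
  for (nobj in n_objects_grid) {
    config <- experiment_config("internal_rep", I = I, n_mc = n_mc,
                                C = cluster_size, n_objects = nobj,
                                patterns_per_mc = patterns_per_mc,
                                S_max = S_max, n_runs = n_runs, seed = seed)
    for (run in seq_len(n_runs)) {
      cell <- c("internal", cluster_size, nobj, run)
      t0 <- proc.time()[["elapsed"]]
      ev <- run_once(config,
                     tree_seed = seed_ladder(seed, cell, "trees"),
                     pattern_seed = seed_ladder(seed, cell, "patterns"),
                     tie_seed = seed_ladder(seed, cell, "ties"))
      k <- k + 1
      rows[[k]] <- data.frame(
        mode = "internal_rep", C = cluster_size, n_objects = nobj,
        run = run, seed = seed,
        accuracy_l5 = ev$accuracy$l5,
        accuracy_l23 = ev$accuracy$l23,
        accuracy_simultaneous = ev$accuracy$simultaneous
      )
      append_csv(rows[[k]], out_csv, first = k == 1)
      if (verbose) {
        message(sprintf(
          "internal_rep C=%d n_objects=%d run %d/%d: L5 %.3f L2/3 %.3f simultaneous %.3f (%.1fs)",
          cluster_size, nobj, run, n_runs, ev$accuracy$l5, ev$accuracy$l23,
          ev$accuracy$simultaneous, proc.time()[["elapsed"]] - t0))
      }
    }
  }
  runs <- do.call(rbind, rows)
  summary <- summarize_runs(runs, "n_objects",
                            c("accuracy_l5", "accuracy_l23",
                              "accuracy_simultaneous"))
  if (!is.null(summary_csv)) utils::write.csv(summary, summary_csv,
                                              row.names = FALSE)
  list(runs = runs, summary = summary)
}

#' Hierarchical-connectivity minicolumn experiment
#'
#' Sweeps the layer-2/3-to-layer-5 connectivity factor F. For each F and
#' each run: fresh L5 trees sampling the two prewired object detectors at
#' factor F, a fresh paired pattern set (half solid patterns, half gapped
#' location-twins assigned to different minicolumns), one all-positive
#' training epoch, winner-take-all testing of L5. The pattern seed depends
#' on the run index but not on F, so pattern sets are identical across F
#' values and F comparisons are paired.
#'
#' @param cluster_size Synaptic cluster size C.
#' @param f_grid Connectivity factors to sweep (include 0 for the
#'   no-connectivity baseline).
#' @param n_runs Independent runs per F.
#' @param n_objects Objects per pattern.
#' @param seed Master seed.
#' @param I,n_mc,patterns_per_mc,S_max Passed to [experiment_config()].
#' @param out_csv,summary_csv Optional incremental/summary CSV paths.
#' @param verbose Emit one message per completed run.
#' @return List with data.frames `runs` (mode, C, F, run, seed,
#'   accuracy_l5) and `summary` (per F: mean/sd/sem, n_runs).
#' @export
run_hierarchical_experiment <- function(cluster_size = 4,
                                        f_grid = c(0, 1, 2, 5, 10, 20, 50, 100),
                                        n_runs = 50,
                                        n_objects = 5,
                                        seed = 1,
                                        I = 100, n_mc = 10,
                                        patterns_per_mc = 10,
                                        S_max = 20000,
                                        out_csv = NULL, summary_csv = NULL,
                                        verbose = FALSE) {
  rows <- vector("list", length(f_grid) * n_runs)
  k <- 0
  for (F in f_grid) {
    config <- experiment_config("hierarchical", I = I, n_mc = n_mc,
                                C = cluster_size, F = F,
                                n_objects = n_objects,
                                patterns_per_mc = patterns_per_mc,
                                S_max = S_max, n_runs = n_runs, seed = seed)
    for (run in seq_len(n_runs)) {
      t0 <- proc.time()[["elapsed"]]
      ev <- run_once(
        config,
        tree_seed = seed_ladder(seed, "hier", cluster_size, F, run, "trees"),
        # no F in the pattern labels: paired pattern sets across the F grid
        pattern_seed = seed_ladder(seed, "hier", cluster_size, run, "patterns"),
        tie_seed = seed_ladder(seed, "hier", cluster_size, F, run, "ties"))
      k <- k + 1
      rows[[k]] <- data.frame(
        mode = "hierarchical", C = cluster_size, F = F, run = run,
        seed = seed, accuracy_l5 = ev$accuracy$l5
      )
      append_csv(rows[[k]], out_csv, first = k == 1)
      if (verbose) {
        message(sprintf("hierarchical C=%d F=%g run %d/%d: L5 %.3f (%.1fs)",
                        cluster_size, F, run, n_runs, ev$accuracy$l5,
                        proc.time()[["elapsed"]] - t0))
      }
    }
  }
  runs <- do.call(rbind, rows)
  summary <- summarize_runs(runs, "F", "accuracy_l5")
  if (!is.null(summary_csv)) utils::write.csv(summary, summary_csv,
                                              row.names = FALSE)
  list(runs = runs, summary = summary)
}

#' Summarise a run table
#'
#' Arithmetic mean, standard deviation and standard error
#' (sd / sqrt(n_runs)) of each accuracy column, grouped by a key column.
#'
#' @param runs A run data.frame.
#' @param group_col Grouping column name (`"n_objects"` or `"F"`).
#' @param acc_cols Accuracy column names present in `runs`.
#' @return A summary data.frame, one row per group value.
#' @export
summarize_runs <- function(runs, group_col, acc_cols) {
  acc_cols <- intersect(acc_cols, names(runs))
  groups <- unique(runs[[group_col]])
  out <- lapply(groups, function(g) {
    sub <- runs[runs[[group_col]] == g, , drop = FALSE]
    row <- data.frame(mode = sub$mode[1], C = sub$C[1])
    row[[group_col]] <- g
    for (col in acc_cols) {
      x <- sub[[col]]
      row[[paste0(col, "_mean")]] <- mean(x)
      row[[paste0(col, "_sd")]] <- stats::sd(x)
      row[[paste0(col, "_sem")]] <- stats::sd(x) / sqrt(length(x))
    }
    row$n_runs <- nrow(sub)
    row
  })
  do.call(rbind, out)
}

append_csv <- function(row, path, first) {
  if (is.null(path)) return(invisible())
  utils::write.table(row, path, sep = ",", row.names = FALSE,
                     col.names = first, append = !first)
}
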