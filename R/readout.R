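# Memory readout: per-cell response scores and winner-take-all
# classification across minicolumns. Testing is read-only — no weight
# changes.

#' Response score of one learner cell
#'
#' The summed weight of the cell's excited clusters (those with at least
#' `G` active sources) under an activity map.
#'
#' @param cell A `learner_cell` (a minicolumn's `$l5` or `$l23`).
#' @param activity Logical activity vector over the cell's source space.
#' @param G Active-source threshold; defaults to the tree's cluster size.
#' @return Numeric score (an integer count under the default +1 rule).
#' @export
pc_response <- function(cell, activity, G = cell$tree$C) {
  sum(cell$tree$weights[tree_eligibility(cell, activity, G)])
}

#' Winner-take-all over scores
#'
#' Index of the maximum score; ties are broken uniformly at random among
#' the tied set. A random draw is consumed from the current RNG stream
#' only when two or more scores tie at the maximum.
#'
#' @param scores Non-empty numeric vector.
#' @return Integer index of the single firing unit.
#' @export
winner_take_all <- function(scores) {
  if (length(scores) == 0) stop("winner_take_all needs at least one score")
  idx <- which(scores == max(scores))
  if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)]
}

#' Test a trained network on its pattern set
#'
#' Presents every pattern once. For each pattern the L5 score of every
#' minicolumn is computed under the extended activity and the minicolumn
#' with the largest score fires (winner-take-all, random tie-break). In
#' internal-representation mode the L2/3 learners run an independent
#' winner-take-all of their own, and a pattern is simultaneously correct
#' iff both layer winners equal the assigned minicolumn. Tie-break draws
#' are consumed in pattern order, L5 before L2/3. Evaluation never
#' modifies weights.
#'
#' @param network A trained `pc_network`.
#' @param pset The `pattern_set` it was trained on.
#' @return An `evaluation`: list with data.frame `outcomes` (per pattern:
#'   `pattern_id`, `assigned_mc`, `winner_l5`, `margin_l5`, `correct_l5`,
#'   and in internal-representation mode `winner_l23`, `margin_l23`,
#'   `correct_l23`, `correct_simultaneous`) and list `accuracy`
#'   (`l5`, and when defined `l23`, `simultaneous`).
#' @export
evaluate <- function(network, pset) {
  cfg <- network$config
  n_pat <- length(pset$patterns)
  n_mc <- cfg$n_mc
  internal <- cfg$mode == "internal_rep"

  # score matrices (n_mc x n_pat), one sparse product per cell
  ext <- vapply(pset$patterns, function(p) extend_activity(p, network),
                logical(if (cfg$mode == "hierarchical") cfg$I + 2L else cfg$I))
  scores_l5 <- t(vapply(network$minicolumns, function(mc) {
    counts <- as.matrix(mc$l5$membership %*% ext)
    as.numeric(crossprod(counts >= cfg$G, mc$l5$tree$weights))
  }, numeric(n_pat)))
  if (internal) {
    ext23 <- vapply(pset$patterns, function(p) p$activity, logical(cfg$I))
    scores_l23 <- t(vapply(network$minicolumns, function(mc) {
      counts <- as.matrix(mc$l23$membership %*% ext23)
      as.numeric(crossprod(counts >= cfg$G, mc$l23$tree$weights))
    }, numeric(n_pat)))
  }

  winner_l5 <- integer(n_pat); margin_l5 <- numeric(n_pat)
  winner_l23 <- integer(n_pat); margin_l23 <- numeric(n_pat)
  for (i in seq_len(n_pat)) {
    winner_l5[i] <- winner_take_all(scores_l5[, i])
    margin_l5[i] <- score_margin(scores_l5[, i])
    if (internal) {
      winner_l23[i] <- winner_take_all(scores_l23[, i])
      margin_l23[i] <- score_margin(scores_l23[, i])
    }
  }

  outcomes <- data.frame(
    pattern_id = seq_len(n_pat),
    assigned_mc = pset$assigned_mc,
    winner_l5 = winner_l5,
    margin_l5 = margin_l5,
    correct_l5 = winner_l5 == pset$assigned_mc
  )
  accuracy <- list(l5 = mean(outcomes$correct_l5))
  if (internal) {
    outcomes$winner_l23 <- winner_l23
    outcomes$margin_l23 <- margin_l23
    outcomes$correct_l23 <- winner_l23 == pset$assigned_mc
    outcomes$correct_simultaneous <- outcomes$correct_l5 & outcomes$correct_l23
    accuracy$l23 <- mean(outcomes$correct_l23)
    accuracy$simultaneous <- mean(outcomes$correct_simultaneous)
  }
  structure(list(outcomes = outcomes, accuracy = accuracy),
            class = "evaluation")
}

# top score minus runner-up (0 when tied or a single unit)
score_margin <- function(scores) {
  if (length(scores) < 2) return(0)
  s <- sort(scores, decreasing = TRUE)
  s[1] - s[2]
}

#' @export
print.evaluation <- function(x, ...) {
  cat(sprintf("<evaluation> %d patterns: L5 accuracy %.3f",
              nrow(x$outcomes), x$accuracy$l5))
  if (!is.null(x$accuracy$simultaneous)) {
    cat(sprintf(", L2/3 %.3f, simultaneous %.3f",
                x$accuracy$l23, x$accuracy$simultaneous))
  }
  cat("\n")
  invisible(x)
}

#' Write per-pattern outcomes to CSV
#'
#' @param evaluation An `evaluation`.
#' @param path Output CSV path.
#' @param run Optional run index prepended as a column.
#' @export
write_outcomes_csv <- function(evaluation, path, run = NULL) {
  out <- evaluation$outcomes
  if (!is.null(run)) out <- cbind(run = run, out)
  utils::write.csv(out, path, row.names = FALSE)
}
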