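# Worked concept-extraction demo: a single cell with all two-synapse
# clusters over a handful of inputs, trial-fired on every presentation,
# learning under the reset-on-punishment rule. After a short sequence of
# rewarded and punished presentations, the clusters left enhanced encode
# the abstract input combination that predicts reward — e.g. "inputs 2 and
# 3 jointly active", even when no presented object ever showed only those
# two inputs.

#' Replay a concept-extraction training sequence
#'
#' The cell carries one binary-strength cluster for every unordered pair of
#' the `n_inputs` inputs (choose(n_inputs, 2) clusters). Each step presents
#' an active-input set with the cell trial-fired; clusters with both
#' sources active are eligible. A positive (or insignificant) reward
#' enhances an eligible cluster; a negative reward removes its enhancement
#' if present.
#'
#' @param steps List of steps, each a list with `active` (integer vector of
#'   active inputs, values in `1:n_inputs`) and `reward` (`"positive"`,
#'   `"insignificant"` or `"negative"`).
#' @param n_inputs Number of inputs (default 4).
#' @return A `concept_demo` object: list with `pairs` (2-column matrix of
#'   all clusters), `enhanced` (2-column matrix of the finally enhanced
#'   pairs), and `history` (list of per-step enhancement states).
#' @examples
#' # a rule-then-exceptions sequence distilling "2 and 3 jointly active"
#' steps <- list(
#'   list(active = c(2, 3, 4), reward = "positive"),
#'   list(active = c(2, 4), reward = "negative"),
#'   list(active = c(3, 4), reward = "negative")
#' )
#' run_concept_demo(steps)$enhanced   # the single pair (2, 3)
#' @export
run_concept_demo <- function(steps, n_inputs = 4) {
  stopifnot(n_inputs >= 2)
  pairs <- t(utils::combn(n_inputs, 2))
  weights <- numeric(nrow(pairs))
  rule <- plasticity_rule(weakening_mode = "reset_to_zero")
  history <- vector("list", length(steps))
  for (s in seq_along(steps)) {
    step <- steps[[s]]
    active <- as.integer(step$active)
    if (length(active) &&
        (any(active < 1) || any(active > n_inputs))) {
      stop("active inputs must lie in 1..", n_inputs)
    }
    act <- rep(FALSE, n_inputs)
    act[active] <- TRUE
    eligible <- act[pairs[, 1]] & act[pairs[, 2]]
    weights <- apply_reward_rule(weights, eligible, reward_signal(step$reward),
                                 rule)
    # binary enhancement: any accumulated strength counts as enhanced
    weights <- as.numeric(weights > 0)
    history[[s]] <- weights > 0
  }
  structure(list(pairs = pairs,
                 enhanced = pairs[weights > 0, , drop = FALSE],
                 history = history,
                 steps = steps,
                 n_inputs = n_inputs),
            class = "concept_demo")
}

#' @export
print.concept_demo <- function(x, ...) {
  for (s in seq_along(x$history)) {
    step <- x$steps[[s]]
    cat(sprintf("step %d: active {%s}, reward %s\n", s,
                paste(step$active, collapse = ","), step$reward))
    print_pair_grid(x$pairs, x$history[[s]], x$n_inputs)
  }
  enh <- apply(x$enhanced, 1, paste, collapse = ",")
  cat("enhanced pairs:",
      if (length(enh)) paste0("(", enh, ")", collapse = " ") else "none", "\n")
  invisible(x)
}

# upper-triangle text grid of pair enhancement states
print_pair_grid <- function(pairs, enhanced, n_inputs) {
  cat("   ", paste(sprintf("%2d", seq_len(n_inputs)), collapse = " "), "\n")
  for (i in seq_len(n_inputs - 1)) {
    row <- vapply(seq_len(n_inputs), function(j) {
      if (j <= i) return("  ")
      k <- which(pairs[, 1] == i & pairs[, 2] == j)
      if (enhanced[k]) " #" else " ."
    }, character(1))
    cat(sprintf("%2d ", i), paste(row, collapse = " "), "\n")
  }
}
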