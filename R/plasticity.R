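# The reward-gated cluster plasticity rule.
#
# A cluster is eligible for plasticity in an episode when it is excited
# (enough of its sources coincidently active) while its cell fires via the
# apical selection input. The accompanying reward then decides the sign:
# positive or insignificant rewards enhance the cluster's weight, negative
# rewards (punishments) weaken it. The behavioural-timescale eligibility
# window collapses to same-episode coincidence here because patterns are
# static within an episode.

#' Reward signal
#'
#' @param sign `"positive"`, `"insignificant"` or `"negative"`.
#' @param magnitude Non-negative reward size; forced to 0 for
#'   `"insignificant"`. Defaults to 1, the value used throughout the
#'   standard experiments.
#' @return A `reward_signal`.
#' @export
reward_signal <- function(sign = c("positive", "insignificant", "negative"),
                          magnitude = 1) {
  sign <- match.arg(sign)
  stopifnot(magnitude >= 0)
  if (sign == "insignificant") magnitude <- 0
  structure(list(sign = sign, magnitude = magnitude), class = "reward_signal")
}

#' Plasticity rule parameters
#'
#' @param potentiation_increment Weight gain per unit reward magnitude for
#'   an eligible cluster under positive reward (and the flat gain under an
#'   insignificant reward).
#' @param weakening_mode `"reset_to_zero"` (an eligible cluster's
#'   enhancement is removed outright on punishment) or `"decrement"`
#'   (graded weakening by `decrement_step * magnitude`, floored at 0).
#' @param decrement_step Step size for `"decrement"` mode.
#' @return A `plasticity_rule`.
#' @export
plasticity_rule <- function(potentiation_increment = 1,
                            weakening_mode = c("reset_to_zero", "decrement"),
                            decrement_step = 1) {
  weakening_mode <- match.arg(weakening_mode)
  stopifnot(potentiation_increment > 0, decrement_step > 0)
  structure(list(potentiation_increment = potentiation_increment,
                 weakening_mode = weakening_mode,
                 decrement_step = decrement_step),
            class = "plasticity_rule")
}

#' Is a cluster excited under an activity map?
#'
#' @param sources Integer vector of the cluster's source ids.
#' @param activity Logical activity vector over all source ids (see
#'   [extend_activity()]).
#' @param G Number of active sources required; `G = length(sources)` is
#'   "all synapses active".
#' @return Logical scalar.
#' @export
cluster_active <- function(sources, activity, G = length(sources)) {
  if (any(sources < 1 | sources > length(activity))) {
    stop("cluster references a source outside the activity map")
  }
  sum(activity[sources]) >= G
}

# eligibility of every cluster of a tree at once (sparse count >= G)
tree_eligibility <- function(cell, activity, G) {
  counts <- as.numeric(cell$membership %*% activity)
  counts >= G
}

#' Apply the reward rule to cluster weights
#'
#' Vectorised over `weight` and `eligible`. Eligible clusters gain
#' `potentiation_increment * magnitude` under a positive reward and
#' `potentiation_increment` under an insignificant one (zero reward still
#' teaches: absence of punishment is treated as an acceptable outcome);
#' under a negative reward they are reset to 0 or decremented, by mode.
#' Ineligible clusters never change. Weights stay non-negative.
#'
#' @param weight Numeric vector of current weights (all >= 0).
#' @param eligible Logical vector: cluster excited while its cell fired.
#' @param reward A [reward_signal()].
#' @param rule A [plasticity_rule()].
#' @return Updated weight vector.
#' @export
apply_reward_rule <- function(weight, eligible, reward,
                              rule = plasticity_rule()) {
  if (any(weight < 0)) stop("weights must be non-negative")
  out <- weight
  if (reward$sign %in% c("positive", "insignificant")) {
    mag <- if (reward$sign == "insignificant") 1 else reward$magnitude
    out[eligible] <- out[eligible] + rule$potentiation_increment * mag
  } else {
    if (rule$weakening_mode == "reset_to_zero") {
      out[eligible] <- 0
    } else {
      out[eligible] <- pmax(0, out[eligible] -
                              rule$decrement_step * reward$magnitude)
    }
  }
  out
}

#' One training episode
#'
#' Presents a pattern with a set of apically fired cells and a reward:
#' every cluster of every fired learner is updated by [apply_reward_rule()]
#' with eligibility taken from that cell's extended activity. Non-fired
#' cells are untouched.
#'
#' @param network A `pc_network`.
#' @param pattern An `input_pattern`.
#' @param fired_mc Minicolumn id whose cells fire this episode.
#' @param reward A [reward_signal()].
#' @param rule A [plasticity_rule()].
#' @param cross_induction Fire the minicolumn's co-bundled L2/3 learner
#'   along with its L5 (internal-representation mode). Ignored when the
#'   minicolumn has no L2/3 learner.
#' @return The updated network.
#' @export
training_episode <- function(network, pattern, fired_mc,
                             reward = reward_signal("positive"),
                             rule = plasticity_rule(),
                             cross_induction = TRUE) {
  mc <- network$minicolumns[[fired_mc]]
  ext <- extend_activity(pattern, network)
  G <- network$config$G
  elig <- tree_eligibility(mc$l5, ext, G)
  mc$l5$tree$weights <- apply_reward_rule(mc$l5$tree$weights, elig, reward, rule)
  if (cross_induction && !is.null(mc$l23)) {
    a_ext <- pattern$activity  # L2/3 learners see external inputs only
    elig23 <- tree_eligibility(mc$l23, a_ext, G)
    mc$l23$tree$weights <- apply_reward_rule(mc$l23$tree$weights, elig23,
                                             reward, rule)
  }
  network$minicolumns[[fired_mc]] <- mc
  network
}

#' Train a network on an assigned pattern set
#'
#' One episode per pattern, in order: the pattern's assigned minicolumn is
#' fired apically (its L5 learner, plus its L2/3 learner through apical
#' cross-induction when present) and the scheduled reward is delivered.
#' Under the default all-positive schedule the final weights are invariant
#' to the presentation order.
#'
#' @param network A `pc_network`.
#' @param pset A `pattern_set` from [make_pattern_set()].
#' @param rule A [plasticity_rule()].
#' @param rewards A single [reward_signal()] applied to every episode, or a
#'   list of one signal per pattern.
#' @return The trained network.
#' @export
train <- function(network, pset, rule = plasticity_rule(),
                  rewards = reward_signal("positive")) {
  n_pat <- length(pset$patterns)
  if (inherits(rewards, "reward_signal")) {
    rewards <- rep(list(rewards), n_pat)
  }
  stopifnot(length(rewards) == n_pat)
  for (i in seq_len(n_pat)) {
    network <- training_episode(network, pset$patterns[[i]],
                                pset$assigned_mc[i], rewards[[i]], rule)
  }
  network
}
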