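test_that("the reward rule potentiates, resets and leaves weights alone correctly", {
  rule <- plasticity_rule()
  # unit potentiation of an eligible cluster
  expect_identical(apply_reward_rule(0, TRUE, reward_signal("positive"), rule), 1)
  # punishment removes accumulated enhancement outright in reset mode
  expect_identical(apply_reward_rule(3, TRUE, reward_signal("negative"), rule), 0)
  # no coincidence, no change
  expect_identical(apply_reward_rule(5, FALSE, reward_signal("negative"), rule), 5)
  expect_identical(apply_reward_rule(5, FALSE, reward_signal("positive"), rule), 5)
  # graded weakening floors at zero
  dec <- plasticity_rule(weakening_mode = "decrement", decrement_step = 2)
  expect_identical(apply_reward_rule(3, TRUE, reward_signal("negative", 1), dec), 1)
  expect_identical(apply_reward_rule(1, TRUE, reward_signal("negative", 5), dec), 0)
  # magnitude scales potentiation linearly
  expect_identical(apply_reward_rule(0, TRUE, reward_signal("positive", 3), rule), 3)
  # vectorised over clusters
  expect_identical(
    apply_reward_rule(c(0, 2, 4), c(TRUE, FALSE, TRUE),
                      reward_signal("positive"), rule),
    c(1, 2, 5))
  expect_error(apply_reward_rule(-1, TRUE, reward_signal("positive"), rule),
               "non-negative")
})

test_that("an insignificant reward teaches like a unit positive reward", {
  rule <- plasticity_rule()
  w <- c(0, 1, 7)
  e <- c(TRUE, TRUE, FALSE)
  expect_identical(apply_reward_rule(w, e, reward_signal("insignificant"), rule),
                   apply_reward_rule(w, e, reward_signal("positive", 1), rule))
})

test_that("cluster excitation thresholds count active sources", {
  act <- rep(FALSE, 10); act[3:7] <- TRUE
  expect_true(cluster_active(c(3, 4, 5, 6), act, G = 4))
  act5off <- act; act5off[5] <- FALSE
  expect_false(cluster_active(c(3, 4, 5, 6), act5off, G = 4))
  expect_true(cluster_active(c(3, 4, 5, 6), act5off, G = 3))
  expect_error(cluster_active(c(3, 11), act, G = 1), "outside")
})

test_that("extended activity maps detectors from the pattern content", {
  set.seed(7)
  cfg_h <- experiment_config("hierarchical", F = 1, n_objects = 2)
  net_h <- build_network(cfg_h)
  solid <- place_objects(100, "XXXXX", 2)
  ext <- extend_activity(solid, net_h)
  expect_length(ext, 102)
  expect_identical(ext[101], TRUE)    # solid detector
  expect_identical(ext[102], FALSE)   # gapped detector
  zero <- place_objects(100, "XXXXX", 0)
  expect_false(any(extend_activity(zero, net_h)))
  cfg_i <- experiment_config("internal_rep", n_objects = 2)
  net_i <- build_network(cfg_i)
  expect_length(extend_activity(solid, net_i), 100)
})

test_that("a training episode updates exactly the fired cell's covered clusters", {
  set.seed(13)
  # small clusters and a strong detector weight so that some clusters land
  # entirely inside the active source set
  cfg <- experiment_config("hierarchical", C = 2, F = 50, n_objects = 1,
                           S_max = 2000)
  net <- build_network(cfg)
  pat <- structure(list(
    activity = c(rep(TRUE, 5), rep(FALSE, 95)),
    placements = data.frame(object_type = "XXXXX", start = 1L,
                            stringsAsFactors = FALSE)
  ), class = "input_pattern")
  net2 <- training_episode(net, pat, fired_mc = 3,
                           reward = reward_signal("positive"))
  # brute force: clusters whose sources lie in {ext 1..5, solid detector}
  covered <- c(1:5, 101)
  for (k in seq_len(cfg$n_mc)) {
    w_before <- net$minicolumns[[k]]$l5$tree$weights
    w_after <- net2$minicolumns[[k]]$l5$tree$weights
    if (k == 3) {
      exp_delta <- as.numeric(apply(net$minicolumns[[k]]$l5$tree$clusters, 1,
                                    function(s) all(s %in% covered)))
      expect_identical(w_after - w_before, exp_delta)
      expect_gt(sum(exp_delta), 0)  # the example is non-degenerate
    } else {
      expect_identical(w_after, w_before)
    }
  }
  # an all-zero pattern changes nothing anywhere
  zero <- place_objects(100, "XXXXX", 0)
  net3 <- training_episode(net, zero, fired_mc = 3)
  expect_identical(net3, net)
})

test_that("one positive epoch matches the closed-form coverage-count oracle", {
  set.seed(19)
  cfg <- experiment_config("internal_rep", n_objects = 5, S_max = 2000)
  pset <- make_pattern_set(cfg)
  net <- build_network(cfg)
  trained <- train(net, pset)
  expected <- expected_weights_after_epoch(net, pset)
  for (k in seq_len(cfg$n_mc)) {
    expect_identical(trained$minicolumns[[k]]$l5$tree$weights,
                     expected[[k]]$l5)
    expect_identical(trained$minicolumns[[k]]$l23$tree$weights,
                     expected[[k]]$l23)
  }
  # cross-induction: both layers of a minicolumn learn from exactly the
  # episodes assigned to it, so total added weight is positive in both
  # layers wherever any cluster was covered
  expect_gt(sum(trained$minicolumns[[1]]$l23$tree$weights), 0)
})

test_that("final weights are order-invariant under an all-positive schedule", {
  set.seed(29)
  cfg <- experiment_config("internal_rep", n_objects = 5, S_max = 1000)
  pset <- make_pattern_set(cfg)
  net <- build_network(cfg)
  trained <- train(net, pset)
  for (perm_i in 1:3) {
    perm <- sample(length(pset$patterns))
    pset_perm <- pset
    pset_perm$patterns <- pset$patterns[perm]
    pset_perm$assigned_mc <- pset$assigned_mc[perm]
    trained_perm <- train(net, pset_perm)
    expect_identical(trained_perm$minicolumns, trained$minicolumns)
  }
  # additivity: a second identical epoch doubles every weight delta
  twice <- train(trained, pset)
  for (k in seq_len(cfg$n_mc)) {
    expect_identical(twice$minicolumns[[k]]$l5$tree$weights,
                     2 * trained$minicolumns[[k]]$l5$tree$weights)
  }
})

test_that("weights never go negative and grow monotonically under positive rewards", {
  set.seed(37)
  cfg <- experiment_config("internal_rep", n_objects = 5, S_max = 1000)
  pset <- make_pattern_set(cfg)
  net <- build_network(cfg)
  prev <- net
  for (i in seq_along(pset$patterns)) {
    cur <- training_episode(prev, pset$patterns[[i]], pset$assigned_mc[i])
    for (k in seq_len(cfg$n_mc)) {
      expect_true(all(cur$minicolumns[[k]]$l5$tree$weights >=
                        prev$minicolumns[[k]]$l5$tree$weights))
      expect_true(all(cur$minicolumns[[k]]$l5$tree$weights >= 0))
    }
    prev <- cur
  }
  # mixed schedule still keeps weights non-negative
  rewards <- lapply(seq_along(pset$patterns), function(i) {
    reward_signal(sample(c("positive", "negative", "insignificant"), 1))
  })
  mixed <- train(net, pset, rewards = rewards)
  for (k in seq_len(cfg$n_mc)) {
    expect_true(all(mixed$minicolumns[[k]]$l5$tree$weights >= 0))
    expect_true(all(mixed$minicolumns[[k]]$l23$tree$weights >= 0))
  }
})
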