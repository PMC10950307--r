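test_that("placed objects respect footprint, count and spacing", {
  set.seed(2)
  for (rep in 1:20) {
    p <- place_objects(100, "XXXXX", 5)
    expect_identical(sum(p$activity), 25L)
    expect_identical(nrow(p$placements), 5L)
    starts <- sort(p$placements$start)
    expect_true(all(diff(starts) >= 6))        # no overlap, no touching
    expect_true(starts[1] >= 1 && starts[5] <= 96)
    q <- place_objects(100, "XXOXX", 5)
    expect_identical(sum(q$activity), 20L)     # 4 active inputs per object
    # each gapped object leaves its centre inactive
    expect_true(all(!q$activity[q$placements$start + 2]))
  }
})

test_that("degenerate and infeasible placements are handled", {
  p0 <- place_objects(100, "XXXXX", 0)
  expect_identical(sum(p0$activity), 0L)
  expect_error(place_objects(10, "XXXXX", 2), "cannot place")
  # exactly-full packing is feasible: 2 objects need 11 inputs
  p <- place_objects(11, "XXXXX", 2)
  expect_identical(p$placements$start, c(1L, 7L))
})

test_that("object detection works on raw activity", {
  # a single object of each type is unambiguous
  solid <- place_objects(10, "XXXXX", 1)
  gapped <- place_objects(10, "XXOXX", 1)
  expect_true(detect_object(solid, "XXXXX"))
  expect_false(detect_object(solid, "XXOXX"))
  expect_true(detect_object(gapped, "XXOXX"))
  expect_false(detect_object(gapped, "XXXXX"))
  expect_false(detect_object(rep(FALSE, 30), "XXXXX"))
  expect_false(detect_object(rep(FALSE, 30), "XXOXX"))
  expect_false(detect_object(rep(TRUE, 4), "XXXXX"))  # too short
  # raw 0/1 vectors are accepted
  expect_true(detect_object(c(0, 1, 1, 0, 1, 1, 0), "XXOXX"))
})

test_that("generated patterns always contain their own object type", {
  set.seed(31)
  for (rep in 1:25) {
    solid <- place_objects(100, "XXXXX", sample(1:8, 1))
    expect_true(detect_object(solid, "XXXXX"))
    # a solid pattern shows a spurious gapped window exactly when two of
    # its objects sit at the minimum spacing of one inactive input
    # (…11111 0 11111… contains 1,1,0,1,1 across the boundary)
    min_spaced <- any(diff(sort(solid$placements$start)) == 6)
    expect_identical(detect_object(solid, "XXOXX"), min_spaced)
    gapped <- place_objects(100, "XXOXX", sample(1:8, 1))
    expect_true(detect_object(gapped, "XXOXX"))
    # a gapped pattern never holds 5 consecutive active inputs
    expect_false(detect_object(gapped, "XXXXX"))
  }
})

test_that("placement sampling is uniform over the valid sets", {
  # I = 12, n = 2 has exactly three valid start sets
  valid <- enumerate_placements(12, 2)
  expect_length(valid, 3)
  set.seed(17)
  n <- 3000
  keys <- vapply(seq_len(n), function(i) {
    paste(sort(place_objects(12, "XXXXX", 2)$placements$start), collapse = ",")
  }, character(1))
  valid_keys <- vapply(valid, paste, character(1), collapse = ",")
  expect_setequal(unique(keys), valid_keys)
  freq <- table(keys) / n
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})

test_that("internal-representation pattern sets are balanced and distinct", {
  set.seed(41)
  cfg <- experiment_config("internal_rep", n_objects = 5)
  pset <- make_pattern_set(cfg)
  expect_length(pset$patterns, 100)
  expect_identical(as.vector(table(pset$assigned_mc)), rep(10L, 10))
  acts <- vapply(pset$patterns,
                 function(p) paste0(as.integer(p$activity), collapse = ""),
                 character(1))
  expect_identical(anyDuplicated(acts), 0L)
  expect_true(all(is.na(pset$twin)))
})

test_that("hierarchical pattern sets pair location twins across minicolumns", {
  set.seed(43)
  cfg <- experiment_config("hierarchical", n_objects = 5, F = 1)
  pset <- make_pattern_set(cfg)
  expect_length(pset$patterns, 100)
  expect_identical(as.vector(table(pset$assigned_mc)), rep(10L, 10))
  types <- vapply(pset$patterns, function(p) p$placements$object_type[1],
                  character(1))
  expect_identical(sum(types == "XXXXX"), 50L)
  for (i in seq_along(pset$patterns)) {
    j <- pset$twin[i]
    expect_identical(pset$twin[j], i)                 # twin pairing is mutual
    expect_identical(pset$patterns[[i]]$placements$start,
                     pset$patterns[[j]]$placements$start)
    expect_false(pset$assigned_mc[i] == pset$assigned_mc[j])
    # twin activities differ exactly at the objects' centre positions
    diff_pos <- which(pset$patterns[[i]]$activity != pset$patterns[[j]]$activity)
    expect_identical(diff_pos, sort(pset$patterns[[i]]$placements$start + 2L))
  }
  acts <- vapply(pset$patterns,
                 function(p) paste0(as.integer(p$activity), collapse = ""),
                 character(1))
  expect_identical(anyDuplicated(acts), 0L)
})

test_that("pattern sets round-trip losslessly through the text format", {
  set.seed(47)
  for (mode in c("internal_rep", "hierarchical")) {
    cfg <- experiment_config(mode, n_objects = 3,
                             F = if (mode == "hierarchical") 2 else 0)
    pset <- make_pattern_set(cfg)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_pattern_set(pset, path)
    back <- read_pattern_set(path)
    expect_equal(back, pset, ignore_attr = FALSE)
  }
})
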