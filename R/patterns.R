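# Synthetic input patterns: bar-like objects placed on a 1-D line of I
# binary inputs. Two object types, both 5 inputs wide:
#   solid  "XXXXX" — 5 adjacent active inputs
#   gapped "XXOXX" — two active pairs separated by one inactive input
# Objects may neither overlap nor touch (>= 1 inactive input between
# footprints); there is no wrap-around. Positions are 1-based.

OBJECT_TYPES <- c("XXXXX", "XXOXX")
OBJECT_WIDTH <- 5L

object_offsets <- function(object_type) {
  switch(object_type,
         XXXXX = 0:4,
         XXOXX = c(0L, 1L, 3L, 4L),
         stop("unknown object type: ", object_type))
}

#' Place objects uniformly at random on an input line
#'
#' Draws a set of `n_objects` non-overlapping, non-touching placements
#' uniformly over all valid placement sets, by the stars-and-bars gap
#' construction (the spare inactive inputs are distributed over the
#' n_objects + 1 gaps via a uniform random combination), then builds the
#' binary activity vector.
#'
#' @param I Length of the input line.
#' @param object_type `"XXXXX"` or `"XXOXX"`.
#' @param n_objects Number of objects; must satisfy
#'   `5 * n_objects + (n_objects - 1) <= I`.
#' @return An `input_pattern`: list with logical `activity` (length `I`)
#'   and data.frame `placements` (columns `object_type`, `start`; `start`
#'   is the 1-based leftmost input of the 5-wide footprint).
#' @export
place_objects <- function(I, object_type = c("XXXXX", "XXOXX"), n_objects) {
  object_type <- match.arg(object_type)
  stopifnot(I >= 1, n_objects >= 0, n_objects == floor(n_objects))
  if (n_objects > 0 && OBJECT_WIDTH * n_objects + (n_objects - 1) > I) {
    stop("cannot place ", n_objects, " non-touching width-5 objects on ",
         I, " inputs (needs at least ",
         OBJECT_WIDTH * n_objects + n_objects - 1, ")")
  }
  if (n_objects == 0) {
    return(new_pattern(I, data.frame(object_type = character(0),
                                     start = integer(0))))
  }
  slack <- I - 6L * n_objects + 1L
  # subset of {1..slack+n} <-> weak composition of slack over n+1 gaps;
  # starts come out as c_k + 5 (k - 1)
  comb <- sort(sample.int(slack + n_objects, n_objects))
  starts <- comb + OBJECT_WIDTH * (seq_len(n_objects) - 1L)
  new_pattern(I, data.frame(object_type = object_type, start = starts,
                            stringsAsFactors = FALSE))
}

new_pattern <- function(I, placements) {
  activity <- rep(FALSE, I)
  for (k in seq_len(nrow(placements))) {
    activity[placements$start[k] + object_offsets(placements$object_type[k])] <- TRUE
  }
  structure(list(activity = activity, placements = placements),
            class = "input_pattern")
}

#' @export
print.input_pattern <- function(x, ...) {
  cat(paste0(ifelse(x$activity, "X", "."), collapse = ""), "\n")
  if (nrow(x$placements)) {
    cat("objects:",
        paste(sprintf("%s@%d", x$placements$object_type, x$placements$start),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Detect an object type in raw activity
#'
#' Sensory detection operating on the activity vector alone (never on the
#' placement metadata): a solid object is present iff some window of 5
#' consecutive inputs is all active; a gapped object iff some window matches
#' active, active, inactive, active, active.
#'
#' @param pattern An `input_pattern` or a logical/0-1 activity vector.
#' @param object_type `"XXXXX"` or `"XXOXX"`.
#' @return Logical scalar.
#' @export
detect_object <- function(pattern, object_type = c("XXXXX", "XXOXX")) {
  object_type <- match.arg(object_type)
  a <- if (inherits(pattern, "input_pattern")) pattern$activity else as.logical(pattern)
  n <- length(a)
  if (n < OBJECT_WIDTH) return(FALSE)
  i <- seq_len(n - OBJECT_WIDTH + 1L)
  hit <- if (object_type == "XXXXX") {
    a[i] & a[i + 1L] & a[i + 2L] & a[i + 3L] & a[i + 4L]
  } else {
    a[i] & a[i + 1L] & !a[i + 2L] & a[i + 3L] & a[i + 4L]
  }
  any(hit)
}

activity_string <- function(pattern) {
  paste0(as.integer(pattern$activity), collapse = "")
}

#' Generate an experiment's pattern set with minicolumn assignment
#'
#' Internal-representation mode: `n_mc * patterns_per_mc` distinct solid
#' ("XXXXX") patterns, each minicolumn assigned `patterns_per_mc` of them at
#' random. Hierarchical mode: half as many distinct random solid patterns,
#' each paired with a gapped ("XXOXX") twin copying its object start
#' positions exactly; twins are always assigned to different minicolumns,
#' and every minicolumn still receives exactly `patterns_per_mc` patterns.
#'
#' @param config An [experiment_config()].
#' @return A `pattern_set`: list with `patterns` (list of `input_pattern`),
#'   integer `assigned_mc`, integer `twin` (index of the location twin, NA
#'   in internal-representation mode), and `mode`.
#' @export
make_pattern_set <- function(config) {
  n_mc <- config$n_mc
  per_mc <- config$patterns_per_mc
  n_pat <- n_mc * per_mc
  if (config$mode == "internal_rep") {
    patterns <- draw_distinct_patterns(config$I, "XXXXX", config$n_objects,
                                       n_pat)
    assigned <- sample(rep(seq_len(n_mc), each = per_mc))
    twin <- rep(NA_integer_, n_pat)
  } else {
    if (n_pat %% 2L != 0L) stop("hierarchical mode needs an even pattern count")
    half <- n_pat %/% 2L
    solid <- draw_distinct_patterns(config$I, "XXXXX", config$n_objects, half)
    gapped <- lapply(solid, function(p) {
      pl <- p$placements
      pl$object_type <- "XXOXX"
      new_pattern(config$I, pl)
    })
    patterns <- c(solid, gapped)
    twin <- c(seq_len(half) + half, seq_len(half))
    assigned <- assign_with_twin_constraint(n_mc, per_mc, twin)
  }
  structure(list(patterns = patterns, assigned_mc = assigned, twin = twin,
                 mode = config$mode),
            class = "pattern_set")
}

# draw n patterns with pairwise-distinct activity vectors; bounded redraws
draw_distinct_patterns <- function(I, object_type, n_objects, n,
                                   max_redraws = 1000) {
  patterns <- vector("list", n)
  seen <- character(0)
  redraws <- 0
  k <- 1
  while (k <= n) {
    p <- place_objects(I, object_type, n_objects)
    key <- activity_string(p)
    if (key %in% seen) {
      redraws <- redraws + 1
      if (redraws > max_redraws) {
        stop("could not generate ", n, " distinct patterns after ",
             max_redraws, " redraws")
      }
    } else {
      patterns[[k]] <- p
      seen <- c(seen, key)
      k <- k + 1
    }
  }
  patterns
}

# balanced assignment (each minicolumn gets per_mc patterns) under the
# constraint assigned[i] != assigned[twin[i]]; shuffle then swap-repair
assign_with_twin_constraint <- function(n_mc, per_mc, twin,
                                        max_attempts = 10000) {
  n_pat <- length(twin)
  assigned <- sample(rep(seq_len(n_mc), each = per_mc))
  if (n_mc < 2) stop("twin constraint needs at least 2 minicolumns")
  attempts <- 0
  repeat {
    bad <- which(assigned == assigned[twin])
    if (length(bad) == 0) return(assigned)
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      stop("could not satisfy the twin-assignment constraint")
    }
    i <- bad[sample.int(length(bad), 1)]
    j <- sample.int(n_pat, 1)
    # swap keeps the assignment balanced; accept if it breaks i's violation
    # without creating one at j
    ai <- assigned[j]; aj <- assigned[i]
    if (ai != assigned[twin[i]] && aj != assigned[twin[j]] && i != twin[j]) {
      assigned[i] <- ai
      assigned[j] <- aj
    }
  }
}

#' Write a pattern set to a plain-text file
#'
#' Tab-separated, one pattern per line: `pattern_id`, `assigned_mc`, the
#' activity as a 0/1 string, the placements as `type:start;...` (1-based
#' starts), and the twin pattern id (`NA` when absent). Lossless round-trip
#' with [read_pattern_set()].
#'
#' @param pset A `pattern_set`.
#' @param path Output file path.
#' @export
write_pattern_set <- function(pset, path) {
  lines <- vapply(seq_along(pset$patterns), function(i) {
    p <- pset$patterns[[i]]
    pl <- if (nrow(p$placements)) {
      paste(sprintf("%s:%d", p$placements$object_type, p$placements$start),
            collapse = ";")
    } else "-"
    paste(i, pset$assigned_mc[i], activity_string(p), pl, pset$twin[i],
          sep = "\t")
  }, character(1))
  writeLines(c(paste0("#mode=", pset$mode), lines), path)
}

#' Read a pattern set written by [write_pattern_set()]
#'
#' @param path File path.
#' @return A `pattern_set`.
#' @export
read_pattern_set <- function(path) {
  lines <- readLines(path)
  mode <- sub("^#mode=", "", lines[1])
  lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  patterns <- vector("list", length(fields))
  assigned <- integer(length(fields))
  twin <- integer(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    assigned[i] <- as.integer(f[2])
    I <- nchar(f[3])
    placements <- if (f[4] == "-") {
      data.frame(object_type = character(0), start = integer(0))
    } else {
      parts <- strsplit(strsplit(f[4], ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
      data.frame(object_type = vapply(parts, `[`, character(1), 1),
                 start = as.integer(vapply(parts, `[`, character(1), 2)),
                 stringsAsFactors = FALSE)
    }
    p <- new_pattern(I, placements)
    if (activity_string(p) != f[3]) {
      stop("corrupt pattern file: activity does not match placements at line ", i)
    }
    patterns[[i]] <- p
    twin[i] <- suppressWarnings(as.integer(f[5]))
  }
  structure(list(patterns = patterns, assigned_mc = assigned, twin = twin,
                 mode = mode),
            class = "pattern_set")
}
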