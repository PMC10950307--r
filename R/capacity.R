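# Exact binomial selection capacity.
#
# The number of pyramidal cells that can be individually addressed through
# apical tuft clusters is the number of distinct G-subsets of I selection
# inputs, i.e. choose(I, G). These counts overflow double precision quickly
# (choose(100, 50) has 30 digits), so they are computed exactly with a small
# base-1e6 limb arithmetic: multiply-by-small and exact divide-by-small are
# all the multiplicative binomial algorithm needs, and every intermediate
# product limb * small stays far below 2^53.

BIG_BASE <- 1e6

# little-endian limb vector (doubles holding exact integers < BIG_BASE)
big_from_int <- function(x) {
  stopifnot(x >= 0, x == floor(x))
  if (x == 0) return(0)
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% BIG_BASE)
    x <- x %/% BIG_BASE
  }
  limbs
}

big_mul_small <- function(a, m) {
  stopifnot(m >= 0, m < 2^31)
  carry <- 0
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    v <- a[i] * m + carry
    out[i] <- v %% BIG_BASE
    carry <- v %/% BIG_BASE
  }
  while (carry > 0) {
    out <- c(out, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  out
}

# exact division; errors if a remainder is left (guards the binomial algebra)
big_div_small <- function(a, d) {
  stopifnot(d > 0, d < 2^31)
  rem <- 0
  out <- numeric(length(a))
  for (i in rev(seq_along(a))) {
    cur <- rem * BIG_BASE + a[i]
    out[i] <- cur %/% d
    rem <- cur %% d
  }
  if (rem != 0) stop("big_div_small: inexact division")
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_to_string <- function(a) {
  n <- length(a)
  head <- format(a[n], scientific = FALSE)
  if (n == 1) return(head)
  tail <- vapply(rev(a[-n]), function(l) sprintf("%06d", l), character(1))
  paste0(head, paste0(tail, collapse = ""))
}

#' Exact count of individually addressable cells
#'
#' Number of distinct cells that can be selected for firing when each cell's
#' apical tuft carries a cluster formed by a distinct `G`-subset of `I`
#' selection inputs and an NMDA spike (hence selection) requires `G` active
#' synapses: the binomial coefficient choose(`I`, `G`), computed exactly in
#' arbitrary precision.
#'
#' @param I Number of selection inputs (non-negative integer).
#' @param G Number of coincidently active synapses required (0 <= G <= I).
#' @return An object of class `selection_capacity`: the exact count, with
#'   `as.character()` giving the full decimal representation and
#'   `as.numeric()` the double value (exact whenever the count is below
#'   2^53, which covers all counts of up to 15 digits).
#' @examples
#' selection_capacity(25, 8)   # 1081575, about 10^6
#' selection_capacity(50, 20)  # 47129212243960, about 5e13
#' @export
selection_capacity <- function(I, G) {
  if (length(I) != 1 || length(G) != 1 || is.na(I) || is.na(G) ||
      I != floor(I) || G != floor(G)) {
    stop("I and G must be single integers")
  }
  if (I < 0 || G < 0) stop("I and G must be non-negative")
  if (G > I) stop("G must not exceed I")
  k <- min(G, I - G)
  acc <- big_from_int(1)
  # running value after step i is choose(I - k + i, i), an integer, so the
  # division is exact at every step
  for (i in seq_len(k)) {
    acc <- big_mul_small(acc, I - k + i)
    acc <- big_div_small(acc, i)
  }
  structure(list(limbs = acc, I = I, G = G), class = "selection_capacity")
}

#' @export
as.character.selection_capacity <- function(x, ...) big_to_string(x$limbs)

#' @export
as.double.selection_capacity <- function(x, ...) {
  v <- sum(x$limbs * BIG_BASE^(seq_along(x$limbs) - 1))
  if (v >= 2^53) {
    warning("capacity exceeds 2^53; double value is approximate")
  }
  v
}

#' @export
print.selection_capacity <- function(x, ...) {
  s <- as.character(x)
  cat(sprintf("choose(%d, %d) = %s  (~%s)\n", x$I, x$G, s, signif_string(s)))
  invisible(x)
}

# one-significant-figure scientific rendering of a decimal integer string
signif_string <- function(s) {
  if (s == "0") return("0")
  d1 <- as.integer(substr(s, 1, 1))
  d2 <- if (nchar(s) >= 2) as.integer(substr(s, 2, 2)) else 0
  if (d2 >= 5) d1 <- d1 + 1
  expo <- nchar(s) - 1
  if (d1 == 10) { d1 <- 1; expo <- expo + 1 }
  sprintf("%de%d", d1, expo)
}
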