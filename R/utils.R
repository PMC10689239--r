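# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded package functions do not disturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialise RNG state
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# stop() with sprintf-style formatting, no call in the condition
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Dense matrix view of a (possibly sparse) matrix
as_dense <- function(x) {
  if (methods::is(x, "sparseMatrix")) as.matrix(x) else as.matrix(x)
}

# Pairwise correlation distance (1 - Pearson r) between rows of `x`.
correlation_dist <- function(x) {
  r <- stats::cor(t(x))
  r[!is.finite(r)] <- 0
  d <- 1 - r
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# Modal value of a character vector; ties broken by first appearance in
# `levels` (or sorted order).
modal_label <- function(x, levels = NULL) {
  if (length(x) == 0L) return(NA_character_)
  tab <- table(x)
  winners <- names(tab)[tab == max(tab)]
  if (!is.null(levels)) {
    winners <- winners[order(match(winners, levels))]
  } else {
    winners <- sort(winners)
  }
  winners[[1L]]
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells.
#' Used to compare recovered clusters with planted ground truth.
#'
#' @param a,b Vectors of labels of equal length.
#' @return A single number in \[-1, 1\]; 1 means identical partitions.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(NA_real_)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
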