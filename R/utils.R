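#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two labelings of the same items, corrected for
#' chance; 1 means identical partitions, 0 is the expectation under random
#' labeling.  Used to score recovery of planted co-expression modules.
#'
#' @param x,y vectors of cluster labels of equal length.
#' @return a single numeric value in [-1, 1].
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

# internal: stop with a formatted message
abort <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: check a numeric scalar lies in a range
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort("'%s' must be a single number in [0, 1]", name)
  invisible(x)
}
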