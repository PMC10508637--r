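#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least k annotated genes when sampling n genes from a universe of N
#' containing K annotated ones.  The tail sum is accumulated in log space
#' (log-binomials + log-sum-exp) for numerical stability.
#'
#' @param k observed overlap; @param K term size in the universe;
#' @param n module size in the universe; @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeometric_p <- function(k, K, n, N) {
  if (K < 0 || n < 0 || K > N || n > N || k < 0 || k > min(K, n))
    abort("inconsistent hypergeometric counts (k=%s K=%s n=%s N=%s)",
          k, K, n, N)
  i <- k:min(K, n)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up procedure: sort p ascending, multiply by m/i, take the
#' cumulative minimum from the largest rank down, cap at 1, restore input
#' order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    abort("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Read / write GMT gene-set files
#'
#' GMT: one set per line, tab-separated: term id, description, member ids.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors with a "description"
#'   attribute per element name kept in `attr(x, "descriptions")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[`, "", 2),
                                         names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional named descriptions (default the term ids).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(t)
    paste(c(t, desc[[t]], sets[[t]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of gene sets in a module
#'
#' Tests each term with at least one universe member and at least one
#' module hit, adjusts with Benjamini-Hochberg within each namespace, and
#' keeps terms with adjusted p < `alpha` and q < `q_cap` (q is computed as
#' BH, i.e. identical to the adjusted p; see the methods vignette).
#'
#' @param genes module gene ids (genes outside the universe are dropped
#'   with a warning).
#' @param sets named list of term -> member ids, or the result of
#'   [read_gmt()].
#' @param universe character vector of all testable gene ids.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param q_cap q-value threshold (default 0.2).
#' @param namespaces optional named vector term -> namespace tag; BH is
#'   applied within namespace (single namespace assumed when NULL).
#' @return data.frame: term, namespace, k, K, n, N, p, p_adj, q, ordered by
#'   p; only rows passing both thresholds.  The full unfiltered table is
#'   attached as attribute "all".
#' @export
enrich_module <- function(genes, sets, universe, alpha = 0.05, q_cap = 0.2,
                          namespaces = NULL) {
  if (length(universe) == 0) abort("empty universe")
  universe <- unique(universe)
  drop <- setdiff(genes, universe)
  if (length(drop)) {
    warning(length(drop), " module genes outside the universe dropped")
    genes <- intersect(genes, universe)
  }
  genes <- unique(genes)
  N <- length(universe)
  n <- length(genes)
  ns <- namespaces %||% setNames(rep("sets", length(sets)), names(sets))
  rows <- lapply(names(sets), function(term) {
    members <- intersect(sets[[term]], universe)
    K <- length(members)
    k <- length(intersect(genes, members))
    if (K < 1 || k < 1) return(NULL)
    data.frame(term = term, namespace = unname(ns[term]), k = k, K = K,
               n = n, N = N, p = hypergeometric_p(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(term = character(0), namespace = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0))
  tab$p_adj <- rep(NA_real_, nrow(tab))
  for (s in unique(tab$namespace))
    tab$p_adj[tab$namespace == s] <- bh_adjust(tab$p[tab$namespace == s])
  tab$q <- tab$p_adj
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  out <- tab[!is.na(tab$p_adj) & tab$p_adj < alpha & tab$q < q_cap, ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- tab
  out
}
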