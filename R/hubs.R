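#' Pearson correlation with p-value
#'
#' Two-sided p from t = r sqrt(n-2)/sqrt(1-r^2) with n-2 df; |r| = 1 gives
#' p = 0; zero-variance input gives NaN with a warning.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list(r, p).
#' @export
cor_with_p <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) abort("need two vectors of equal length >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance input; correlation undefined")
    return(list(r = NaN, p = NaN))
  }
  r <- cor(x, y)
  list(r = r, p = cor_p_from_r(r, n))
}

#' Within-module correlation edges
#'
#' For every unordered pair of probes in the same module, the Pearson
#' correlation and p-value are computed over all samples; pairs with
#' r > r_min and p < alpha (both strict) become edges.  Per-module counts
#' of distinct lncRNAs, mRNAs and TFs appearing in at least one edge are
#' reported.
#'
#' @param matrix `signal_matrix` (normalized) or probes x samples matrix.
#' @param assignment named probe -> module vector ("grey" skipped).
#' @param tags data.frame(probe_id, kind in {"lncRNA","mRNA"}, is_tf).
#' @param r_min correlation threshold (default 0.7, signed: anticorrelated
#'   pairs never qualify).
#' @param alpha p-value threshold (default 0.05).
#' @param absolute if TRUE, threshold |r| instead of signed r.
#' @return named list per module: list(edges = data.frame(node_a, node_b,
#'   r, p), counts = c(lncRNA, mRNA, TF)).
#' @export
build_edges <- function(matrix, assignment, tags, r_min = 0.7, alpha = 0.05,
                        absolute = FALSE) {
  v <- if (inherits(matrix, "signal_matrix")) matrix$values else matrix
  untagged <- setdiff(names(assignment), tags$probe_id)
  if (length(untagged)) abort("probes without kind tags: %s",
                              paste(head(untagged, 3), collapse = ", "))
  kind <- setNames(tags$kind, tags$probe_id)
  is_tf <- setNames(tags$is_tf, tags$probe_id)
  mods <- setdiff(unique(assignment), "grey")
  n <- ncol(v)
  out <- lapply(mods, function(m) {
    mem <- sort(names(assignment)[assignment == m])
    if (length(mem) < 2)
      return(list(edges = data.frame(node_a = character(0),
                                     node_b = character(0),
                                     r = numeric(0), p = numeric(0)),
                  counts = c(lncRNA = 0L, mRNA = 0L, TF = 0L)))
    r <- cor(t(v[mem, , drop = FALSE]))
    p <- cor_p_from_r(r, n)
    score <- if (absolute) abs(r) else r
    sel <- which(upper.tri(r) & score > r_min & p < alpha, arr.ind = TRUE)
    edges <- data.frame(node_a = mem[sel[, 1]], node_b = mem[sel[, 2]],
                        r = r[sel], p = p[sel], stringsAsFactors = FALSE)
    nodes <- unique(c(edges$node_a, edges$node_b))
    counts <- c(lncRNA = sum(kind[nodes] == "lncRNA"),
                mRNA = sum(kind[nodes] == "mRNA"),
                TF = sum(is_tf[nodes]))
    list(edges = edges, counts = counts)
  })
  names(out) <- mods
  out
}

#' Hub transcription factors and hub genes of one module
#'
#' Scores each node by sums of edge correlation coefficients and reports
#' four roles: the TF with the largest sum over edges to lncRNA partners
#' (lncRNA_hub_TF), the TF with the largest sum over edges to non-TF mRNA
#' partners (mRNA_hub_TF), the lncRNA with the largest sum over all its
#' edges (hub_lncRNA), and the non-TF mRNA with the largest sum over all
#' its edges (hub_mRNA).  Ties break lexicographically; empty categories
#' yield NA.
#'
#' @param edges data.frame(node_a, node_b, r, p) for one module.
#' @param tags data.frame(probe_id, kind, is_tf).
#' @return one-row data.frame: lncRNA_hub_TF, mRNA_hub_TF, hub_lncRNA,
#'   hub_mRNA and their scores.
#' @export
find_hubs <- function(edges, tags) {
  kind <- setNames(tags$kind, tags$probe_id)
  is_tf <- setNames(tags$is_tf, tags$probe_id)
  # long form: each edge contributes to both endpoints
  long <- rbind(
    data.frame(node = edges$node_a, partner = edges$node_b, r = edges$r),
    data.frame(node = edges$node_b, partner = edges$node_a, r = edges$r))
  best <- function(node_ok, partner_ok = NULL) {
    d <- long[node_ok(long$node), , drop = FALSE]
    if (!is.null(partner_ok)) d <- d[partner_ok(d$partner), , drop = FALSE]
    if (nrow(d) == 0) return(list(id = NA_character_, score = NA_real_))
    s <- tapply(d$r, d$node, sum)
    s <- s[order(-s, names(s))]               # ties: lexicographic id
    list(id = names(s)[1], score = unname(s[1]))
  }
  tf <- function(x) is_tf[x] %in% TRUE
  lnc <- function(x) kind[x] %in% "lncRNA"
  mrna_non_tf <- function(x) kind[x] %in% "mRNA" & !(is_tf[x] %in% TRUE)
  a <- best(tf, lnc)
  b <- best(tf, mrna_non_tf)
  c_ <- best(lnc)
  d_ <- best(mrna_non_tf)
  data.frame(lncRNA_hub_TF = a$id, lncRNA_hub_TF_score = a$score,
             mRNA_hub_TF = b$id, mRNA_hub_TF_score = b$score,
             hub_lncRNA = c_$id, hub_lncRNA_score = c_$score,
             hub_mRNA = d_$id, hub_mRNA_score = d_$score,
             stringsAsFactors = FALSE)
}

#' Per-module hub table
#'
#' Combines [build_edges()] counts and [find_hubs()] roles into a table
#' with one row per module: the module name, the numbers of distinct
#' lncRNAs, mRNAs and TFs with at least one significant correlation, and
#' the four hub roles.
#'
#' @inheritParams build_edges
#' @return data.frame, one row per module.
#' @export
hub_table <- function(matrix, assignment, tags, r_min = 0.7, alpha = 0.05) {
  per_mod <- build_edges(matrix, assignment, tags, r_min, alpha)
  if (length(per_mod) == 0)
    return(data.frame(module = character(0), n_lncRNA = integer(0),
                      n_mRNA = integer(0), n_TF = integer(0)))
  do.call(rbind, lapply(names(per_mod), function(m) {
    cnt <- per_mod[[m]]$counts
    cbind(data.frame(module = m, n_lncRNA = cnt[["lncRNA"]],
                     n_mRNA = cnt[["mRNA"]], n_TF = cnt[["TF"]],
                     stringsAsFactors = FALSE),
          find_hubs(per_mod[[m]]$edges, tags))
  }))
}
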