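#' Signed weighted adjacency from a correlation matrix
#'
#' The signed transform a_ij = ((1 + r_ij) / 2)^beta maps correlation -1 to
#' adjacency 0 and +1 to 1, so anti-correlated probes are unconnected.
#' The diagonal is forced to 1.
#'
#' @param r symmetric correlation matrix with values in [-1, 1].
#' @param beta soft-thresholding power (default 12).
#' @return adjacency matrix in [0, 1].
#' @export
signed_adjacency <- function(r, beta = 12) {
  if (beta < 1) abort("beta must be >= 1")
  if (max(abs(r)) > 1 + 1e-8) abort("correlations outside [-1, 1]")
  r <- pmin(pmax(r, -1), 1)
  a <- ((1 + r) / 2)^beta
  diag(a) <- 1
  a
}

# internal: connectivity (sum of adjacency to all other nodes)
connectivity <- function(a) rowSums(a) - diag(a)

#' Scale-free topology fit
#'
#' Bins connectivities into `nbins` equal-width bins, and regresses
#' log10(frequency) on log10(mean connectivity) over non-empty bins.
#' R-squared counts toward scale-free fit only when the slope is negative.
#'
#' @param k numeric vector of node connectivities.
#' @param nbins number of bins (default 10).
#' @return list: `r_squared`, `slope`, `fit_signed` (R^2 if slope < 0 else
#'   -R^2).
#' @export
scale_free_fit <- function(k, nbins = 10) {
  brk <- seq(min(k), max(k), length.out = nbins + 1)
  bin <- cut(k, brk, include.lowest = TRUE)
  freq <- as.numeric(table(bin))
  mk <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(mk) & mk > 0
  if (sum(ok) < 2) abort("not enough non-empty connectivity bins")
  fit <- lm(log10(freq[ok]) ~ log10(as.numeric(mk[ok])))
  r2 <- summary(fit)$r.squared
  slope <- unname(coef(fit)[2])
  list(r_squared = r2, slope = slope,
       fit_signed = ifelse(slope < 0, r2, -r2))
}

#' Choose the soft-thresholding power
#'
#' Evaluates candidate powers and returns the smallest one meeting the
#' scale-free criterion (signed R^2 >= `r2_target` with negative slope) and
#' the mean-connectivity cap.  If no candidate qualifies, the power with the
#' best signed fit is returned with a warning.
#'
#' @param matrix `signal_matrix` (normalized) or plain probes x samples
#'   matrix.
#' @param betas candidate powers (default 1:20).
#' @param r2_target scale-free R^2 target (default 0.9).
#' @param k_cap mean-connectivity cap (default 100).
#' @return list: `beta`, `diagnostics` (per-beta beta, r_squared, slope,
#'   mean_k), `met_criterion`.
#' @export
pick_soft_threshold <- function(matrix, betas = 1:20, r2_target = 0.9,
                                k_cap = 100) {
  v <- if (inherits(matrix, "signal_matrix")) matrix$values else matrix
  if (nrow(v) < 50) abort("need >= 50 probes")
  if (ncol(v) < 10) abort("need >= 10 samples")
  r <- cor(t(v))
  diag <- do.call(rbind, lapply(betas, function(b) {
    a <- signed_adjacency(r, b)
    k <- connectivity(a)
    f <- scale_free_fit(k)
    data.frame(beta = b, r_squared = f$fit_signed, slope = f$slope,
               mean_k = mean(k))
  }))
  ok <- diag$r_squared >= r2_target & diag$mean_k < k_cap
  if (any(ok)) {
    beta <- diag$beta[which(ok)[1]]
    met <- TRUE
  } else {
    beta <- diag$beta[which.max(diag$r_squared)]
    met <- FALSE
    warning("no candidate power met the scale-free criterion; ",
            "returning the best fit (beta = ", beta, ")")
  }
  list(beta = beta, diagnostics = diag, met_criterion = met)
}

#' Signed topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with the
#' sum over u distinct from i and j; TOM_ii = 1.  Nodes sharing many strong
#' neighbors score high even if their direct adjacency is modest.
#'
#' @param a adjacency matrix (symmetric, values in [0, 1], unit diagonal).
#' @return TOM matrix in [0, 1].
#' @export
topological_overlap <- function(a) {
  if (any(a < -1e-12) || any(a > 1 + 1e-12)) abort("adjacency outside [0, 1]")
  k <- connectivity(a)
  aa <- a %*% a
  # remove u = i and u = j terms (diagonal of a is 1)
  num <- aa - a * (diag(a)[row(a)] + diag(a)[col(a)]) + a
  den <- outer(k, k, pmin) + 1 - a
  stopifnot(all(den[upper.tri(den)] > 0))   # diagonal is overwritten below
  tom <- num / den
  diag(tom) <- 1
  tom
}

# fixed module color palette (standard co-expression labeling order)
module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

# internal: static cut height in the middle of the largest gap between
# consecutive merge heights, restricted to gaps starting at or above the
# median height (gaps among the small within-branch joins are irrelevant)
largest_gap_height <- function(heights) {
  hs <- sort(heights)
  if (length(hs) < 2 || max(hs) == min(hs)) return(max(hs) + 1e-9)
  gaps <- diff(hs)
  ok <- hs[-length(hs)] >= median(hs)
  if (!any(ok)) return(max(hs) + 1e-9)
  i <- which(ok)[which.max(gaps[ok])]
  (hs[i] + hs[i + 1]) / 2
}

# internal: relabel clusters by decreasing size using the fixed palette
relabel_by_size <- function(labels) {
  non_grey <- labels[labels != "grey"]
  if (length(non_grey) == 0) return(labels)
  sizes <- sort(table(non_grey), decreasing = TRUE)
  if (length(sizes) > length(module_palette))
    abort("more modules than palette colors")
  map <- setNames(module_palette[seq_along(sizes)], names(sizes))
  out <- labels
  out[labels != "grey"] <- map[non_grey]
  out
}

#' Cut modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of 1 - TOM, cut at a static
#' height; clusters smaller than `min_module_size` are assigned to "grey".
#' By default the cut height is placed in the middle of the largest gap
#' between consecutive merge heights in the upper half of the height
#' distribution, i.e. just below the joins that glue well-separated
#' branches together (a height quantile, the obvious alternative, proved
#' brittle: it can land among those top joins and fuse distinct modules).
#' Module labels are colors assigned by decreasing size from a fixed
#' palette (largest = "turquoise").
#'
#' @param diss dissimilarity matrix (1 - TOM).
#' @param min_module_size minimum module size (default 30).
#' @param cut_height static cut height; NULL selects the largest-gap
#'   default.
#' @return named character vector: probe -> module color (or "grey").
#' @export
cut_modules <- function(diss, min_module_size = 30, cut_height = NULL) {
  n <- nrow(diss)
  ids <- rownames(diss) %||% paste0("P", seq_len(n))
  if (n < min_module_size) {
    warning("fewer probes than min_module_size; everything grey")
    return(setNames(rep("grey", n), ids))
  }
  tree <- hclust(as.dist(diss), method = "average")
  h <- cut_height %||% largest_gap_height(tree$height)
  cl <- cutree(tree, h = h)
  sizes <- table(cl)
  lab <- ifelse(sizes[as.character(cl)] >= min_module_size,
                paste0("C", cl), "grey")
  setNames(relabel_by_size(lab), ids)
}

#' Module eigengenes
#'
#' Each module's members are standardized per probe across samples; the
#' eigengene is the first right-singular vector of the member matrix (unit
#' norm), sign-oriented so that its mean correlation with members is
#' non-negative (ties orient to the first member).
#'
#' @param matrix `signal_matrix` (normalized) or plain probes x samples
#'   matrix.
#' @param assignment named vector probe -> module label ("grey" skipped).
#' @return list of class `eigengene_set`: `eigengenes` (samples x modules),
#'   `var_explained` (named fraction of variance explained).
#' @export
module_eigengene <- function(matrix, assignment) {
  v <- if (inherits(matrix, "signal_matrix")) matrix$values else matrix
  mods <- setdiff(unique(assignment), "grey")
  if (length(mods) == 0) abort("no non-grey modules")
  me <- matrix(NA_real_, ncol(v), length(mods),
               dimnames = list(colnames(v), mods))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    mem <- names(assignment)[assignment == m]
    x <- v[mem, , drop = FALSE]
    sds <- apply(x, 1, sd)
    if (any(sds == 0)) {
      warning("zero-variance probes excluded from eigengene of ", m)
      x <- x[sds > 0, , drop = FALSE]
    }
    if (nrow(x) < 2) abort("module %s has < 2 usable members", m)
    xs <- t(scale(t(x)))
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    mc <- mean(cor(e, t(xs)))
    if (mc < 0 || (mc == 0 && cor(e, xs[1, ]) < 0)) e <- -e
    me[, m] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = me, var_explained = ve),
            class = "eigengene_set")
}

#' Merge modules with similar eigengenes
#'
#' Modules whose eigengene dissimilarity (1 - Pearson r) falls below `cut`
#' are merged (average linkage over eigengenes), eigengenes are recomputed,
#' and the procedure iterates until stable.  Surviving modules are
#' relabeled by decreasing size from the fixed palette.
#'
#' @param matrix expression matrix (as in [module_eigengene()]).
#' @param assignment named probe -> module vector.
#' @param cut merge threshold on eigengene dissimilarity (default 0.25);
#'   0 disables merging.
#' @return updated named assignment vector.
#' @export
merge_close_modules <- function(matrix, assignment, cut = 0.25) {
  if (cut <= 0) return(assignment)
  repeat {
    mods <- setdiff(unique(assignment), "grey")
    if (length(mods) < 2) break
    me <- module_eigengene(matrix, assignment)$eigengenes
    d <- 1 - cor(me)
    grp <- cutree(hclust(as.dist(d), method = "average"), h = cut)
    if (max(table(grp)) == 1) break
    for (g in unique(grp)) {
      members <- names(grp)[grp == g]
      if (length(members) < 2) next
      sizes <- table(assignment)[members]
      target <- members[which.max(sizes)]
      assignment[assignment %in% members] <- target
    }
  }
  relabel <- relabel_by_size(assignment)
  setNames(relabel, names(assignment))
}

#' Module-trait (tissue) correlation
#'
#' Each tissue is one-hot encoded over samples and correlated (Pearson)
#' with each module eigengene; two-sided p-values come from the
#' t-distribution with n - 2 df.
#'
#' @param eigengenes `eigengene_set` or samples x modules matrix.
#' @param meta sample metadata (sample_id, tissue) covering all samples.
#' @return list: `r` and `p`, modules x tissues matrices.
#' @export
module_trait_correlation <- function(eigengenes, meta) {
  me <- if (inherits(eigengenes, "eigengene_set")) eigengenes$eigengenes
        else eigengenes
  n <- nrow(me)
  if (n < 3) abort("need >= 3 samples")
  tissue <- meta$tissue[match(rownames(me), meta$sample_id)]
  tl <- unique(meta$tissue)
  ind <- vapply(tl, function(t) as.numeric(tissue == t), numeric(n))
  r <- matrix(NaN, ncol(me), length(tl), dimnames = list(colnames(me), tl))
  for (t in seq_along(tl)) {
    if (sd(ind[, t]) == 0) next              # single-tissue design: undefined
    r[, t] <- cor(me, ind[, t])
  }
  p <- cor_p_from_r(r, n)
  list(r = r, p = p)
}

# internal: two-sided p-value from Pearson r and sample size
cor_p_from_r <- function(r, n) {
  p <- r
  idx <- is.finite(r)
  rr <- pmin(pmax(r[idx], -1), 1)
  tt <- rr * sqrt(n - 2) / sqrt(pmax(1 - rr^2, 0))
  pv <- 2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  pv[abs(rr) == 1] <- 0
  p[idx] <- pv
  p
}

#' Module composition statistics
#'
#' Per-module counts of mRNA and lncRNA probes, transcription factors and
#' housekeeping genes, with fractions, plus the across-module Pearson
#' correlation between the housekeeping fraction and the lncRNA fraction.
#'
#' @param assignment named probe -> module vector.
#' @param labels consensus labels (probe_id, final_class).
#' @param tf_ids,hkg_ids character vectors of TF / housekeeping probe ids.
#' @return list: `table` (module, size, n_mRNA, n_lncRNA, n_TF, n_HKG,
#'   frac_lncRNA, frac_HKG), `hkg_lnc_correlation` (r, p; NaN with a
#'   warning when fewer than 3 modules).
#' @export
module_composition <- function(assignment, labels, tf_ids = character(0),
                               hkg_ids = character(0)) {
  mods <- setdiff(unique(assignment), "grey")
  if (length(mods) == 0) abort("no modules to summarize")
  cls <- setNames(labels$final_class, labels$probe_id)
  tab <- do.call(rbind, lapply(mods, function(m) {
    mem <- names(assignment)[assignment == m]
    n_l <- sum(cls[mem] == "lncRNA", na.rm = TRUE)
    data.frame(module = m, size = length(mem),
               n_mRNA = length(mem) - n_l, n_lncRNA = n_l,
               n_TF = sum(mem %in% tf_ids), n_HKG = sum(mem %in% hkg_ids),
               stringsAsFactors = FALSE)
  }))
  tab$frac_lncRNA <- tab$n_lncRNA / tab$size
  tab$frac_HKG <- tab$n_HKG / tab$size
  tab <- tab[order(-tab$size), ]
  rownames(tab) <- NULL
  if (nrow(tab) < 3 || sd(tab$frac_HKG) == 0 || sd(tab$frac_lncRNA) == 0) {
    warning("housekeeping/lncRNA fraction correlation undefined")
    corr <- list(r = NaN, p = NaN)
  } else {
    ct <- cor.test(tab$frac_HKG, tab$frac_lncRNA)
    corr <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  list(table = tab, hkg_lnc_correlation = corr)
}

#' Full network construction convenience wrapper
#'
#' Correlation -> signed adjacency -> TOM -> static tree cut ->
#' eigengene-based module merging.
#'
#' @param matrix `signal_matrix` (normalized) or probes x samples matrix.
#' @param beta soft power (default 12).
#' @param min_module_size minimum module size (default 30).
#' @param merge_cut eigengene merge height (default 0.25).
#' @param cut_height static tree cut height (NULL = 0.99 height quantile).
#' @return list: `assignment`, `eigengenes` (eigengene_set), `tom`.
#' @export
build_network_modules <- function(matrix, beta = 12, min_module_size = 30,
                                  merge_cut = 0.25, cut_height = NULL) {
  v <- if (inherits(matrix, "signal_matrix")) matrix$values else matrix
  r <- cor(t(v))
  a <- signed_adjacency(r, beta)
  tom <- topological_overlap(a)
  assignment <- cut_modules(1 - tom, min_module_size, cut_height)
  if (length(setdiff(unique(assignment), "grey")) >= 2)
    assignment <- merge_close_modules(v, assignment, merge_cut)
  eg <- if (length(setdiff(unique(assignment), "grey")) >= 1)
    module_eigengene(v, assignment) else NULL
  list(assignment = assignment, eigengenes = eg, tom = tom)
}
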