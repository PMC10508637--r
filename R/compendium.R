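#' Log2 transform and quantile normalize a raw signal matrix
#'
#' All raw intensities are log2 transformed, then quantile normalization is
#' applied across all arrays: each column's sorted values are replaced by
#' the across-column means of the order statistics.  Tied values within a
#' column receive the mean of the reference values over their tied rank
#' span, so the result is deterministic and invariant to input order.
#'
#' @param matrix a `signal_matrix` on the raw scale.
#' @return a `signal_matrix` with scale "log2_normalized".
#' @export
log2_and_quantile_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "signal_matrix"))
  if (matrix$scale != "raw") abort("expected a raw-scale matrix")
  v <- matrix$values
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)[1, ]
    abort("non-positive intensity at probe %s, sample %s",
          rownames(v)[bad[1]], colnames(v)[bad[2]])
  }
  lv <- log2(v)
  ref <- rowMeans(apply(lv, 2, sort))
  out <- apply(lv, 2, function(col) {
    y <- numeric(length(col))
    y[order(col)] <- ref
    ave(y, col, FUN = mean)        # ties share the mean reference value
  })
  dimnames(out) <- dimnames(lv)
  signal_matrix(out, "log2_normalized")
}

#' Compendium quality control: pairwise Spearman correlations
#'
#' @param matrix a `signal_matrix` (normalized scale expected).
#' @param meta sample metadata (sample_id, series_id, tissue); optional,
#'   required for series-level screening.
#' @return list of class `compendium_qc`: `rho` (sample x sample Spearman
#'   matrix), `median_rho` (per-sample median correlation to all others),
#'   `meta`.
#' @export
compendium_qc <- function(matrix, meta = NULL) {
  v <- if (inherits(matrix, "signal_matrix")) matrix$values else matrix
  if (ncol(v) < 3) abort("need >= 3 samples for QC")
  rho <- cor(v, method = "spearman")
  med <- vapply(seq_len(ncol(rho)),
                function(i) median(rho[-i, i]), numeric(1))
  names(med) <- colnames(rho)
  structure(list(rho = rho, median_rho = med, meta = meta),
            class = "compendium_qc")
}

#' Flag outlier samples and series
#'
#' A sample is an outlier if its median Spearman correlation to all other
#' samples falls below max(floor, Q1 - 1.5 IQR) of the per-sample medians
#' (a Tukey fence with an absolute floor).  Series are screened by the same
#' rule applied to the per-series means of their samples' medians.
#'
#' @param qc a `compendium_qc`.
#' @param floor absolute correlation floor (default 0.5).
#' @return list: `sample_flags` (named logical), `series_flags` (named
#'   logical, NULL without metadata), `cutoff_samples`, `cutoff_series`.
#' @export
screen_outliers <- function(qc, floor = 0.5) {
  stopifnot(inherits(qc, "compendium_qc"))
  med <- qc$median_rho
  fence <- function(x) {
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    max(floor, q[1] - 1.5 * (q[2] - q[1]))
  }
  cut_s <- fence(med)
  sample_flags <- med < cut_s
  series_flags <- cut_g <- NULL
  if (!is.null(qc$meta)) {
    ser <- tapply(med[qc$meta$sample_id], qc$meta$series_id, mean)
    cut_g <- fence(as.numeric(ser))
    series_flags <- setNames(as.numeric(ser) < cut_g, names(ser))
  }
  list(sample_flags = sample_flags, series_flags = series_flags,
       cutoff_samples = cut_s, cutoff_series = cut_g)
}

#' Per-array detection threshold from negative controls
#'
#' The threshold of an array is the 95th percentile of its negative-control
#' raw intensities, with linear interpolation between closest ranks
#' (0-based index 0.95 (n-1)).  A pooled mode uses all arrays' controls at
#' once.
#'
#' @param negctl numeric matrix of raw control intensities, controls x
#'   arrays.
#' @param percentile percentile in (0, 1); default 0.95.
#' @param pooled if TRUE a single threshold from the pooled controls is
#'   replicated across arrays.
#' @return named numeric vector, one threshold per array.
#' @export
detection_threshold <- function(negctl, percentile = 0.95, pooled = FALSE) {
  check_fraction(percentile, "percentile")
  if (nrow(negctl) < 20) abort("need >= 20 negative controls per array")
  if (pooled) {
    th <- quantile(as.numeric(negctl), percentile, type = 7, names = FALSE)
    return(setNames(rep(th, ncol(negctl)), colnames(negctl)))
  }
  apply(negctl, 2, quantile, probs = percentile, type = 7, names = FALSE)
}

#' Call detection against per-array thresholds
#'
#' A probe is detected on an array iff its raw intensity strictly exceeds
#' that array's threshold.
#'
#' @param matrix `signal_matrix` on the raw scale.
#' @param thresholds named vector from [detection_threshold()] covering
#'   every array of the matrix.
#' @return logical matrix, probes x samples.
#' @export
call_detection <- function(matrix, thresholds) {
  stopifnot(inherits(matrix, "signal_matrix"))
  if (matrix$scale != "raw") abort("detection is called on raw intensities")
  v <- matrix$values
  if (!all(colnames(v) %in% names(thresholds)))
    abort("missing detection threshold for some arrays")
  sweep(v, 2, thresholds[colnames(v)], ">")
}

#' Drop probes never detected in any sample
#'
#' @param det logical detection matrix.
#' @return list: `kept` (probe ids), `dropped` (probe ids), `n_dropped`.
#' @export
drop_never_expressed <- function(det) {
  never <- rowSums(det) == 0
  list(kept = rownames(det)[!never], dropped = rownames(det)[never],
       n_dropped = sum(never))
}

#' Tissue expression and specificity summary
#'
#' A probe is expressed in a tissue iff it is detected in strictly more
#' than `frac` of that tissue's samples.  Tissue-specific probes are those
#' expressed in exactly one tissue.
#'
#' @param det logical detection matrix (probes x samples).
#' @param meta sample metadata with sample_id and tissue covering every
#'   column of `det`.
#' @param frac detection fraction threshold (default 0.65).
#' @return list of class `tissue_expression`: `expressed` (probes x
#'   tissues logical), `n_tissues` (per-probe count), `expressed_sets` and
#'   `specific_sets` (per-tissue probe id lists), `frac`.
#' @export
tissue_expression <- function(det, meta, frac = 0.65) {
  check_fraction(frac, "frac")
  unknown <- setdiff(colnames(det), meta$sample_id)
  if (length(unknown)) abort("samples without metadata: %s",
                             paste(head(unknown, 3), collapse = ", "))
  tissue <- meta$tissue[match(colnames(det), meta$sample_id)]
  tl <- unique(meta$tissue)
  expr <- matrix(FALSE, nrow(det), length(tl),
                 dimnames = list(rownames(det), tl))
  for (t in tl) {
    cols <- tissue == t
    if (!any(cols)) abort("tissue %s has no samples", t)
    expr[, t] <- rowMeans(det[, cols, drop = FALSE]) > frac
  }
  n_tis <- rowSums(expr)
  specific <- lapply(tl, function(t) rownames(expr)[expr[, t] & n_tis == 1])
  names(specific) <- tl
  structure(list(expressed = expr, n_tissues = n_tis,
                 expressed_sets = lapply(tl, function(t) rownames(expr)[expr[, t]]) |>
                   setNames(tl),
                 specific_sets = specific, frac = frac),
            class = "tissue_expression")
}

#' Expression breadth report by probe category
#'
#' Cross-tabulates, per category (mRNA vs lncRNA), how many probes are
#' expressed in 0, 1, ..., T tissues, with within-category percentages, and
#' reports per-tissue expressed totals.
#'
#' @param summary a `tissue_expression`.
#' @param labels consensus label data.frame (probe_id, final_class) for the
#'   same probes.
#' @return list: `breadth` (data.frame n_tissues x category counts and
#'   percentages), `per_tissue` (tissue, n_expressed, n_mRNA, n_lncRNA).
#' @export
expression_breadth_report <- function(summary, labels) {
  stopifnot(inherits(summary, "tissue_expression"))
  cls <- setNames(labels$final_class, labels$probe_id)
  ids <- rownames(summary$expressed)
  cls <- cls[ids]
  nt <- summary$n_tissues
  tmax <- ncol(summary$expressed)
  breadth <- do.call(rbind, lapply(0:tmax, function(k) {
    sel <- nt == k
    n_m <- sum(sel & cls == "mRNA", na.rm = TRUE)
    n_l <- sum(sel & cls == "lncRNA", na.rm = TRUE)
    data.frame(n_tissues = k, n_mRNA = n_m, n_lncRNA = n_l)
  }))
  tot_m <- sum(breadth$n_mRNA)
  tot_l <- sum(breadth$n_lncRNA)
  breadth$pct_mRNA <- if (tot_m > 0) 100 * breadth$n_mRNA / tot_m else 0
  breadth$pct_lncRNA <- if (tot_l > 0) 100 * breadth$n_lncRNA / tot_l else 0
  per_tissue <- do.call(rbind, lapply(colnames(summary$expressed), function(t) {
    sel <- summary$expressed[, t]
    data.frame(tissue = t, n_expressed = sum(sel),
               n_mRNA = sum(sel & cls == "mRNA", na.rm = TRUE),
               n_lncRNA = sum(sel & cls == "lncRNA", na.rm = TRUE))
  }))
  per_tissue <- per_tissue[order(-per_tissue$n_expressed), ]
  rownames(per_tissue) <- NULL
  list(breadth = breadth, per_tissue = per_tissue)
}
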