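#' Reporting arithmetic for compendium summaries
#'
#' Small, exact bookkeeping operations used when summarizing an annotated
#' compendium: class shares, retained totals and module sizes from
#' composition counts.  They operate on plain counts so the same code
#' serves synthetic runs and published platform figures.
#'
#' @name reporting
NULL

#' @describeIn reporting percentage share of a count within a total.
#' @param count,total non-negative counts, total > 0.
#' @return a percentage on the 0-100 scale.
#' @export
share_pct <- function(count, total) {
  if (total <= 0 || count < 0 || count > total)
    abort("need 0 <= count <= total with total > 0")
  100 * count / total
}

#' @describeIn reporting lincRNA vs genic shares of the lncRNA probe set.
#' @param n_lincRNA,n_genic counts of intergenic and genic (intronic +
#'   antisense) lncRNA probes.
#' @return list: total, lincRNA_pct, genic_pct.
#' @export
lnc_subclass_shares <- function(n_lincRNA, n_genic) {
  total <- n_lincRNA + n_genic
  list(total = total,
       lincRNA_pct = share_pct(n_lincRNA, total),
       genic_pct = share_pct(n_genic, total))
}

#' @describeIn reporting total probes retained = mRNA + lncRNA probes.
#' @param n_mRNA,n_lncRNA retained probe counts per category.
#' @export
retained_total <- function(n_mRNA, n_lncRNA) {
  stopifnot(n_mRNA >= 0, n_lncRNA >= 0)
  n_mRNA + n_lncRNA
}

#' @describeIn reporting module size from its composition counts
#'   (non-TF mRNAs + lncRNAs + TFs).
#' @param n_mRNA_non_tf,n_lnc,n_tf composition counts.
#' @export
module_size_from_counts <- function(n_mRNA_non_tf, n_lnc, n_tf) {
  stopifnot(n_mRNA_non_tf >= 0, n_lnc >= 0, n_tf >= 0)
  n_mRNA_non_tf + n_lnc + n_tf
}
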