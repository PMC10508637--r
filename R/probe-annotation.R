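#' Classify probes against one annotation source
#'
#' Implements the per-database reannotation rules: a probe is an mRNA probe
#' if it overlaps at least one exon of a protein-coding gene on the same
#' strand; an intronic lncRNA probe if it lies fully within an intron of a
#' same-strand gene (and touches no exon); an antisense lncRNA probe if it
#' overlaps a gene body on the opposite strand; and a lincRNA probe if it
#' overlaps no gene body on either strand.  A probe qualifying both as mRNA
#' and as any lncRNA category within the same source is `ambiguous` (such
#' probes are discarded at consensus).  Probes overlapping a same-strand
#' gene body without satisfying the exon or intron rule (boundary spanners)
#' are also routed to `ambiguous`, the conservative choice.
#'
#' When a probe qualifies as both intronic and antisense (two different
#' genes), antisense takes precedence; this is not ambiguity, which is
#' strictly an mRNA-vs-lncRNA conflict.
#'
#' @param probes a `probe_alignments` data.frame.
#' @param source an `annotation_source`.
#' @return character vector (one per probe) in
#'   {"mRNA","intronic_lncRNA","antisense_lncRNA","lincRNA","ambiguous"}.
#' @export
classify_probes_one_source <- function(probes, source) {
  pg <- probes_gr(probes)
  gn <- genes_gr(source)
  ex <- exons_gr(source)
  n <- length(pg)
  if (n == 0) return(character(0))

  hit <- function(query, subject, ...) {
    # probes on chromosomes absent from the source are a legitimate
    # no-overlap case, not worth a seqlevel warning
    ov <- suppressWarnings(GenomicRanges::findOverlaps(query, subject, ...))
    tabulate(queryHits(ov), nbins = n) > 0
  }
  pg_flip <- pg
  strand(pg_flip) <- ifelse(as.character(strand(pg)) == "+", "-", "+")

  exon_ss <- hit(pg, ex)                       # exon overlap, same strand
  gene_ss <- hit(pg, gn)                       # gene-body overlap, same strand
  gene_os <- hit(pg_flip, gn)                  # gene-body overlap, opposite
  if (nrow(source$exons) > nrow(source$genes)) {
    intr <- introns_gr(source)
    in_intron <- hit(pg, intr, type = "within")
  } else in_intron <- rep(FALSE, n)

  mRNA_f <- exon_ss
  intronic_f <- in_intron & !exon_ss
  antisense_f <- gene_os
  linc_f <- !gene_ss & !gene_os

  out <- rep("ambiguous", n)
  amb <- mRNA_f & (intronic_f | antisense_f)
  out[!amb & mRNA_f] <- "mRNA"
  rest <- !amb & !mRNA_f
  out[rest & antisense_f] <- "antisense_lncRNA"
  out[rest & !antisense_f & intronic_f] <- "intronic_lncRNA"
  out[rest & !antisense_f & !intronic_f & linc_f] <- "lincRNA"
  # remaining: same-strand genic boundary spanners stay "ambiguous"
  out
}

#' Consensus probe classification across annotation sources
#'
#' One database suffices to call a probe mRNA; a lncRNA call requires all
#' databases to concur on some lncRNA category; any per-source ambiguity
#' discards the probe.  The lncRNA subclass is the majority of per-source
#' subclasses, ties broken by the fixed priority antisense > intronic >
#' lincRNA.
#'
#' @param per_source data.frame or matrix of per-source classes, one row
#'   per probe, one column per source (values as returned by
#'   [classify_probes_one_source()]).
#' @param probe_id optional probe identifiers (default rownames or P<i>).
#' @return data.frame with columns probe_id, final_class
#'   ("mRNA"/"lncRNA"/"discarded") and subclass
#'   ("intronic"/"antisense"/"lincRNA"/"none").
#' @export
classify_consensus <- function(per_source, probe_id = NULL) {
  per_source <- as.matrix(per_source)
  if (ncol(per_source) == 0 || nrow(per_source) == 0)
    abort("empty per-source class table")
  if (is.null(probe_id))
    probe_id <- rownames(per_source) %||% paste0("P", seq_len(nrow(per_source)))

  lnc_classes <- c("antisense_lncRNA", "intronic_lncRNA", "lincRNA")
  sub_of <- c(antisense_lncRNA = "antisense", intronic_lncRNA = "intronic",
              lincRNA = "lincRNA")

  res <- apply(per_source, 1, function(cl) {
    if (anyNA(cl) || any(cl == "ambiguous")) return(c("discarded", "none"))
    if (any(cl == "mRNA")) return(c("mRNA", "none"))
    if (all(cl %in% lnc_classes)) {
      subs <- sub_of[cl]
      cnt <- table(factor(subs, levels = c("antisense", "intronic", "lincRNA")))
      # which.max on the priority-ordered table applies the tie-break
      return(c("lncRNA", names(cnt)[which.max(cnt)]))
    }
    c("discarded", "none")
  })
  data.frame(probe_id = probe_id, final_class = res[1, ], subclass = res[2, ],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Distance-based categorization of lincRNA probes
#'
#' For each probe, finds the nearest gene body (gap distance; touching
#' intervals have distance 0; ties broken by smaller gene_id) and assigns a
#' category: `utr_extension_candidate` if within 1 kb (inclusive) on the
#' same strand, `far` if more than 50 kb away, else `distal`.
#'
#' @param probes `probe_alignments` (intended: consensus-lincRNA probes).
#' @param source an `annotation_source` providing the gene models.
#' @return data.frame: probe_id, nearest_gene_id, distance, same_strand,
#'   category.
#' @export
lincRNA_distance_category <- function(probes, source) {
  genes <- source$genes
  if (nrow(genes) == 0) abort("no genes in source; distance undefined")
  out <- lapply(seq_len(nrow(probes)), function(i) {
    p <- probes[i, ]
    g <- genes[genes$chrom == p$chrom, , drop = FALSE]
    if (nrow(g) == 0)
      return(data.frame(probe_id = p$probe_id, nearest_gene_id = NA_character_,
                        distance = NA_real_, same_strand = NA,
                        category = NA_character_, stringsAsFactors = FALSE))
    d <- pmax(0, pmax(g$start - p$end - 1L, p$start - g$end - 1L))
    j <- order(d, g$gene_id)[1]              # tie -> smaller gene_id
    same <- g$strand[j] == p$strand
    cat <- if (d[j] <= 1000 && same) "utr_extension_candidate"
           else if (d[j] > 50000) "far" else "distal"
    data.frame(probe_id = p$probe_id, nearest_gene_id = g$gene_id[j],
               distance = d[j], same_strand = same, category = cat,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Deduplicate probes targeting the same gene by mean signal
#'
#' When several probes target one gene, only the probe with the highest
#' row-mean signal is kept (ties: lexicographically smallest probe_id).
#' Probes with no gene assignment (lncRNAs) are all kept.
#'
#' @param probe_gene data.frame with columns probe_id, gene_id (gene_id NA
#'   for unassigned probes).
#' @param matrix a `signal_matrix` (or plain matrix with probe rownames).
#' @return character vector of kept probe ids.
#' @export
deduplicate_by_mean_signal <- function(probe_gene, matrix) {
  vals <- if (inherits(matrix, "signal_matrix")) matrix$values else matrix
  missing <- setdiff(probe_gene$probe_id, rownames(vals))
  if (length(missing))
    abort("probes missing from matrix: %s",
          paste(head(missing, 3), collapse = ", "))
  keep_free <- probe_gene$probe_id[is.na(probe_gene$gene_id)]
  assigned <- probe_gene[!is.na(probe_gene$gene_id), , drop = FALSE]
  if (nrow(assigned) == 0) return(sort(keep_free))
  m <- rowMeans(vals[assigned$probe_id, , drop = FALSE])
  assigned <- assigned[order(assigned$gene_id, -m, assigned$probe_id), ]
  kept <- assigned$probe_id[!duplicated(assigned$gene_id)]
  sort(c(keep_free, kept))
}

#' Per-chromosome probe counts, densities and mRNA/lncRNA correlation
#'
#' Counts consensus mRNA and lncRNA probes per chromosome, derives per-Mb
#' densities and reports the Pearson correlation (on raw counts) between
#' the two, mirroring the chromosome-density summary of reannotation
#' studies.
#'
#' @param labels consensus label data.frame (from [classify_consensus()])
#'   with an added `chrom` column, or any data.frame with columns chrom and
#'   final_class.
#' @param genome a `genome_model`.
#' @return list with `table` (chrom, length, n_mRNA, n_lncRNA,
#'   mRNA_per_mb, lncRNA_per_mb) and `correlation` (r, p; NaN if a count
#'   vector is constant).
#' @export
chromosome_density <- function(labels, genome) {
  if (any(genome$length <= 0)) abort("zero-length chromosome")
  if (nrow(genome) < 3) abort("need >= 3 chromosomes for a correlation")
  tab <- data.frame(chrom = genome$chrom, length = genome$length)
  cnt <- function(cls) {
    t <- table(factor(labels$chrom[labels$final_class == cls],
                      levels = genome$chrom))
    as.integer(t)
  }
  tab$n_mRNA <- cnt("mRNA")
  tab$n_lncRNA <- cnt("lncRNA")
  tab$mRNA_per_mb <- tab$n_mRNA / (tab$length / 1e6)
  tab$lncRNA_per_mb <- tab$n_lncRNA / (tab$length / 1e6)
  if (sd(tab$n_mRNA) == 0 || sd(tab$n_lncRNA) == 0) {
    warning("constant per-chromosome counts; correlation undefined")
    corr <- list(r = NaN, p = NaN)
  } else {
    ct <- cor.test(tab$n_mRNA, tab$n_lncRNA, method = "pearson")
    corr <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  list(table = tab, correlation = corr)
}
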