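#' Genome model
#'
#' A minimal genome: chromosome names and lengths.  Stands in for a
#' reference assembly when working with synthetic data.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @return a data.frame of class `genome_model` with columns chrom, length.
#' @export
genome_model <- function(chrom, length) {
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length <= 0))
    abort("chromosome lengths must be positive")
  structure(data.frame(chrom = as.character(chrom), length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_model", "data.frame"))
}

#' Annotation source
#'
#' One database's view of the protein-coding gene models: an exon table
#' (1-based closed coordinates) from which gene bodies are derived.
#'
#' @param source_name identifier, e.g. "ucsc".
#' @param exons data.frame with columns gene_id, chrom, strand ("+"/"-"),
#'   start, end (1-based, closed).  Exons of one gene must be disjoint.
#' @return list of class `annotation_source` with elements source_name,
#'   exons (sorted) and genes (one row per gene: gene body span).
#' @export
annotation_source <- function(source_name, exons) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(exons))) abort("exon table needs columns %s",
                                          paste(need, collapse = ", "))
  if (any(exons$end < exons$start)) abort("exon end < start")
  if (!all(exons$strand %in% c("+", "-"))) abort("strand must be + or -")
  exons <- exons[order(exons$gene_id, exons$start), need, drop = FALSE]
  rownames(exons) <- NULL
  # disjointness within gene
  by_gene <- split(exons, exons$gene_id)
  for (g in by_gene) {
    if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)]))
      abort("overlapping exons in gene %s", g$gene_id[1])
    if (length(unique(g$chrom)) > 1 || length(unique(g$strand)) > 1)
      abort("gene %s spans chromosomes or strands", g$gene_id[1])
  }
  genes <- do.call(rbind, c(list(
    data.frame(gene_id = character(0), chrom = character(0),
               strand = character(0), start = numeric(0), end = numeric(0),
               n_exons = integer(0), stringsAsFactors = FALSE)),
    lapply(by_gene, function(g) {
      data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
                 strand = g$strand[1], start = min(g$start), end = max(g$end),
                 n_exons = nrow(g), stringsAsFactors = FALSE)
    })))
  rownames(genes) <- NULL
  structure(list(source_name = source_name, exons = exons, genes = genes),
            class = "annotation_source")
}

#' @export
print.annotation_source <- function(x, ...) {
  cat(sprintf("annotation_source '%s': %d genes, %d exons\n",
              x$source_name, nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Probe alignment table
#'
#' @param probe_id,chrom,start,end,strand vectors describing mapped probes;
#'   coordinates 1-based closed.
#' @return data.frame of class `probe_alignments`.
#' @export
probe_alignments <- function(probe_id, chrom, start, end, strand) {
  if (anyDuplicated(probe_id)) abort("probe ids must be unique")
  if (any(end < start)) abort("probe end < start")
  if (!all(strand %in% c("+", "-"))) abort("probe strand must be + or -")
  structure(data.frame(probe_id = as.character(probe_id),
                       chrom = as.character(chrom),
                       start = as.integer(start), end = as.integer(end),
                       strand = as.character(strand),
                       stringsAsFactors = FALSE),
            class = c("probe_alignments", "data.frame"))
}

# internal: GRanges views of the model objects
genes_gr <- function(source) {
  with(source$genes,
       GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand, gene_id = gene_id))
}
exons_gr <- function(source) {
  with(source$exons,
       GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand, gene_id = gene_id))
}
introns_gr <- function(source) {
  ex <- exons_gr(source)
  grl <- S4Vectors::split(ex, ex$gene_id)
  ir <- IRanges::psetdiff(unlist(range(grl)), grl)
  out <- unlist(ir)
  out$gene_id <- rep(names(ir), lengths(ir))
  names(out) <- NULL
  out
}
probes_gr <- function(probes) {
  with(probes, GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                      strand = strand, probe_id = probe_id))
}

#' Write / read annotation sources as GFF3
#'
#' Gene bodies are emitted as `gene` features and exons as `exon` features
#' with a `Parent` attribute; coordinates follow the GFF3 1-based closed
#' convention (the in-memory model already uses it).
#'
#' @param source an `annotation_source`.
#' @param path output/input file path.
#' @return `write_annotation_gff3` returns `path` invisibly;
#'   `read_annotation_gff3` returns an `annotation_source`.
#' @export
write_annotation_gff3 <- function(source, path) {
  g <- genes_gr(source)
  g$type <- "gene"
  g$ID <- g$gene_id
  e <- exons_gr(source)
  e$type <- "exon"
  e$Parent <- e$gene_id
  gr <- c(g, e)
  gr$source <- source$source_name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @param source_name name to give the source; default basename of path.
#' @export
read_annotation_gff3 <- function(path, source_name = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  parent <- as.character(if (!is.null(ex$Parent)) unlist(ex$Parent) else ex$gene_id)
  annotation_source(
    source_name %||% sub("\\.gff3?$", "", basename(path)),
    data.frame(gene_id = parent, chrom = as.character(seqnames(ex)),
               strand = as.character(strand(ex)),
               start = start(ex), end = end(ex), stringsAsFactors = FALSE))
}

#' Write / read probe alignments as BED6
#'
#' BED is 0-based half-open on disk; rtracklayer converts to/from the
#' package's 1-based closed in-memory representation.
#'
#' @param probes a `probe_alignments` data.frame.
#' @param path file path.
#' @export
write_probes_bed <- function(probes, path) {
  gr <- probes_gr(probes)
  names(gr) <- gr$probe_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_probes_bed
#' @export
read_probes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  probe_alignments(gr$name, as.character(seqnames(gr)), start(gr), end(gr),
                   as.character(strand(gr)))
}
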