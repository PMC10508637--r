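#' Simulation design
#'
#' Bundles every knob of the synthetic-data generator.  Defaults emulate the
#' structure of the real compendium: five tissue classes with strongly
#' unequal sample counts (468 samples over 62 series), 757 negative-control
#' probes, probe-class proportions mirroring the reannotated platform
#' (~100x scaled down), planted co-expression modules whose eigengenes are
#' tissue-linked, and planted tissue-specific probe sets.
#'
#' @param seed integer RNG seed; all generator functions are deterministic
#'   given the design.
#' @param n_genes number of protein-coding genes shared by the sources.
#' @param n_chromosomes chromosomes; genes are spread over them with
#'   decreasing weights so per-chromosome counts vary.
#' @param probe_length probe length in bp (60-mer platform).
#' @param n_probes_per_class named counts for classes mRNA, intronic,
#'   antisense, lincRNA.
#' @param annotation_disagreement_rate per-gene probability that one source
#'   perturbs the gene (drop / strand flip / shift by 2x probe length).
#' @param tissues data.frame(tissue, n_samples, n_series).
#' @param n_modules,module_sizes planted co-expression modules.
#' @param module_tissue_map tissue driving each module's eigengene.
#' @param within_module_cor target expected pairwise correlation within a
#'   module.
#' @param tissue_effect latent-factor mean shift (in factor SD units) for
#'   samples of the module's driving tissue.
#' @param noise_sd residual SD (log2 units) of expressed probes; must be
#'   > 0.
#' @param n_negative_controls rows drawn from the background distribution
#'   (default 757 = 604 DarkCorner-like + 153 structural-like).
#' @param signal_over_background log2 offset of expressed probes above the
#'   negative-control background (default 4, so detection is unambiguous).
#' @param background_log2_mean,background_log2_sd background (log-normal)
#'   parameters on the log2 scale.
#' @param tissue_specific_sets named counts of probes expressed only in one
#'   tissue (the oocyte is given the largest set, as in the real data).
#' @param n_never_expressed probes planted below background everywhere.
#' @param n_tfs,n_hkg mRNA probes flagged as transcription factors /
#'   housekeeping genes in the emitted lists.
#' @param series_effect_sd SD of an optional additive per-series log2
#'   offset (default 0 = off); used to exercise outlier screening.
#' @param linc_strata proportions of lincRNA probes placed <=1 kb (same
#'   strand), 1-50 kb, and > 50 kb from the nearest gene (defaults mirror
#'   the reported 9 % / 82 % / 21 % split: 9/70/21).
#' @return validated list of class `sim_design`.
#' @export
simulation_design <- function(
    seed = 1L,
    n_genes = 120,
    n_chromosomes = 8,
    probe_length = 60,
    n_probes_per_class = c(mRNA = 141, intronic = 10, antisense = 15,
                           lincRNA = 53),
    annotation_disagreement_rate = 0,
    tissues = data.frame(
      tissue = c("blastocyst", "granulosa", "oocyte", "cumulus", "two_cell"),
      n_samples = c(217, 159, 52, 28, 12),
      n_series = c(20, 18, 12, 8, 4)),
    n_modules = 5,
    module_sizes = rep(30, 5),
    module_tissue_map = NULL,
    within_module_cor = 0.8,
    tissue_effect = 3,
    noise_sd = 1,
    n_negative_controls = 757,
    signal_over_background = 4,
    background_log2_mean = 6,
    background_log2_sd = 0.5,
    tissue_specific_sets = c(oocyte = 12, blastocyst = 8, granulosa = 6,
                             cumulus = 6, two_cell = 4),
    n_never_expressed = 5,
    n_tfs = 15,
    n_hkg = 20,
    series_effect_sd = 0,
    linc_strata = c(utr = 0.09, distal = 0.70, far = 0.21)) {
  check_fraction(annotation_disagreement_rate, "annotation_disagreement_rate")
  check_fraction(within_module_cor, "within_module_cor")
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  if (n_genes < 1 || n_chromosomes < 1) abort("need genes and chromosomes")
  if (length(module_sizes) != n_modules)
    abort("module_sizes must have length n_modules")
  if (any(module_sizes < 2)) abort("module sizes must be >= 2")
  if (is.null(module_tissue_map))
    module_tissue_map <- rep_len(tissues$tissue, n_modules)
  if (!all(module_tissue_map %in% tissues$tissue))
    abort("module_tissue_map names unknown tissues")
  if (!all(names(tissue_specific_sets) %in% tissues$tissue))
    abort("tissue_specific_sets names unknown tissues")
  stopifnot(all(n_probes_per_class >= 0), n_negative_controls >= 0)
  n_probes <- sum(n_probes_per_class)
  if (sum(module_sizes) + sum(tissue_specific_sets) + n_never_expressed >
      n_probes)
    abort("not enough probes for the requested planted structure")
  if (abs(sum(linc_strata) - 1) > 1e-8) abort("linc_strata must sum to 1")
  structure(as.list(environment()), class = "sim_design")
}

#' Simulate a genome and three disagreeing annotation sources
#'
#' Builds a shared set of multi-exon gene models laid out with large
#' intergenic gaps (so every lincRNA distance stratum has room), then
#' derives three sources; each gene is independently perturbed in one
#' randomly chosen source with probability
#' `annotation_disagreement_rate` (kind drawn uniformly from drop /
#' strand flip / shift by twice the probe length).
#'
#' @param design a `sim_design`.
#' @return list: `genome` (genome_model), `sources` (list of 3
#'   annotation_source: ucsc, ensembl, ncbi), `base` (the unperturbed
#'   source, the ground truth), `perturbation_log` (gene_id, source, kind).
#' @export
simulate_annotation <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  nch <- design$n_chromosomes
  w <- rev(seq_len(nch))
  counts <- floor(design$n_genes * w / sum(w))
  rem <- design$n_genes - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1

  exon_rows <- list()
  chrom_len <- numeric(nch)
  gid <- 0
  for (c in seq_len(nch)) {
    pos <- round(runif(1, 110e3, 160e3))
    for (j in seq_len(counts[c])) {
      gid <- gid + 1
      n_ex <- sample(2:4, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(500:2000, n_ex - 1, replace = TRUE) else integer(0)
      starts <- pos + cumsum(c(0, ex_len[-n_ex] + in_len))
      ends <- starts + ex_len - 1
      strand <- sample(c("+", "-"), 1)
      exon_rows[[gid]] <- data.frame(
        gene_id = sprintf("G%04d", gid), chrom = paste0("chr", c),
        strand = strand, start = starts, end = ends,
        stringsAsFactors = FALSE)
      pos <- ends[n_ex] + round(runif(1, 110e3, 160e3))
    }
    chrom_len[c] <- pos
  }
  base_exons <- do.call(rbind, exon_rows)
  genome <- genome_model(paste0("chr", seq_len(nch)), chrom_len)
  base <- annotation_source("truth", base_exons)

  gene_ids <- unique(base_exons$gene_id)
  hit <- runif(length(gene_ids)) < design$annotation_disagreement_rate
  src_names <- c("ucsc", "ensembl", "ncbi")
  log <- data.frame(gene_id = gene_ids[hit],
                    source = sample(src_names, sum(hit), replace = TRUE),
                    kind = sample(c("drop", "strand_flip", "shift"),
                                  sum(hit), replace = TRUE),
                    stringsAsFactors = FALSE)
  sources <- lapply(src_names, function(s) {
    ex <- base_exons
    for (k in which(log$source == s)) {
      g <- log$gene_id[k]
      rows <- ex$gene_id == g
      ex <- switch(log$kind[k],
        drop = ex[!rows, , drop = FALSE],
        strand_flip = { ex$strand[rows] <- ifelse(ex$strand[rows] == "+", "-", "+"); ex },
        shift = { sh <- 2L * design$probe_length
                  ex$start[rows] <- ex$start[rows] + sh
                  ex$end[rows] <- ex$end[rows] + sh; ex })
    }
    annotation_source(s, ex)
  })
  names(sources) <- src_names
  list(genome = genome, sources = sources, base = base,
       perturbation_log = log)
}

# internal: intergenic gap after each gene of the unperturbed annotation
gaps_after_genes <- function(base, genome) {
  g <- base$genes[order(base$genes$chrom, base$genes$start), ]
  out <- lapply(split(g, g$chrom), function(gc) {
    clen <- genome$length[match(gc$chrom[1], genome$chrom)]
    nxt <- c(gc$start[-1], clen + 1)
    data.frame(gene_id = gc$gene_id, gene_end = gc$end, gene_strand = gc$strand,
               chrom = gc$chrom, gap = nxt - gc$end - 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate probe alignments with known true classes
#'
#' Probes are placed against the unperturbed annotation so that their class
#' is true by construction under the classification rules: inside an exon on
#' the same strand (mRNA), fully within an intron on the same strand
#' (intronic), inside an opposite-strand gene body (antisense), or in
#' intergenic space (lincRNA, with placement distances covering the
#' <=1 kb same-strand, 1-50 kb and > 50 kb strata).
#'
#' @param annotation result of [simulate_annotation()].
#' @param design the `sim_design`.
#' @return list: `probes` (probe_alignments), `truth` (probe_id,
#'   true_class, linc_stratum, gene_id).
#' @export
simulate_probes <- function(annotation, design) {
  set.seed(design$seed + 1L)
  base <- annotation$base
  plen <- design$probe_length
  genes <- base$genes
  exons <- base$exons
  req <- design$n_probes_per_class
  rows <- list()

  add <- function(chrom, start, strand, class, stratum = NA, gene = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      chrom = chrom, start = start, end = start + plen - 1L, strand = strand,
      true_class = class, linc_stratum = stratum, gene_id = gene,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(req[["mRNA"]] %||% 0)) {
    ex <- exons[sample(nrow(exons), 1), ]
    if (ex$end - ex$start + 1 < plen) abort("exon too short for probe")
    s <- ex$start + sample.int(ex$end - ex$start + 2 - plen, 1) - 1L
    add(ex$chrom, s, ex$strand, "mRNA", gene = ex$gene_id)
  }

  n_intr <- req[["intronic"]] %||% 0
  if (n_intr > 0) {
    multi <- genes$gene_id[genes$n_exons >= 2]
    if (length(multi) == 0)
      abort("cannot place intronic probes: no multi-exon genes")
    intr <- as.data.frame(introns_gr(base))
    intr <- intr[intr$width >= plen + 2, , drop = FALSE]
    if (nrow(intr) == 0) abort("cannot place intronic probes: introns too short")
    for (i in seq_len(n_intr)) {
      iv <- intr[sample(nrow(intr), 1), ]
      s <- iv$start + 1L + sample.int(iv$width - plen - 1, 1) - 1L
      add(as.character(iv$seqnames), s, as.character(iv$strand),
          "intronic_lncRNA", gene = iv$gene_id)
    }
  }

  for (i in seq_len(req[["antisense"]] %||% 0)) {
    g <- genes[sample(nrow(genes), 1), ]
    s <- g$start + sample.int(g$end - g$start + 2 - plen, 1) - 1L
    add(g$chrom, s, ifelse(g$strand == "+", "-", "+"), "antisense_lncRNA",
        gene = g$gene_id)
  }

  n_linc <- req[["lincRNA"]] %||% 0
  if (n_linc > 0) {
    ns <- round(design$linc_strata * n_linc)
    ns[1] <- n_linc - sum(ns[-1])
    gaps <- gaps_after_genes(annotation$base, annotation$genome)
    place_linc <- function(stratum) {
      ok <- switch(stratum,
        utr = gaps$gap > 1000 + plen,
        distal = gaps$gap > 21000 + plen,
        far = gaps$gap > 100002 + plen)
      g <- gaps[ok, , drop = FALSE][sample(sum(ok), 1), ]
      d <- switch(stratum,
        utr = sample(100:1000, 1),
        distal = sample(1001:20000, 1),
        far = sample(50001:(g$gap - plen - 50001), 1))
      strand <- if (stratum == "utr") g$gene_strand else sample(c("+", "-"), 1)
      add(g$chrom, g$gene_end + d + 1L, strand, "lincRNA",
          stratum = stratum, gene = g$gene_id)
    }
    for (st in names(ns)) for (i in seq_len(ns[[st]])) place_linc(st)
  }

  tab <- do.call(rbind, rows)
  tab$probe_id <- sprintf("P%04d", seq_len(nrow(tab)))
  probes <- probe_alignments(tab$probe_id, tab$chrom, tab$start, tab$end,
                             tab$strand)
  truth <- tab[, c("probe_id", "true_class", "linc_stratum", "gene_id")]
  rownames(truth) <- NULL
  list(probes = probes, truth = truth)
}

#' Signal matrix container
#'
#' @param values numeric matrix, probes in rows, samples in columns, with
#'   dimnames.
#' @param scale "raw" or "log2_normalized".
#' @return list of class `signal_matrix`.
#' @export
signal_matrix <- function(values, scale = c("raw", "log2_normalized")) {
  scale <- match.arg(scale)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("signal matrix needs probe and sample names")
  if (scale == "raw" && any(values <= 0))
    abort("raw intensities must be positive")
  structure(list(values = values, scale = scale), class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix [%s]: %d probes x %d samples\n", x$scale,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Simulate the expression compendium with planted structure
#'
#' Generates raw-scale intensities for all probes across all samples.
#' Members of a planted module share a latent factor (standardized; mean
#' shifted by `tissue_effect` SD in the module's driving tissue) mixed so
#' the expected pairwise within-module correlation equals
#' `within_module_cor`; the planted hub carries a boosted loading, giving it
#' the largest expected correlation sum in its module.  Tissue-specific
#' probes sit `signal_over_background` log2 units above background only in
#' their own tissue.  Negative controls (and probes planted as never
#' expressed) are drawn from the log-normal background.
#'
#' @param probes result of [simulate_probes()] (or any list with elements
#'   probes, truth).
#' @param design the `sim_design`.
#' @return list: `matrix` (signal_matrix, raw scale), `meta` (sample_id,
#'   series_id, tissue), `negctl` (raw matrix of control rows), `truth`
#'   (module/hub/tissue-specific assignments plus TF and HKG id lists).
#' @export
simulate_expression <- function(probes, design) {
  stopifnot(inherits(design, "sim_design"))
  if (design$noise_sd <= 0) abort("noise_sd must be > 0")
  if (nrow(design$tissues) == 0) abort("design has no tissues")
  set.seed(design$seed + 2L)

  tis <- design$tissues
  meta <- do.call(rbind, lapply(seq_len(nrow(tis)), function(i) {
    n <- tis$n_samples[i]
    series <- sprintf("SER_%s_%02d", tis$tissue[i],
                      rep_len(seq_len(tis$n_series[i]), n))
    data.frame(tissue = tis$tissue[i], series_id = series,
               stringsAsFactors = FALSE)
  }))
  meta$sample_id <- sprintf("S%04d", seq_len(nrow(meta)))
  meta <- meta[, c("sample_id", "series_id", "tissue")]
  ns <- nrow(meta)

  ids <- probes$truth$probe_id
  pool <- sample(ids)
  take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
  module_members <- lapply(design$module_sizes, take)
  names(module_members) <- paste0("M", seq_along(module_members))
  ts_sets <- lapply(design$tissue_specific_sets, take)
  never <- if (design$n_never_expressed > 0) take(design$n_never_expressed)
           else character(0)

  mu_bg <- design$background_log2_mean
  sd_bg <- design$background_log2_sd
  sob <- design$signal_over_background

  x <- matrix(0, length(ids), ns, dimnames = list(ids, meta$sample_id))
  mu <- mu_bg + sob + rnorm(length(ids), 0, 0.5)
  names(mu) <- ids
  for (i in seq_along(ids))
    x[i, ] <- mu[i] + rnorm(ns, 0, design$noise_sd)

  r <- design$within_module_cor
  amp <- 2
  hubs <- character(0)
  for (m in seq_along(module_members)) {
    mem <- module_members[[m]]
    drv <- design$module_tissue_map[m]
    f <- design$tissue_effect * (meta$tissue == drv) + rnorm(ns)
    f <- as.numeric(scale(f))
    rh <- r + 0.6 * (1 - r)
    for (j in seq_along(mem)) {
      rj <- if (j == 1) rh else r
      x[mem[j], ] <- mu[mem[j]] +
        amp * (sqrt(rj) * f + sqrt(1 - rj) * rnorm(ns))
    }
    hubs[names(module_members)[m]] <- mem[1]
  }

  for (t in names(ts_sets)) {
    own <- meta$tissue == t
    for (p in ts_sets[[t]]) {
      x[p, own] <- mu_bg + sob + rnorm(sum(own), 0, design$noise_sd)
      x[p, !own] <- rnorm(sum(!own), mu_bg, sd_bg)
    }
  }
  for (p in never) x[p, ] <- rnorm(ns, mu_bg - 2, sd_bg)

  negctl <- matrix(rnorm(design$n_negative_controls * ns, mu_bg, sd_bg),
                   design$n_negative_controls, ns,
                   dimnames = list(sprintf("NC%04d",
                                           seq_len(design$n_negative_controls)),
                                   meta$sample_id))

  if (design$series_effect_sd > 0) {
    ser <- unique(meta$series_id)
    off <- setNames(rnorm(length(ser), 0, design$series_effect_sd), ser)
    shift <- off[meta$series_id]
    x <- sweep(x, 2, shift, "+")
    negctl <- sweep(negctl, 2, shift, "+")
  }

  module <- setNames(rep("none", length(ids)), ids)
  for (m in names(module_members)) module[module_members[[m]]] <- m
  mrna_ids <- probes$truth$probe_id[probes$truth$true_class == "mRNA"]
  tf_ids <- sample(mrna_ids, min(design$n_tfs, length(mrna_ids)))
  hkg_ids <- sample(setdiff(mrna_ids, never),
                    min(design$n_hkg, length(setdiff(mrna_ids, never))))

  truth <- list(classes = probes$truth, module = module,
                module_tissue = setNames(design$module_tissue_map,
                                         names(module_members)),
                hubs = hubs, tissue_specific = ts_sets,
                never_expressed = never, tf_ids = sort(tf_ids),
                hkg_ids = sort(hkg_ids))
  list(matrix = signal_matrix(2^x, "raw"), meta = meta, negctl = 2^negctl,
       truth = truth)
}

#' Simulate gene-set collections with planted enrichment
#'
#' Builds a GMT-style collection over the mRNA probe ids: one planted set
#' per module (a sample of the module's mRNA members, so enrichment is
#' recoverable) plus random sets; namespace tags cycle through BP, CC, MF
#' and pathway.
#'
#' @param truth ground-truth list from [simulate_expression()].
#' @param n_random number of random (null) sets.
#' @param set_size size of each random set.
#' @param seed RNG seed.
#' @return list: `sets` (named list of ids), `namespaces` (named vector).
#' @export
simulate_gene_sets <- function(truth, n_random = 12, set_size = 15,
                               seed = 1L) {
  set.seed(seed + 3L)
  mrna <- truth$classes$probe_id[truth$classes$true_class == "mRNA"]
  sets <- list()
  for (m in unique(truth$module[truth$module != "none"])) {
    mem <- intersect(names(truth$module)[truth$module == m], mrna)
    if (length(mem) >= 3)
      sets[[paste0("SET_", m)]] <- sample(mem, max(3, ceiling(length(mem) * 0.8)))
  }
  for (i in seq_len(n_random))
    sets[[sprintf("SET_RAND%02d", i)]] <- sample(mrna, min(set_size, length(mrna)))
  ns <- setNames(rep_len(c("BP", "CC", "MF", "pathway"), length(sets)),
                 names(sets))
  list(sets = sets, namespaces = ns)
}

#' Run the full generator
#'
#' Convenience wrapper: annotation, probes and expression in one call.
#'
#' @param design a `sim_design`.
#' @return list with elements genome, sources, base, perturbation_log,
#'   probes, probe_truth, matrix, meta, negctl, truth.
#' @export
simulate_all <- function(design) {
  ann <- simulate_annotation(design)
  pr <- simulate_probes(ann, design)
  ex <- simulate_expression(pr, design)
  c(ann, list(probes = pr$probes, probe_truth = pr$truth), ex)
}
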