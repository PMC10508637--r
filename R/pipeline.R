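# Tabular I/O helpers -------------------------------------------------------

#' Read / write expression matrices and metadata as TSV
#'
#' Matrices are written with a leading `probe_id` column and samples in
#' columns.
#'
#' @param x matrix (or `signal_matrix`) / data.frame to write.
#' @param path file path.
#' @export
write_matrix_tsv <- function(x, path) {
  v <- if (inherits(x, "signal_matrix")) x$values else x
  df <- data.frame(probe_id = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param scale if non-NULL, wrap the matrix in a [signal_matrix()] with
#'   this scale.
#' @export
read_matrix_tsv <- function(path, scale = NULL) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (is.null(scale)) m else signal_matrix(m, scale)
}

#' @rdname write_matrix_tsv
#' @export
write_table_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_table_tsv <- function(path) read.delim(path, check.names = FALSE)

# Configuration --------------------------------------------------------------

#' Default pipeline configuration
#'
#' All stage parameters with their published defaults: soft power 12,
#' minimum module size 30, merge cut height 0.25, detection percentile
#' 0.95, tissue expression fraction 0.65, edge threshold r > 0.7 at
#' alpha 0.05, enrichment alpha 0.05 with q cap 0.2.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "annotate", "assemble", "network", "enrich",
               "hubs"),
    simulate = list(),                       # overrides for simulation_design()
    assemble = list(detection_percentile = 0.95, pooled_controls = FALSE,
                    tissue_fraction = 0.65, outlier_floor = 0.5),
    network = list(beta = 12, min_module_size = 30, merge_cut_height = 0.25,
                   cut_height = NULL),
    enrich = list(alpha = 0.05, q_cap = 0.2),
    hubs = list(r_min = 0.7, alpha = 0.05))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), injects defaults for omitted keys,
#' rejects unknown keys and out-of-range values.  All violations are
#' collected and reported together.
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return validated config list; errors abort with the full violation
#'   list, each naming its key path.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config))
    config <- if (file.exists(config) && file.size(config) > 0)
      yaml::read_yaml(config) else list()
  if (is.null(config)) config <- list()
  def <- default_config()
  errs <- character(0)
  bad_keys <- setdiff(names(config), names(def))
  if (length(bad_keys))
    errs <- c(errs, paste0("unknown key: ", bad_keys))
  for (sec in intersect(names(config), c("assemble", "network", "enrich",
                                         "hubs"))) {
    extra <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(extra))
      errs <- c(errs, paste0("unknown key: ", sec, ".", extra))
  }
  cfg <- modifyList(def, config[setdiff(names(config), bad_keys)])

  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && cfg$seed == as.integer(cfg$seed),
      "seed: must be an integer")
  chk(cfg$network$beta >= 1, "network.beta: must be >= 1")
  chk(cfg$network$min_module_size >= 2,
      "network.min_module_size: must be >= 2")
  chk(cfg$network$merge_cut_height >= 0 && cfg$network$merge_cut_height < 1,
      "network.merge_cut_height: must be in [0, 1)")
  chk(cfg$assemble$detection_percentile > 0 &&
        cfg$assemble$detection_percentile < 1,
      "assemble.detection_percentile: must be in (0, 1)")
  chk(cfg$assemble$tissue_fraction >= 0 && cfg$assemble$tissue_fraction < 1,
      "assemble.tissue_fraction: must be in [0, 1)")
  chk(cfg$enrich$alpha > 0 && cfg$enrich$alpha <= 1,
      "enrich.alpha: must be in (0, 1]")
  chk(cfg$enrich$q_cap > 0 && cfg$enrich$q_cap <= 1,
      "enrich.q_cap: must be in (0, 1]")
  chk(cfg$hubs$r_min >= 0 && cfg$hubs$r_min < 1,
      "hubs.r_min: must be in [0, 1)")
  chk(all(cfg$stages %in% def$stages), "stages: unknown stage name")
  if (length(errs)) abort("invalid configuration:\n  %s",
                          paste(errs, collapse = "\n  "))
  cfg
}

# internal: timestamped stage logging to stderr
stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

# Pipeline -------------------------------------------------------------------

#' Run the full synthetic pipeline
#'
#' Orchestrates simulate -> annotate -> assemble -> network -> enrich ->
#' hubs on synthetic data, writing each stage's outputs under `outdir`
#' before the next stage starts, and returns a machine-readable run
#' manifest with the filter-funnel counts (mapped -> classified ->
#' concordant -> deduplicated -> detected), per-file checksums and the
#' configuration hash.
#'
#' @param config a config list or YAML path (see [validate_config()]).
#' @param outdir output directory (created if needed).
#' @return the manifest (also written to `outdir`/manifest.json),
#'   invisibly; stage results are attached as attribute "results".
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("lncomp_run_")) {
  cfg <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  manifest <- list(package_version = as.character(utils::packageVersion("lncomp")),
                   config = cfg, funnel = list(), outputs = list())
  res <- list()
  emit <- function(name, writer) {
    p <- file.path(outdir, name)
    writer(p)
    paths[[name]] <<- p
  }
  on_fail <- function(stage, e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    abort("pipeline failed in stage '%s': %s", stage, conditionMessage(e))
  }
  want <- function(s) s %in% cfg$stages

  if (want("simulate")) tryCatch({
    stage_log("simulate", "generating synthetic compendium (seed %d)",
              cfg$seed)
    design <- do.call(simulation_design,
                      c(list(seed = cfg$seed), cfg$simulate))
    sim <- simulate_all(design)
    res$sim <- sim
    gs <- simulate_gene_sets(sim$truth, seed = cfg$seed)
    res$gene_sets <- gs
    for (s in names(sim$sources))
      emit(paste0("annotation_", s, ".gff3"),
           function(p) write_annotation_gff3(sim$sources[[s]], p))
    emit("probes.bed", function(p) write_probes_bed(sim$probes, p))
    emit("raw_matrix.tsv", function(p) write_matrix_tsv(sim$matrix, p))
    emit("negative_controls.tsv", function(p) write_matrix_tsv(sim$negctl, p))
    emit("sample_meta.tsv", function(p) write_table_tsv(sim$meta, p))
    emit("tf_probes.txt", function(p) writeLines(sim$truth$tf_ids, p))
    emit("hkg_probes.txt", function(p) writeLines(sim$truth$hkg_ids, p))
    emit("gene_sets.gmt", function(p) write_gmt(gs$sets, p))
    emit("ground_truth.json", function(p)
      jsonlite::write_json(sim$truth, p, auto_unbox = TRUE, null = "null"))
    manifest$funnel$n_probes_mapped <- nrow(sim$probes)
  }, error = function(e) on_fail("simulate", e))

  if (want("annotate")) tryCatch({
    stage_log("annotate", "classifying %d probes against %d sources",
              nrow(res$sim$probes), length(res$sim$sources))
    per_source <- vapply(res$sim$sources, function(s)
      classify_probes_one_source(res$sim$probes, s),
      character(nrow(res$sim$probes)))
    rownames(per_source) <- res$sim$probes$probe_id
    labels <- classify_consensus(per_source)
    labels$chrom <- res$sim$probes$chrom
    # probe -> gene mapping for dedup: same-strand exon-overlap gene (mRNA)
    gene_map <- rep(NA_character_, nrow(res$sim$probes))
    ov <- GenomicRanges::findOverlaps(probes_gr(res$sim$probes),
                                      exons_gr(res$sim$base))
    first <- !duplicated(queryHits(ov))
    gene_map[queryHits(ov)[first]] <-
      exons_gr(res$sim$base)$gene_id[subjectHits(ov)[first]]
    gene_map[labels$final_class != "mRNA"] <- NA
    kept <- deduplicate_by_mean_signal(
      data.frame(probe_id = labels$probe_id, gene_id = gene_map),
      res$sim$matrix)
    kept <- intersect(kept, labels$probe_id[labels$final_class != "discarded"])
    linc <- res$sim$probes[labels$final_class == "lncRNA" &
                             labels$subclass == "lincRNA", , drop = FALSE]
    dist_cat <- if (nrow(linc)) lincRNA_distance_category(linc, res$sim$base)
                else NULL
    res$labels <- labels; res$kept <- kept; res$dist_cat <- dist_cat
    emit("annotation.tsv", function(p) {
      out <- cbind(labels, as.data.frame(per_source),
                   kept_after_dedup = labels$probe_id %in% kept)
      write_table_tsv(out, p)
    })
    if (!is.null(dist_cat))
      emit("lincRNA_distance.tsv", function(p) write_table_tsv(dist_cat, p))
    manifest$funnel$n_classified <- nrow(labels)
    manifest$funnel$n_concordant <-
      sum(labels$final_class != "discarded")
    manifest$funnel$n_deduplicated <- length(kept)
  }, error = function(e) on_fail("annotate", e))

  if (want("assemble")) tryCatch({
    stage_log("assemble", "normalizing and calling detection")
    norm <- log2_and_quantile_normalize(res$sim$matrix)
    qc <- compendium_qc(norm, res$sim$meta)
    flags <- screen_outliers(qc, cfg$assemble$outlier_floor)
    th <- detection_threshold(res$sim$negctl,
                              cfg$assemble$detection_percentile,
                              cfg$assemble$pooled_controls)
    det <- call_detection(res$sim$matrix, th)
    keepdet <- drop_never_expressed(det)
    detected <- intersect(res$kept, keepdet$kept)
    tsum <- tissue_expression(det[detected, , drop = FALSE], res$sim$meta,
                              cfg$assemble$tissue_fraction)
    res$norm <- norm; res$det <- det; res$detected <- detected
    res$tissue_summary <- tsum; res$outliers <- flags
    emit("normalized_matrix.tsv", function(p) write_matrix_tsv(norm, p))
    emit("detection.tsv", function(p) write_matrix_tsv(det * 1L, p))
    emit("qc_outliers.tsv", function(p)
      write_table_tsv(data.frame(sample_id = names(qc$median_rho),
                                 median_rho = qc$median_rho,
                                 outlier = flags$sample_flags), p))
    emit("tissue_summary.tsv", function(p)
      write_table_tsv(data.frame(probe_id = rownames(tsum$expressed),
                                 tsum$expressed * 1L,
                                 n_tissues = tsum$n_tissues,
                                 check.names = FALSE), p))
    manifest$funnel$n_detected <- length(detected)
  }, error = function(e) on_fail("assemble", e))

  if (want("network")) tryCatch({
    stage_log("network", "building signed network on %d probes",
              length(res$detected))
    nv <- res$norm$values[res$detected, , drop = FALSE]
    net <- build_network_modules(nv, cfg$network$beta,
                                 cfg$network$min_module_size,
                                 cfg$network$merge_cut_height,
                                 cfg$network$cut_height)
    res$net <- net
    mt <- if (!is.null(net$eigengenes))
      module_trait_correlation(net$eigengenes, res$sim$meta) else NULL
    comp <- if (length(setdiff(unique(net$assignment), "grey")))
      module_composition(net$assignment, res$labels,
                         res$sim$truth$tf_ids, res$sim$truth$hkg_ids)
    else NULL
    res$module_trait <- mt; res$composition <- comp
    emit("modules.tsv", function(p)
      write_table_tsv(data.frame(probe_id = names(net$assignment),
                                 module = net$assignment), p))
    if (!is.null(net$eigengenes))
      emit("eigengenes.tsv", function(p)
        write_matrix_tsv(t(net$eigengenes$eigengenes), p))
    if (!is.null(mt))
      emit("module_trait.tsv", function(p)
        write_table_tsv(data.frame(module = rownames(mt$r),
                                   r = mt$r, p = mt$p, check.names = FALSE),
                        p))
    if (!is.null(comp))
      emit("module_composition.tsv", function(p)
        write_table_tsv(comp$table, p))
  }, error = function(e) on_fail("network", e))

  if (want("enrich")) tryCatch({
    stage_log("enrich", "hypergeometric enrichment per module")
    universe <- res$labels$probe_id[res$labels$final_class == "mRNA" &
                                      res$labels$probe_id %in% res$detected]
    mods <- setdiff(unique(res$net$assignment), "grey")
    enr <- lapply(mods, function(m) {
      genes <- intersect(names(res$net$assignment)[res$net$assignment == m],
                         universe)
      if (!length(genes)) return(NULL)
      tab <- enrich_module(genes, res$gene_sets$sets, universe,
                           cfg$enrich$alpha, cfg$enrich$q_cap,
                           res$gene_sets$namespaces)
      if (nrow(tab)) cbind(module = m, tab) else NULL
    })
    enr <- do.call(rbind, enr)
    res$enrichment <- enr
    emit("enrichment.tsv", function(p)
      write_table_tsv(enr %||% data.frame(module = character(0)), p))
  }, error = function(e) on_fail("enrich", e))

  if (want("hubs")) tryCatch({
    stage_log("hubs", "scoring hub TFs and genes")
    tags <- data.frame(
      probe_id = res$labels$probe_id,
      kind = ifelse(res$labels$final_class == "lncRNA", "lncRNA", "mRNA"),
      is_tf = res$labels$probe_id %in% res$sim$truth$tf_ids)
    ht <- hub_table(res$norm$values[res$detected, , drop = FALSE],
                    res$net$assignment, tags,
                    cfg$hubs$r_min, cfg$hubs$alpha)
    res$hub_table <- ht
    emit("hub_table.tsv", function(p) write_table_tsv(ht, p))
  }, error = function(e) on_fail("hubs", e))

  manifest$outputs <- lapply(paths, function(p)
    list(file = basename(p), md5 = unname(tools::md5sum(p))))
  manifest$config_hash <- unname(tools::md5sum(
    {tmp <- tempfile(); saveRDS(rapply(cfg, as.character, how = "unlist"),
                                tmp); tmp}))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  attr(manifest, "results") <- res
  invisible(manifest)
}
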