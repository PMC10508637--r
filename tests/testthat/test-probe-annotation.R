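test_that("single-source classification matches the stated rules", {
  src <- annotation_source("s", data.frame(
    gene_id = c("G1", "G1", "G2"), chrom = "chr1",
    strand = c("+", "+", "-"),
    start = c(51, 501, 120), end = c(200, 700, 260)))
  # inside an exon, same strand -> mRNA (G2 is antisense but G1 exon wins
  # only if no lncRNA conflict; probe [101,160] overlaps G2 body -> ambiguous)
  p_amb <- probe_alignments("p1", "chr1", 130, 190, "+")
  expect_equal(classify_probes_one_source(p_amb, src), "ambiguous")

  src2 <- annotation_source("s2", data.frame(
    gene_id = c("G1", "G1"), chrom = "chr1", strand = "+",
    start = c(51, 501), end = c(200, 700)))
  expect_equal(
    classify_probes_one_source(
      probe_alignments(c("pm", "pi", "pa", "pl"), "chr1",
                       c(101, 250, 250, 5000), c(160, 320, 320, 5059),
                       c("+", "+", "-", "+")), src2),
    c("mRNA", "intronic_lncRNA", "antisense_lncRNA", "lincRNA"))

  # chromosome with no genes -> lincRNA
  expect_equal(classify_probes_one_source(
    probe_alignments("px", "chr9", 100, 159, "+"), src2), "lincRNA")
})

test_that("classification agrees with the brute-force oracle", {
  src <- random_source(50, seed = 42)
  set.seed(7)
  n <- 200
  span <- range(c(src$genes$start, src$genes$end))
  starts <- sample(span[1]:(span[2] + 2000), n)
  probes <- probe_alignments(
    sprintf("p%03d", 1:n),
    sample(c("chrA", "chrB"), n, replace = TRUE),
    starts, starts + 59,
    sample(c("+", "-"), n, replace = TRUE))
  got <- classify_probes_one_source(probes, src)
  want <- vapply(seq_len(n),
                 function(i) oracle_classify(probes[i, ], src), "")
  expect_identical(got, want)
})

test_that("consensus voting follows the concordance rules", {
  per <- rbind(
    c("lincRNA", "lincRNA", "lincRNA"),
    c("mRNA", "lincRNA", "lincRNA"),
    c("lincRNA", "intronic_lncRNA", "antisense_lncRNA"),
    c("ambiguous", "lincRNA", "lincRNA"),
    c("mRNA", "mRNA", "mRNA"),
    c("intronic_lncRNA", "intronic_lncRNA", "lincRNA"))
  got <- classify_consensus(per, paste0("p", 1:6))
  expect_equal(got$final_class,
               c("lncRNA", "mRNA", "lncRNA", "discarded", "mRNA", "lncRNA"))
  expect_equal(got$subclass,
               c("lincRNA", "none", "antisense", "none", "none", "intronic"))
  expect_error(classify_consensus(matrix(character(0), 0, 3)), "empty")
})

test_that("every probe gets exactly one final class (partition property)", {
  for (seed in 1:3) {
    d <- small_design(seed = seed, annotation_disagreement_rate = 0.4)
    ann <- simulate_annotation(d)
    pr <- simulate_probes(ann, d)
    per <- vapply(ann$sources,
                  function(s) classify_probes_one_source(pr$probes, s),
                  character(nrow(pr$probes)))
    lab <- classify_consensus(per, pr$probes$probe_id)
    expect_equal(nrow(lab), nrow(pr$probes))
    counts <- table(factor(lab$final_class,
                           levels = c("mRNA", "lncRNA", "discarded")))
    expect_equal(sum(counts), nrow(pr$probes))
    expect_true(all(lab$subclass[lab$final_class != "lncRNA"] == "none"))
    expect_true(all(lab$subclass[lab$final_class == "lncRNA"] != "none"))
  }
})

test_that("raising annotation disagreement never gains consensus lncRNAs", {
  n_lnc <- function(rate, seed) {
    d <- small_design(seed = seed, annotation_disagreement_rate = rate)
    ann <- simulate_annotation(d)
    pr <- simulate_probes(ann, d)
    per <- vapply(ann$sources,
                  function(s) classify_probes_one_source(pr$probes, s),
                  character(nrow(pr$probes)))
    sum(classify_consensus(per)$final_class == "lncRNA")
  }
  rates <- c(0, 0.3, 0.7, 1)
  med <- vapply(rates, function(r)
    median(vapply(1:5, function(s) n_lnc(r, s), numeric(1))), numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("lincRNA distance categories use inclusive 1 kb and 50 kb bounds", {
  src <- annotation_source("s", data.frame(
    gene_id = c("G1", "G2"), chrom = "chr1", strand = c("+", "-"),
    start = c(1000, 500000), end = c(2000, 501000)))
  # gaps: 500, exactly 1000, 60000 downstream of G1; ties
  pr <- probe_alignments(
    c("a", "b", "c", "d"), "chr1",
    c(2501, 3001, 62001, 2501 + 0), # d duplicates a's interval, other strand
    c(2560, 3060, 62060, 2560), c("+", "+", "+", "-"))
  got <- lincRNA_distance_category(pr, src)
  expect_equal(got$distance, c(500, 1000, 60000, 500))
  expect_equal(got$category, c("utr_extension_candidate",
                               "utr_extension_candidate", "far", "distal"))
  expect_equal(got$nearest_gene_id[1], "G1")
  # nearest-gene tie broken by smaller gene_id
  src_tie <- annotation_source("t", data.frame(
    gene_id = c("GB", "GA"), chrom = "chr1", strand = "+",
    start = c(100, 1000), end = c(200, 1100)))
  tie <- lincRNA_distance_category(
    probe_alignments("p", "chr1", 451, 749, "+"), src_tie)
  expect_equal(tie$nearest_gene_id, "GA")
  expect_error(lincRNA_distance_category(
    pr, annotation_source("e", data.frame(gene_id = character(0),
                                          chrom = character(0),
                                          strand = character(0),
                                          start = numeric(0),
                                          end = numeric(0)))), "no genes")
})

test_that("deduplication keeps the highest-mean probe per gene", {
  m <- matrix(c(5, 5, 6, 6, 5, 5), 3, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  pg <- data.frame(probe_id = c("p1", "p2", "p3"),
                   gene_id = c("G", "G", NA))
  expect_equal(deduplicate_by_mean_signal(pg, m), c("p2", "p3"))
  # tie -> lexicographically smallest probe id
  m2 <- m; m2["p2", ] <- c(5, 5)
  expect_equal(deduplicate_by_mean_signal(pg, m2), c("p1", "p3"))
  # 10 genes x 3 probes + 7 unassigned -> 17 kept
  ids <- c(outer(1:3, 1:10, function(i, g) sprintf("g%02dp%d", g, i)))
  free <- sprintf("linc%d", 1:7)
  all_ids <- c(ids, free)
  m3 <- matrix(rnorm(37 * 4), 37, 4, dimnames = list(all_ids, paste0("s", 1:4)))
  pg3 <- data.frame(probe_id = all_ids,
                    gene_id = c(rep(sprintf("G%02d", 1:10), each = 3),
                                rep(NA, 7)))
  kept <- deduplicate_by_mean_signal(pg3, m3)
  expect_length(kept, 17)
  expect_true(all(free %in% kept))
  expect_error(deduplicate_by_mean_signal(
    data.frame(probe_id = "zz", gene_id = "G"), m), "missing")
})

test_that("chromosome density table and correlation behave", {
  gen <- genome_model(c("c1", "c2", "c3"), c(1e6, 2e6, 4e6))
  lab <- data.frame(
    chrom = c(rep("c1", 11), rep("c2", 22), rep("c3", 33)),
    final_class = c(rep("mRNA", 10), "lncRNA",
                    rep("mRNA", 20), rep("lncRNA", 2),
                    rep("mRNA", 30), rep("lncRNA", 3)))
  got <- chromosome_density(lab, gen)
  expect_equal(got$correlation$r, 1.0)
  expect_equal(got$table$n_mRNA, c(10, 20, 30))
  expect_equal(got$table$mRNA_per_mb, c(10, 10, 7.5))
  lab$final_class[lab$final_class == "lncRNA"] <- "mRNA"
  expect_warning(got2 <- chromosome_density(lab, gen), "constant")
  expect_true(is.nan(got2$correlation$r))
  expect_error(chromosome_density(lab, gen[1:2, ]), "3 chromosomes")

  # generator output: proportional placement gives a strong correlation
  rs <- vapply(1:3, function(s) {
    d <- simulation_design(seed = 20 + s)   # default scale: 219 probes
    ann <- simulate_annotation(d)
    pr <- simulate_probes(ann, d)
    per <- vapply(ann$sources,
                  function(x) classify_probes_one_source(pr$probes, x),
                  character(nrow(pr$probes)))
    lab <- classify_consensus(per, pr$probes$probe_id)
    lab$chrom <- pr$probes$chrom
    chromosome_density(lab, ann$genome)$correlation$r
  }, numeric(1))
  expect_gte(median(rs), 0.8)
})
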