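rand_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

test_that("signed adjacency transform evaluates correctly", {
  r <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3, 3)
  a <- signed_adjacency(r, 12)
  expect_equal(a[1, 3], 0)             # r = -1 -> 0
  expect_equal(a[1, 2], 0.5^12)        # r = 0 -> 2.44140625e-4
  expect_equal(a[1, 2], 2.44140625e-4)
  expect_equal(diag(a), rep(1, 3))
  expect_equal(signed_adjacency(matrix(1, 2, 2), 7),
               matrix(1, 2, 2))        # r = 1 fixed point for any beta
  expect_error(signed_adjacency(matrix(1.5, 2, 2), 12), "\\[-1, 1\\]")
})

test_that("TOM matches hand evaluation and the triple-loop oracle", {
  a_complete <- matrix(1, 3, 3)
  expect_equal(topological_overlap(a_complete), matrix(1, 3, 3))

  a <- diag(3)
  a[1, 2] <- a[2, 1] <- 0.5
  tom <- topological_overlap(a)
  expect_equal(tom[1, 2], 0.5 / (min(0.5, 0.5) + 1 - 0.5))  # = 0.5

  for (seed in 1:5) {
    n <- sample(3:10, 1)
    a <- rand_adjacency(n, seed)
    got <- topological_overlap(a)
    expect_equal(got, oracle_tom(a), tolerance = 1e-12)
    expect_equal(got, t(got))
    expect_true(all(got >= 0 & got <= 1 + 1e-12))
    expect_equal(diag(got), rep(1, n))
  }
})

test_that("soft-threshold selection applies the scale-free criterion", {
  set.seed(10)
  noise <- matrix(rnorm(100 * 50), 100, 50,
                  dimnames = list(paste0("p", 1:100), paste0("s", 1:50)))
  r2 <- vapply(1:5, function(s) {
    set.seed(s)
    m <- matrix(rnorm(100 * 50), 100, 50,
                dimnames = list(paste0("p", 1:100), paste0("s", 1:50)))
    a <- signed_adjacency(cor(t(m)), 1)
    scale_free_fit(rowSums(a) - diag(a))$fit_signed
  }, numeric(1))
  expect_true(median(r2) < 0.5)        # pure noise is not scale-free at beta 1

  # single candidate is returned with diagnostics (warns: criterion unmet)
  single <- suppressWarnings(pick_soft_threshold(noise, betas = 12))
  expect_equal(single$beta, 12)
  expect_equal(nrow(single$diagnostics), 1)

  # hub-like structure (heavy-tailed factor loadings) attains a strong fit
  # and the smallest qualifying power is selected
  set.seed(16)
  n <- 300; ns <- 100
  l <- rbeta(n, 0.5, 1.5)
  f <- rnorm(ns)
  m <- t(sapply(l, function(li) li * f + sqrt(1 - li^2) * rnorm(ns)))
  dimnames(m) <- list(paste0("p", 1:n), paste0("s", 1:ns))
  ps <- pick_soft_threshold(m, betas = c(2, 4, 6, 9, 12), r2_target = 0.8)
  expect_gte(max(ps$diagnostics$r_squared), 0.8)
  expect_true(ps$met_criterion)
  d1 <- ps$diagnostics
  expect_equal(ps$beta,
               d1$beta[d1$r_squared >= 0.8 & d1$mean_k < 100][1])
})

test_that("static tree cut separates perfect blocks and respects min size", {
  n <- 80
  diss <- matrix(1, n, n, dimnames = list(sprintf("p%02d", 1:n), NULL))
  diss[1:40, 1:40] <- 0
  diss[41:80, 41:80] <- 0
  asg <- cut_modules(diss, min_module_size = 30)
  expect_equal(sort(as.integer(table(asg))), c(40L, 40L))
  expect_setequal(unique(asg), c("turquoise", "blue"))

  small <- matrix(1, 20, 20, dimnames = list(paste0("p", 1:20), NULL))
  diag(small) <- 0
  expect_warning(asg2 <- cut_modules(small, min_module_size = 30), "grey")
  expect_true(all(asg2 == "grey"))
})

test_that("eigengenes are first principal components with sign convention", {
  set.seed(11)
  base <- rnorm(30)
  m <- matrix(rep(base, 5), 5, 30, byrow = TRUE,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:30)))
  m <- m + matrix(rnorm(150, 0, 1e-8), 5, 30)
  asg <- setNames(rep("turquoise", 5), rownames(m))
  eg <- module_eigengene(m, asg)
  expect_true(all(cor(eg$eigengenes[, 1], t(m)) > 0.999))
  expect_gt(eg$var_explained[["turquoise"]], 0.999)
  expect_equal(sum(eg$eigengenes[, 1]^2), 1)   # unit norm

  # probe and its negation: variance explained 1, oriented to first probe
  m2 <- rbind(p1 = base, p2 = -base)
  colnames(m2) <- paste0("s", 1:30)
  eg2 <- module_eigengene(m2, setNames(rep("blue", 2), rownames(m2)))
  expect_equal(eg2$var_explained[["blue"]], 1)
  expect_gt(cor(eg2$eigengenes[, 1], base), 0.999)

  # variance explained equals the top eigenvalue share (eigen oracle)
  set.seed(12)
  m3 <- matrix(rnorm(50 * 100), 50, 100,
               dimnames = list(paste0("p", 1:50), paste0("s", 1:100)))
  eg3 <- module_eigengene(m3, setNames(rep("brown", 50), rownames(m3)))
  xs <- t(scale(t(m3)))
  ev <- eigen(xs %*% t(xs), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(eg3$var_explained[["brown"]], ev[1] / sum(ev),
               tolerance = 1e-10)

  # eigengene maximality: no member has a higher mean squared correlation
  set.seed(13)
  m4 <- matrix(rnorm(20 * 40), 20, 40,
               dimnames = list(paste0("p", 1:20), paste0("s", 1:40)))
  m4 <- m4 + rep(rnorm(40), each = 20)
  eg4 <- module_eigengene(m4, setNames(rep("red", 20), rownames(m4)))
  score_e <- mean(cor(eg4$eigengenes[, 1], t(m4))^2)
  for (i in 1:20)
    expect_lte(mean(cor(m4[i, ], t(m4))^2), score_e + 1e-12)
})

test_that("module merging joins redundant modules and only those", {
  set.seed(14)
  f1 <- rnorm(60); f2 <- rnorm(60)
  mk <- function(f, n, noise) t(replicate(n, f + rnorm(60, 0, noise)))
  m <- rbind(mk(f1, 10, 0.2), mk(f1, 10, 0.2), mk(f2, 10, 0.2))
  dimnames(m) <- list(sprintf("p%02d", 1:30), sprintf("s%02d", 1:60))
  asg <- setNames(rep(c("turquoise", "blue", "brown"), each = 10),
                  rownames(m))
  merged <- merge_close_modules(m, asg, cut = 0.25)
  expect_equal(length(setdiff(unique(merged), "grey")), 2)
  expect_equal(length(unique(merged[1:20])), 1)   # same-factor modules joined
  expect_equal(length(unique(merged[21:30])), 1)

  # cut = 0 never merges
  expect_equal(length(setdiff(unique(merge_close_modules(m, asg, 0)),
                              "grey")), 3)
})

test_that("module-trait correlations use the t-distribution p-value", {
  meta <- data.frame(sample_id = sprintf("s%02d", 1:40), series_id = "A",
                     tissue = rep(c("oocyte", "blastocyst"), each = 20))
  me <- cbind(turquoise = as.numeric(meta$tissue == "oocyte"))
  rownames(me) <- meta$sample_id
  mt <- module_trait_correlation(me, meta)
  expect_equal(mt$r["turquoise", "oocyte"], 1)
  expect_equal(mt$p["turquoise", "oocyte"], 0)

  # closed form: r = 0.7, n = 30 -> p ~= 1.68e-5
  x <- scale(rnorm(30))[, 1]
  e <- scale(resid(lm(rnorm(30) ~ x)))[, 1]
  y <- 0.7 * x + sqrt(1 - 0.49) * e
  cw <- cor_with_p(x, y)
  expect_equal(cw$r, 0.7, tolerance = 1e-10)
  expect_equal(cw$p, 1.68e-5, tolerance = 0.01)

  # orthogonal eigengene: p > 0.05 in >= 90 % of seeds
  ps <- vapply(1:50, function(s) {
    set.seed(s)
    meta50 <- data.frame(sample_id = sprintf("s%02d", 1:50), series_id = "A",
                         tissue = rep(c("oocyte", "blastocyst"), 25))
    me50 <- cbind(blue = rnorm(50))
    rownames(me50) <- meta50$sample_id
    module_trait_correlation(me50, meta50)$p["blue", "oocyte"]
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("module composition bookkeeping and HKG correlation", {
  asg <- setNames(rep("turquoise", 45), sprintf("p%02d", 1:45))
  lab <- data.frame(probe_id = names(asg),
                    final_class = c(rep("mRNA", 43), rep("lncRNA", 2)))
  expect_warning(
    comp <- module_composition(asg, lab, tf_ids = sprintf("p%02d", 1:4)),
    "undefined")
  expect_equal(comp$table$size, 45)
  expect_equal(comp$table$n_TF, 4)
  expect_equal(comp$table$frac_lncRNA, 2 / 45)
  expect_equal(100 * comp$table$frac_lncRNA, 4.44, tolerance = 0.01)
  expect_true(is.nan(comp$hkg_lnc_correlation$r))

  # planted anti-association between HKG and lncRNA fractions is recovered
  set.seed(15)
  mods <- paste0("m", 1:10)
  asg2 <- setNames(rep(mods, each = 30), sprintf("q%03d", 1:300))
  frac_l <- seq(0.05, 0.6, length.out = 10)
  lab2 <- do.call(rbind, lapply(1:10, function(i) {
    ids <- names(asg2)[asg2 == mods[i]]
    nl <- round(30 * frac_l[i])
    data.frame(probe_id = ids,
               final_class = c(rep("lncRNA", nl), rep("mRNA", 30 - nl)))
  }))
  hkg <- unlist(lapply(1:10, function(i) {
    ids <- lab2$probe_id[lab2$final_class == "mRNA"][
      lab2$probe_id[lab2$final_class == "mRNA"] %in%
        names(asg2)[asg2 == mods[i]]]
    sample(ids, round(length(ids) * (11 - i) / 30))
  }))
  comp2 <- module_composition(asg2, lab2, hkg_ids = hkg)
  expect_lt(comp2$hkg_lnc_correlation$r, -0.3)
  expect_error(module_composition(setNames(character(0), character(0)),
                                  lab2), "no modules")
})
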