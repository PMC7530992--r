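test_that("the log transform and maternal gate follow their definitions", {
  m <- triple_matrix(c(0, 1, 7,
                       2.0, 5, 5,
                       2.01, 5, 5))
  e <- log_transform(m)
  expect_equal(unname(e["g1", ]), c(0, 1, 3))
  # FPKM > 2 at GV is strict: 2.0 excluded, 2.01 included
  expect_equal(select_maternal(m, 2), "g3")
  no_gv <- triple_matrix(c(1, 1, 1), stages = c("zygote", "8-cell", "morula"))
  expect_error(select_maternal(no_gv), "GV stage absent")
})

test_that("worked FPKM triples classify exactly as the rules force", {
  m <- triple_matrix(c(7, 0, 0,
                       7, 7, 0,
                       15, 3, 0,
                       7, 7, 7,
                       3, 15, 15))
  cl <- classify_decay(m)
  expect_equal(as.character(cl$cluster),
               c("I", "II", "III", "IV", "UNCLASSIFIED"))
  # and a sub-threshold gene is NOT_MATERNAL
  m2 <- triple_matrix(c(1.5, 0, 0))
  expect_equal(as.character(classify_decay(m2)$cluster), "NOT_MATERNAL")
})

test_that("cluster predicates are mutually exclusive and exhaustive", {
  set.seed(42)
  n <- 1e4
  e_gv <- runif(n, 0, 12); e_zyg <- runif(n, 0, 12); e_post <- runif(n, 0, 12)
  m <- 1
  preds <- cbind(
    I = e_gv > e_zyg + m & e_zyg <= e_post + m,
    II = e_gv <= e_zyg + m & e_gv > e_zyg - m & e_zyg > e_post + m,
    III = e_gv > e_zyg + m & e_zyg > e_post + m,
    IV = e_gv <= e_zyg + m & e_gv > e_zyg - m &
      e_zyg <= e_post + m & e_zyg > e_post - m)
  expect_true(all(rowSums(preds) <= 1))
  lab <- cluster_rules(e_gv, e_zyg, e_post)
  hit <- rowSums(preds) == 1
  expect_equal(as.character(lab[hit]), colnames(preds)[apply(preds[hit, ], 1, which)])
  expect_true(all(lab[!hit] == "UNCLASSIFIED"))
})

test_that("cluster sizes always sum to the gene universe", {
  sim <- generate_stage_matrix(
    n_genes = 500, noise_sd = 0.6, seed = 3,
    class_proportions = c(I = 0.2, II = 0.2, III = 0.2, IV = 0.2,
                          UNCLASSIFIED = 0.1, NOT_MATERNAL = 0.1))
  cl <- classify_decay(sim$matrix)
  expect_equal(sum(table(cl$cluster)), 500L)
})

test_that("lowering E(8-cell) of a Cluster IV gene can only yield Cluster II", {
  set.seed(7)
  for (i in 1:200) {
    e_gv <- runif(1, 2, 10)
    e_zyg <- runif(1, e_gv - 0.99, e_gv + 0.99)
    e_post <- runif(1, e_zyg - 0.99, e_zyg + 12)
    if (cluster_rules(e_gv, e_zyg, e_post) != "IV") next
    lowered <- cluster_rules(e_gv, e_zyg, e_post - runif(1, 0, 15))
    expect_true(as.character(lowered) %in% c("IV", "II"))
  }
})

test_that("morula extension degrades only 2-fold-dropping Cluster IV genes", {
  m <- triple_matrix(c(7, 7, 7, 1,
                       7, 7, 7, 7),
                     stages = c("GV", "zygote", "8-cell", "morula"))
  cl <- classify_decay(m)
  cl <- classify_morula_extension(m, cl)
  expect_equal(as.character(cl$cluster), c("IV", "IV"))
  expect_equal(cl$morula_degraded, c("degraded", "stable"))

  no_morula <- triple_matrix(c(7, 7, 7))
  cl2 <- classify_morula_extension(no_morula, classify_decay(no_morula))
  expect_equal(cl2$morula_degraded, "not_applicable")
})

test_that("ZGA dependence distinguishes abolished from persisting decay", {
  mk <- function(zyg, post, treated = FALSE) {
    vals <- matrix(c(15, 15, 15, zyg, post, 14), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC"), c("z1", "p1")))
    # gA: the gene under test; gB fixed decaying; gC fixed stable
    vals["gA", ] <- c(zyg, post)
    vals["gB", ] <- c(15, 1)
    vals["gC", ] <- c(15, 14)
    meta <- data.frame(sample = c("z1", "p1"),
                       treatment = if (treated) "alpha-amanitin" else "none")
    stage_matrix(vals, c(z1 = "zygote", p1 = "8-cell"), meta = meta)
  }
  gv <- triple_matrix(c(15, 15, 1,
                        15, 15, 1,
                        15, 15, 1))
  rownames(gv$values) <- c("gA", "gB", "gC")
  cl <- classify_decay(gv)  # all Cluster II
  expect_equal(as.character(cl$cluster), rep("II", 3))

  # decay abolished under the transcription block -> dependent
  control <- mk(15, 1); treated <- mk(15, 14, treated = TRUE)
  res <- zga_dependence(control, treated, cl)
  expect_equal(res$zga_dependent[res$gene == "gA"], "dependent")
  # decay persists -> independent
  res2 <- zga_dependence(control, mk(15, 1, treated = TRUE), cl)
  expect_equal(res2$zga_dependent[res2$gene == "gA"], "independent")
  # not decaying in controls (ratio >= 0.5) -> not selected
  expect_equal(res$zga_dependent[res$gene == "gC"], "not_applicable")
  # missing treatment flag is an error
  expect_error(zga_dependence(control, mk(15, 14), cl), "alpha-amanitin")
})

test_that("ZGA calls are invariant to sample and replicate permutation", {
  sim <- generate_stage_matrix(n_genes = 150, noise_sd = 0.2, seed = 21)
  pair <- generate_amanitin_pair(sim$truth, noise_sd = 0.2,
                                 n_replicates = 3, seed = 22)
  cl <- classify_decay(sim$matrix)
  res <- zga_dependence(pair$control, pair$treated, cl)

  shuffle <- function(x, perm) {
    stage_matrix(x$values[, perm], x$stages[perm],
                 meta = if (is.null(x$meta)) NULL else
                   x$meta[match(colnames(x$values)[perm], x$meta$sample), ])
  }
  set.seed(1)
  perm <- sample(ncol(pair$control$values))
  res_p <- zga_dependence(shuffle(pair$control, perm),
                          shuffle(pair$treated, rev(perm)), cl)
  expect_identical(res$zga_dependent, res_p$zga_dependent)
})

test_that("the stage triplet is configurable to the mouse convention", {
  m <- triple_matrix(c(7, 0, 0), stages = c("GV", "zygote", "2-cell"))
  cfg <- classifier_config(stage_triplet = c("GV", "zygote", "2-cell"))
  expect_equal(as.character(classify_decay(m, cfg)$cluster), "I")
})
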