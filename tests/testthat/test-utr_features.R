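test_that("motif counting is exact, overlapping, and strand-specific", {
  expect_equal(count_motifs("AATAAA", pas_motifs()), 1L)
  # overlapping starts all counted
  expect_equal(count_motifs("AATAAATAAA", pas_motifs()), 2L)
  expect_equal(count_motifs("TTTTATTTTAAT", cpe_motifs()), 2L)
  # RNA input and case are normalized
  expect_equal(count_motifs("auuaaa", pas_motifs()), 1L)
  # N never matches
  expect_equal(count_motifs("AATANA", pas_motifs()), 0L)
  expect_equal(count_motifs("", pas_motifs()), 0L)
  expect_error(count_motifs("ACGT", character(0)), "empty motif set")
  # scanning the reverse complement is a different question
  s <- "AATAAA"
  rc <- "TTTATT"
  expect_equal(count_motifs(rc, pas_motifs()), 0L)
})

test_that("motif counts match an exhaustive sliding-window oracle", {
  set.seed(99)
  n <- 500
  lens <- sample(0:300, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  }, character(1))
  for (motifs in list(cpe_motifs(), pas_motifs())) {
    expect_equal(count_motifs(seqs, motifs),
                 vapply(seqs, brute_count_motifs, integer(1),
                        motifs = motifs, USE.NAMES = FALSE))
  }
})

test_that("concatenation can only create boundary-spanning extra matches", {
  set.seed(17)
  w_max <- max(nchar(cpe_motifs()))
  for (i in 1:100) {
    s1 <- paste(sample(c("A", "T"), sample(5:60, 1), TRUE), collapse = "")
    s2 <- paste(sample(c("A", "T"), sample(5:60, 1), TRUE), collapse = "")
    c1 <- count_motifs(s1, cpe_motifs())
    c2 <- count_motifs(s2, cpe_motifs())
    cc <- count_motifs(paste0(s1, s2), cpe_motifs())
    expect_gte(cc, c1 + c2)
    expect_lte(cc, c1 + c2 + 2 * (w_max - 1))
  }
})

test_that("UTR annotation joins decay classes and reports exclusions", {
  m <- triple_matrix(c(7, 0, 0,
                       7, 7, 0,
                       7, 7, 7))
  cl <- classify_decay(m)
  seqs <- c(g1 = paste0(strrep("C", 27), "TTTTAT", strrep("C", 27)),
            g2 = strrep("G", 40), g4 = "ACGT")
  rec <- annotate_utrs(seqs, cl)
  expect_equal(rec$decay_class[rec$gene == "g1"], "M-decay")
  expect_equal(rec$decay_class[rec$gene == "g2"], "Z-decay")
  expect_equal(rec$length[rec$gene == "g1"], 60L)
  expect_equal(rec$cpe_count[rec$gene == "g1"], 1L)
  expect_equal(rec$pas_count[rec$gene == "g1"], 0L)
  # classified gene without a UTR is excluded and reported
  expect_true("g3" %in% attr(rec, "unmatched"))
  expect_false("g3" %in% rec$gene)
})

test_that("class comparison matches the pooled t-test closed form", {
  rec <- data.frame(gene = paste0("g", 1:6),
                    decay_class = rep(c("M-decay", "Z-decay"), each = 3),
                    length = c(1, 2, 3, 4, 5, 6))
  cc <- compare_classes(rec, "length")
  oracle <- pooled_t_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cc$t_statistic, oracle$t, tolerance = 1e-12)
  expect_equal(cc$df, oracle$df)
  expect_equal(cc$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(cc$summary$n, c(3L, 3L))

  # identical groups: t = 0, p = 1
  rec0 <- data.frame(gene = paste0("g", 1:6),
                     decay_class = rep(c("M-decay", "Z-decay"), each = 3),
                     length = rep(3, 6))
  cc0 <- compare_classes(rec0, "length")
  expect_equal(cc0$t_statistic, 0)
  expect_equal(cc0$p_value, 1)

  # swapping group labels negates t, p unchanged
  cc_sw <- compare_classes(rec, "length", classes = c("Z-decay", "M-decay"))
  expect_equal(cc_sw$t_statistic, -cc$t_statistic, tolerance = 1e-12)
  expect_equal(cc_sw$p_value, cc$p_value, tolerance = 1e-12)

  rec_small <- rec[-(1:2), ]
  expect_error(compare_classes(rec_small, "length"), "fewer than 2")
})

test_that("summary quantiles cover the box-plot statistics", {
  v <- c(10, 20, 30, 40, 50)
  rec <- data.frame(gene = paste0("g", 1:10),
                    decay_class = rep(c("M-decay", "Z-decay"), each = 5),
                    length = c(v, v * 2))
  cc <- compare_classes(rec, "length")
  s <- cc$summary[cc$summary$class == "M-decay", ]
  expect_equal(s$median, 30)
  expect_equal(s$mean, 30)
  expect_equal(s$sem, sd(v) / sqrt(5))
  expect_equal(s$q25, unname(quantile(v, 0.25)))
  expect_equal(s$q97.5, unname(quantile(v, 0.975)))
})

test_that("a planted 2x motif-rate contrast is recovered from the scans", {
  cl <- data.frame(gene = sprintf("g%04d", 1:4000),
                   cluster = rep(c("I", "II"), each = 2000))
  class(cl) <- c("decay_classification", "data.frame")
  ut <- generate_utrs(cl, seed = 33)
  an <- data.frame(decay_class = ut$truth$decay_class,
                   length = ut$truth$length,
                   cpe_count = ut$truth$cpe_count)
  bg <- motif_background_rate(cpe_motifs())
  rate <- function(cls) {
    sub <- an[an$decay_class == cls, ]
    sum(sub$cpe_count) / sum(sub$length) - bg
  }
  ratio <- rate("Z-decay") / rate("M-decay")
  n_m <- sum(an$cpe_count[an$decay_class == "M-decay"])
  n_z <- sum(an$cpe_count[an$decay_class == "Z-decay"])
  se_log <- sqrt(1 / n_m + 1 / n_z)
  expect_lt(abs(log(ratio) - log(2)), 3 * se_log)
})
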