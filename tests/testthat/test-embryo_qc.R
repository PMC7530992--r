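test_that("pairwise correlations match the direct Pearson formula", {
  lg <- cbind(e1 = c(1, 2, 3, 4, 5), e2 = c(2, 2.5, 3, 4.5, 4),
              e3 = c(5, 4, 3, 2, 1), e4 = c(1, 3, 2, 5, 4))
  profiles <- 2^lg - 1
  rownames(profiles) <- paste0("g", 1:5)
  res <- pairwise_correlation(profiles,
                              groups = c(e1 = "A", e2 = "A", e3 = "B",
                                         e4 = "B"))
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:4) for (j in 1:4) {
    expect_equal(res$r[i, j], pearson(lg[, i], lg[, j]), tolerance = 1e-12)
  }
  expect_equal(unname(res$group_mean_r["A"]), pearson(lg[, 1], lg[, 2]),
               tolerance = 1e-12)
  # identical profiles correlate at 1; a log-space negation at -1
  expect_equal(pairwise_correlation(cbind(a = profiles[, 1],
                                          b = profiles[, 1]))$r["a", "b"], 1)
  neg <- 2^(6 - lg[, 1]) - 1
  expect_equal(pairwise_correlation(cbind(a = profiles[, 1], b = neg))$r["a", "b"],
               -1, tolerance = 1e-12)
  # constant profiles are reported
  const <- cbind(a = profiles[, 1], b = rep(1, 5))
  rownames(const) <- paste0("g", 1:5)
  expect_equal(pairwise_correlation(const)$zero_variance, "b")
})

test_that("PCA coordinates agree with an eigendecomposition oracle", {
  set.seed(12)
  profiles <- matrix(rexp(24, 0.2), 6, 4,
                     dimnames = list(paste0("g", 1:6), paste0("e", 1:4)))
  p <- run_pca(profiles, n_components = 3)
  lg <- t(log2(profiles + 1))
  centered <- scale(lg, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(centered))
  expect_equal(p$explained_variance, ev$values[1:3], tolerance = 1e-9)
  expect_equal(sum(p$explained_variance) + sum(ev$values[-(1:3)]),
               p$total_variance, tolerance = 1e-9)
  for (j in 1:3) {
    expect_equal(abs(p$coordinates[, j]), abs((centered %*% ev$vectors)[, j]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # two samples: one nontrivial component, coordinates symmetric about 0
  p2 <- run_pca(profiles[, 1:2], n_components = 1)
  expect_equal(sum(p2$coordinates), 0, tolerance = 1e-9)
  expect_error(run_pca(profiles, n_components = 4), "exceeds")
})

test_that("PCA output is invariant to sample ordering up to nothing", {
  set.seed(30)
  profiles <- matrix(rexp(60, 0.2), 10, 6,
                     dimnames = list(paste0("g", 1:10), paste0("e", 1:6)))
  p <- run_pca(profiles, 2)
  perm <- c(4, 1, 6, 2, 5, 3)
  pp <- run_pca(profiles[, perm], 2)
  expect_equal(pp$coordinates[colnames(profiles), ], p$coordinates,
               tolerance = 1e-9)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
})

test_that("fold changes label thresholds correctly and are antisymmetric", {
  test <- matrix(c(7, 0, 5), ncol = 1, dimnames = list(c("a", "b", "c"), "t"))
  ref <- matrix(c(1, 9, 5), ncol = 1, dimnames = list(c("a", "b", "c"), "r"))
  fc <- fold_changes(test, ref)
  expect_equal(fc$ratio, c(4, 0.1, 1))
  expect_equal(fc$fc_2, c("up", "down", "none"))
  expect_equal(fc$fc_5, c("none", "down", "none"))
  expect_equal(attr(fc, "counts")[["2"]], c(up = 1L, down = 1L))
  rev_fc <- fold_changes(ref, test)
  expect_equal(rev_fc$ratio, 1 / fc$ratio, tolerance = 1e-12)
  expect_error(fold_changes(test, ref[1:2, , drop = FALSE]),
               "same gene universe")
})

test_that("overlap enrichment equals exhaustive combinatorial enumeration", {
  u <- paste0("g", 1:10)
  res <- overlap_enrichment(u[1:5], u[1:4], u)
  expect_equal(res$n_overlap, 4L)
  expect_equal(res$p_value, enum_hyper_tail(10, 5, 4, 4), tolerance = 1e-12)
  # degenerate cases
  expect_equal(overlap_enrichment(u, u, u)$p_value, 1)
  expect_equal(overlap_enrichment(u[1:3], u[4:6], u)$p_value <= 1, TRUE)
  expect_equal(overlap_enrichment(character(0), u[1:3], u)$p_value, 1)
  expect_error(overlap_enrichment(c(u, "zz"), u[1:2], u), "subsets")
  # a spread of small universes against the oracle
  set.seed(5)
  for (i in 1:25) {
    nu <- sample(4:9, 1)
    a <- sample(0:nu, 1); b <- sample(0:nu, 1)
    uu <- paste0("x", seq_len(nu))
    sa <- sample(uu, a); sb <- sample(uu, b)
    k <- length(intersect(sa, sb))
    expect_equal(overlap_enrichment(sa, sb, uu)$p_value,
                 enum_hyper_tail(nu, a, b, k), tolerance = 1e-10)
  }
})

test_that("the k-of-n marker rule drives the M-decay defect call", {
  markers <- paste0("M", 1:6)
  ctrl <- matrix(rep(c(0.9, 1.0, 1.1), each = 6), 6, 3,
                 dimnames = list(markers, NULL))
  up <- matrix(rep(c(7.5, 8, 8.5), each = 6), 6, 3,
               dimnames = list(markers, NULL))
  # 6/6 accumulated and significant
  expect_equal(call_m_decay_defect(up, ctrl)$call, "M_DECAY_DEFECT")
  # 3/6 accumulated -> below k
  mixed <- up
  mixed[4:6, ] <- ctrl[4:6, ]
  expect_equal(call_m_decay_defect(mixed, ctrl)$call, "NO_DEFECT")
  # fold > 1 everywhere but nothing significant -> NO_DEFECT
  set.seed(8)
  noisy_test <- matrix(2^rnorm(18, 0.05, 2), 6, 3,
                       dimnames = list(markers, NULL))
  noisy_ctrl <- matrix(2^rnorm(18, 0, 2), 6, 3,
                       dimnames = list(markers, NULL))
  res <- call_m_decay_defect(noisy_test, noisy_ctrl)
  expect_true(all(res$evidence$p_value[res$evidence$fold_change > 1] > 0.05))
  expect_equal(res$call, "NO_DEFECT")
  # fewer than 4 detected markers -> INDETERMINATE
  expect_equal(call_m_decay_defect(up[1:3, ], ctrl)$call, "INDETERMINATE")
  # 5 detected: proportional threshold ceiling(4 * 5 / 6) = 4
  res5 <- call_m_decay_defect(up[1:5, ], ctrl)
  expect_equal(res5$parameters$k_effective, 4)
  expect_equal(res5$call, "M_DECAY_DEFECT")
})

test_that("Z-decay groups partition as forced and never intersect", {
  genes <- c("ga", "gb", "gc")
  e <- function(fpkm) log2(fpkm + 1)
  e_nz <- setNames(e(c(15, 0, 15)), genes)
  e_n8 <- setNames(e(c(0, 15, 0)), genes)
  e_a8 <- setNames(e(c(15, 0, 0)), genes)
  res <- call_z_decay_groups(e_nz, e_n8, e_a8)
  expect_equal(res$group_a, "ga")   # degraded in normal, stable in arrested
  expect_equal(res$group_b, "gb")   # induced in normal, absent in arrested
  expect_false("gc" %in% c(res$group_a, res$group_b))  # degraded in both
  # fuzz: the two groups are disjoint for any input
  set.seed(44)
  for (i in 1:50) {
    n <- 30
    nz <- setNames(runif(n, 0, 8), paste0("g", 1:n))
    n8 <- setNames(runif(n, 0, 8), paste0("g", 1:n))
    a8 <- setNames(runif(n, 0, 8), paste0("g", 1:n))
    r <- call_z_decay_groups(nz, n8, a8)
    expect_length(intersect(r$group_a, r$group_b), 0)
  }
})

test_that("greedy concordance screening drops discordant embryos", {
  set.seed(2)
  base <- rexp(200, 0.1)
  mk <- function(noise) pmax(base * 2^rnorm(200, 0, noise), 0)
  profiles <- cbind(e1 = mk(0.2), e2 = mk(0.2), e3 = mk(0.2),
                    outlier = rexp(200, 0.1))
  rownames(profiles) <- paste0("g", 1:200)
  kept <- select_concordant_embryos(profiles, r_min = 0.9)
  expect_false("outlier" %in% kept)
  expect_setequal(kept, c("e1", "e2", "e3"))
})
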