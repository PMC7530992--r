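#' Pairwise correlation of single-embryo transcriptomes
#'
#' Pearson correlation of every sample pair on log2(FPKM + 1); an embryo
#' with zero variance yields NA for its pairs and is reported. When groups
#' are supplied, the mean off-diagonal correlation within each group is
#' returned alongside.
#'
#' @param profiles Numeric matrix, genes x embryos (FPKM), or a
#'   [stage_matrix()].
#' @param groups Optional named character vector, embryo -> group.
#' @return List: `r` (correlation matrix), `group_mean_r` (named numeric, or
#'   NULL), `zero_variance` (ids of constant profiles).
#' @export
pairwise_correlation <- function(profiles, groups = NULL) {
  m <- as_profile_matrix(profiles)
  if (ncol(m) < 2) stop("need >= 2 profiles", call. = FALSE)
  lg <- log2(m + 1)
  sds <- apply(lg, 2, stats::sd)
  zero_var <- colnames(lg)[sds == 0]
  r <- suppressWarnings(stats::cor(lg, method = "pearson"))
  group_mean_r <- NULL
  if (!is.null(groups)) {
    groups <- groups[colnames(m)]
    group_mean_r <- vapply(unique(groups), function(g) {
      ids <- colnames(m)[groups == g]
      if (length(ids) < 2) return(NA_real_)
      sub <- r[ids, ids]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    names(group_mean_r) <- unique(groups)
  }
  list(r = r, group_mean_r = group_mean_r, zero_variance = zero_var)
}

as_profile_matrix <- function(profiles) {
  if (inherits(profiles, "stage_matrix")) return(profiles$values)
  if (!is.matrix(profiles) || !is.numeric(profiles))
    stop("`profiles` must be a numeric matrix or stage_matrix", call. = FALSE)
  profiles
}

#' Principal component analysis of embryo transcriptomes
#'
#' PCA of log2(FPKM + 1) profiles: genes are centered, not scaled (the
#' prcomp default), and coordinates come from the singular value
#' decomposition of the centered matrix. Sign convention: each component's
#' loading vector has its largest-magnitude entry positive, so coordinates
#' are reproducible across sample orderings.
#'
#' @param profiles Numeric matrix genes x embryos, or a [stage_matrix()].
#' @param n_components Number of components to return; default 2.
#' @return List: `coordinates` (embryos x components), `explained_variance`
#'   (component variances), `rotation` (gene loadings).
#' @export
run_pca <- function(profiles, n_components = 2) {
  m <- as_profile_matrix(profiles)
  lg <- t(log2(m + 1))             # embryos x genes
  max_comp <- min(nrow(lg) - 1, ncol(lg))
  if (n_components > max_comp)
    stop("n_components exceeds min(samples - 1, genes) = ", max_comp,
         call. = FALSE)
  p <- stats::prcomp(lg, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- p$rotation[, k, drop = FALSE]
  coords <- p$x[, k, drop = FALSE]
  for (j in k) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  list(coordinates = coords,
       explained_variance = p$sdev[k]^2,
       total_variance = sum(p$sdev^2),
       rotation = rot)
}

#' Fold changes of pseudocounted group means
#'
#' Per-gene ratio (mean FPKM_test + 1)/(mean FPKM_ref + 1), with up/down
#' labels at each configured threshold: `up` iff ratio > t, `down` iff
#' ratio < 1/t. Swapping test and reference inverts every ratio exactly.
#'
#' @param test,ref Numeric matrices (genes x embryos) or vectors on a shared
#'   gene universe.
#' @param thresholds Fold-change thresholds; default `c(2, 5)`.
#' @param pseudocount Added to the means; default 1.
#' @return Data.frame of class `fold_change_table`: `gene`, `mean_test`,
#'   `mean_ref`, `ratio`, `log2_ratio`, and one label column `fc_<t>` per
#'   threshold; attribute `counts` tabulates labels per threshold.
#' @export
fold_changes <- function(test, ref, thresholds = c(2, 5), pseudocount = 1) {
  test <- as_gene_matrix(test); ref <- as_gene_matrix(ref)
  if (ncol(ref) == 0 || ncol(test) == 0)
    stop("empty test or reference set", call. = FALSE)
  if (!identical(rownames(test), rownames(ref)))
    stop("test and reference must share the same gene universe",
         call. = FALSE)
  mt <- rowMeans(test); mr <- rowMeans(ref)
  ratio <- (mt + pseudocount) / (mr + pseudocount)
  out <- data.frame(gene = rownames(test), mean_test = mt, mean_ref = mr,
                    ratio = ratio, log2_ratio = log2(ratio),
                    stringsAsFactors = FALSE, row.names = NULL)
  counts <- list()
  for (t in thresholds) {
    lab <- ifelse(ratio > t, "up", ifelse(ratio < 1 / t, "down", "none"))
    out[[paste0("fc_", t)]] <- lab
    counts[[as.character(t)]] <- c(up = sum(lab == "up"),
                                   down = sum(lab == "down"))
  }
  attr(out, "counts") <- counts
  class(out) <- c("fold_change_table", "data.frame")
  out
}

as_gene_matrix <- function(x) {
  if (inherits(x, "stage_matrix")) return(x$values)
  if (is.null(dim(x))) {
    if (is.null(names(x))) stop("profiles need gene names", call. = FALSE)
    return(matrix(x, ncol = 1, dimnames = list(names(x), "s1")))
  }
  x
}

#' Hypergeometric enrichment of a set overlap
#'
#' Upper-tail hypergeometric probability (one-sided Fisher model) of
#' observing at least the realized overlap between two gene sets drawn from
#' a common universe: P(X >= |A intersect B|) with X ~
#' Hypergeometric(|U|, |A|, |B|).
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of the gene universe.
#' @return List of class `overlap_result`: `n_a`, `n_b`, `n_overlap`,
#'   `n_universe`, `p_value`, `fold_enrichment`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe)))
    stop("sets must be subsets of the universe", call. = FALSE)
  k <- length(intersect(set_a, set_b))
  na <- length(set_a); nb <- length(set_b); nu <- length(universe)
  p <- stats::phyper(k - 1, na, nu - na, nb, lower.tail = FALSE)
  expected <- na * nb / nu
  structure(list(n_a = na, n_b = nb, n_overlap = k, n_universe = nu,
                 p_value = p,
                 fold_enrichment = if (expected > 0) k / expected else NA_real_),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap %d of |A|=%d, |B|=%d in universe %d; fold = %.3g, p = %.3g\n",
    x$n_overlap, x$n_a, x$n_b, x$n_universe, x$fold_enrichment, x$p_value))
  invisible(x)
}

#' Call an M-decay defect from a marker panel
#'
#' Implements the k-of-n marker rule for development-arrested zygotes: a
#' marker transcript counts as accumulated when its mean level in the test
#' group exceeds the control group (fold change > 1) and a one-way ANOVA
#' across the two groups is significant at `alpha`. The embryo (or patient)
#' is called `M_DECAY_DEFECT` when at least `k` of the `n_panel` detected
#' markers accumulated. When fewer than `n_panel` markers are detected the
#' rule is applied proportionally (ceiling(k * detected / n_panel)); fewer
#' than `min_detected` detected markers yields `INDETERMINATE`.
#'
#' @param test Numeric matrix markers x replicates: relative marker levels
#'   in the test embryo/patient (>= 3 replicates expected).
#' @param control Numeric matrix markers x replicates of the control group.
#' @param id Identifier attached to the call.
#' @param k Markers required; default 4.
#' @param n_panel Panel size the rule is stated for; default 6.
#' @param alpha Significance level; default 0.05.
#' @param min_detected Below this detected-marker count the call is
#'   `INDETERMINATE`; default 4.
#' @return A `defect_call`: list with `id`, `call`, `evidence` (per-marker
#'   fold change, p-value, accumulated flag) and `parameters`.
#' @export
call_m_decay_defect <- function(test, control, id = "embryo",
                                k = 4, n_panel = 6, alpha = 0.05,
                                min_detected = 4) {
  markers <- intersect(rownames(test), rownames(control))
  detected <- length(markers)
  evidence <- do.call(rbind, lapply(markers, function(mk) {
    x <- test[mk, ]; y <- control[mk, ]
    fc <- mean(x) / mean(y)
    p <- anova_p(c(x, y), rep(c("test", "control"), c(length(x), length(y))))
    data.frame(marker = mk, fold_change = fc, p_value = p,
               accumulated = is.finite(fc) && fc > 1 && p < alpha,
               stringsAsFactors = FALSE)
  }))
  k_eff <- ceiling(k * detected / n_panel)
  call <- if (detected < min_detected) {
    "INDETERMINATE"
  } else if (sum(evidence$accumulated) >= k_eff) {
    "M_DECAY_DEFECT"
  } else {
    "NO_DEFECT"
  }
  structure(list(id = id, call = call, evidence = evidence,
                 parameters = list(k = k, n_panel = n_panel, alpha = alpha,
                                   detected = detected, k_effective = k_eff)),
            class = "defect_call")
}

# One-way fixed-effects ANOVA p-value; degenerate zero-residual-variance
# inputs resolve deterministically (means differ -> 0, all equal -> 1).
anova_p <- function(values, groups) {
  groups <- factor(groups)
  fit <- stats::aov(values ~ groups)
  # a zero-residual fit warns; the degenerate case is resolved below
  p <- suppressWarnings(stats::anova(fit)[["Pr(>F)"]][1])
  if (is.na(p)) {
    gm <- tapply(values, groups, mean)
    p <- if (max(gm) - min(gm) > 0) 0 else 1
  }
  p
}

#' @export
print.defect_call <- function(x, ...) {
  cat(sprintf("%s: %s (%d/%d markers accumulated, need %d)\n",
              x$id, x$call, sum(x$evidence$accumulated),
              x$parameters$detected, x$parameters$k_effective))
  invisible(x)
}

#' Partition transcripts into Z-decay failure groups and call the defect
#'
#' Compares normal development (zygote and 8-cell stages) with arrested
#' 8-cell embryos on E = log2(mean FPKM + 1). Group A: transcripts degraded
#' more than 2-fold during the normal zygote-to-8-cell transition that
#' remained stable in the arrested embryos. Group B: transcripts induced
#' more than 2-fold in normal embryos (ZGA products) that failed to rise in
#' the arrested embryos. A `Z_DECAY_DEFECT` is called when Group A is
#' significantly enriched (hypergeometric, [overlap_enrichment()]) among
#' the arrested embryos' stabilized transcripts.
#'
#' @param e_normal_zygote,e_normal_8cell,e_arrested_8cell Named numeric
#'   vectors of E = log2(mean FPKM + 1) on a shared gene universe.
#' @param margin Log2 fold-change margin; default 1 (2-fold).
#' @param alpha Significance level for the enrichment; default 0.05.
#' @param id Identifier attached to the call.
#' @return List: `group_a`, `group_b` (gene vectors), `overlap`
#'   (an `overlap_result`), `call` (a `defect_call`).
#' @export
call_z_decay_groups <- function(e_normal_zygote, e_normal_8cell,
                                e_arrested_8cell, margin = 1, alpha = 0.05,
                                id = "cohort") {
  genes <- names(e_normal_zygote)
  if (is.null(genes) || !identical(genes, names(e_normal_8cell)) ||
      !identical(genes, names(e_arrested_8cell)))
    stop("the three E vectors must share one named gene universe",
         call. = FALSE)
  degraded_normal <- e_normal_zygote > e_normal_8cell + margin
  stable_arrested <- e_arrested_8cell >= e_normal_zygote - margin
  induced_normal <- e_normal_8cell > e_normal_zygote + margin
  low_arrested <- e_arrested_8cell <= e_normal_zygote + margin
  group_a <- genes[degraded_normal & stable_arrested]
  group_b <- genes[induced_normal & low_arrested]
  ov <- overlap_enrichment(genes[degraded_normal], genes[stable_arrested],
                           genes)
  call <- if (length(group_a) > 0 && ov$p_value < alpha)
    "Z_DECAY_DEFECT" else "NO_DEFECT"
  evidence <- data.frame(marker = c("group_a", "group_b"),
                         fold_change = c(ov$fold_enrichment, NA_real_),
                         p_value = c(ov$p_value, NA_real_),
                         accumulated = c(call == "Z_DECAY_DEFECT", FALSE),
                         stringsAsFactors = FALSE)
  dc <- structure(list(id = id, call = call, evidence = evidence,
                       parameters = list(margin = margin, alpha = alpha,
                                         n_group_a = length(group_a),
                                         n_group_b = length(group_b))),
                  class = "defect_call")
  list(group_a = group_a, group_b = group_b, overlap = ov, call = dc)
}

#' Greedy selection of a concordant embryo subset
#'
#' Retains the largest subset of embryos whose mean pairwise Pearson
#' correlation (log2 scale) reaches `r_min`, by greedily removing the
#' embryo with the lowest mean correlation to the rest. A screening
#' heuristic for cohorts where a minority of embryos arrested for unrelated
#' reasons.
#'
#' @param profiles Numeric matrix genes x embryos, or a [stage_matrix()].
#' @param r_min Target mean pairwise correlation; default 0.7.
#' @return Character vector of retained embryo ids.
#' @export
select_concordant_embryos <- function(profiles, r_min = 0.7) {
  r <- pairwise_correlation(profiles)$r
  ids <- colnames(r)
  repeat {
    if (length(ids) <= 2) return(ids)
    sub <- r[ids, ids]
    if (mean(sub[upper.tri(sub)]) >= r_min) return(ids)
    mean_r <- rowMeans(sub) - 1 / length(ids)  # exclude self contribution
    ids <- ids[-which.min(mean_r)]
  }
}
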