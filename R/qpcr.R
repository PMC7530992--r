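#' Relative expression from qPCR Ct values (delta-Ct method)
#'
#' level = 2^(Ct_ref - Ct_gene): one cycle fewer than the reference means a
#' 2-fold higher level, so the reference gene's level is exactly 1 in every
#' sample. Technical replicates (if mapped) are averaged on the Ct scale
#' before exponentiation; biological replicates are averaged on the linear
#' scale downstream ([qpcr_group_compare()]).
#'
#' The `convention` flag also exposes the literal exponent orientation
#' 2^(Ct_gene - Ct_ref) for cross-checking against sources that state the
#' delta the other way around.
#'
#' @param table A [qpcr_table()].
#' @param convention `"ref_minus_gene"` (default, conventional: abundant
#'   transcripts get high levels) or `"gene_minus_ref"`.
#' @param tech_replicates Optional named character vector mapping technical
#'   replicate samples to the biological sample they measure; Ct values are
#'   averaged within each biological sample first.
#' @return List of class `relative_levels`: `levels` (genes x samples
#'   matrix), `reference_gene`, `groups`.
#' @export
relative_expression <- function(table,
                                convention = c("ref_minus_gene",
                                               "gene_minus_ref"),
                                tech_replicates = NULL) {
  stopifnot(inherits(table, "qpcr_table"))
  convention <- match.arg(convention)
  ct <- table$ct
  groups <- table$groups
  if (!is.null(tech_replicates)) {
    missing_map <- setdiff(colnames(ct), names(tech_replicates))
    if (length(missing_map))
      stop("sample(s) without a technical-replicate mapping: ",
           paste(missing_map, collapse = ", "), call. = FALSE)
    bio <- tech_replicates[colnames(ct)]
    ct <- vapply(unique(bio), function(b) {
      rowMeans(ct[, bio == b, drop = FALSE])
    }, numeric(nrow(ct)))
    ct <- matrix(ct, nrow = nrow(table$ct),
                 dimnames = list(rownames(table$ct), unique(bio)))
    if (!is.null(groups))
      groups <- groups[match(unique(bio), names(tech_replicates))]
  }
  dct <- sweep(ct, 2, ct[table$reference_gene, ], `-`)
  levels <- if (convention == "ref_minus_gene") 2^(-dct) else 2^dct
  structure(list(levels = levels, reference_gene = table$reference_gene,
                 groups = groups, convention = convention),
            class = "relative_levels")
}

#' Compare relative expression between biological groups
#'
#' Per-gene two-tailed pooled-variance Student's t-test (two groups) or
#' one-way fixed-effects ANOVA F-test (two or more groups) on relative
#' levels, with the fold change of group means against a designated control
#' group. Biological replicates are averaged on the linear scale.
#'
#' @param levels A `relative_levels` from [relative_expression()], or a
#'   numeric genes x samples matrix.
#' @param groups Named character vector sample -> group (taken from the
#'   levels object when omitted).
#' @param test `"anova"` (default) or `"t_test"` (exactly two groups).
#' @param control Name of the control group for fold changes; default the
#'   first group encountered.
#' @return Data.frame: `gene`, one `mean_<group>` column per group,
#'   `fold_change_vs_control`, `statistic` (F or t), `p_value`.
#' @export
qpcr_group_compare <- function(levels, groups = NULL,
                               test = c("anova", "t_test"), control = NULL) {
  test <- match.arg(test)
  if (inherits(levels, "relative_levels")) {
    if (is.null(groups)) groups <- levels$groups
    levels <- levels$levels
  }
  if (is.null(groups)) stop("`groups` required", call. = FALSE)
  groups <- groups[colnames(levels)]
  if (anyNA(groups)) stop("every sample needs a group", call. = FALSE)
  grp <- factor(groups)
  if (nlevels(grp) < 2) stop("need >= 2 groups", call. = FALSE)
  if (test == "t_test" && nlevels(grp) != 2)
    stop("t_test requires exactly 2 groups", call. = FALSE)
  sizes <- table(grp)
  if (test == "t_test" && any(sizes < 2))
    stop("t_test requires >= 2 replicates per group", call. = FALSE)
  if (is.null(control)) control <- base::levels(grp)[1]
  if (!control %in% base::levels(grp))
    stop("control group '", control, "' not present", call. = FALSE)
  out <- do.call(rbind, lapply(rownames(levels), function(g) {
    v <- levels[g, ]
    means <- tapply(v, grp, mean)
    if (test == "t_test") {
      other <- setdiff(base::levels(grp), control)
      tt <- two_sample_t(v[grp == other], v[grp == control])
      stat <- tt$statistic; p <- tt$p.value
      fc <- means[other] / means[control]
    } else {
      fit <- suppressWarnings(stats::anova(stats::aov(v ~ grp)))
      stat <- fit[["F value"]][1]
      p <- anova_p(v, grp)
      non_ctrl <- setdiff(base::levels(grp), control)
      fc <- mean(means[non_ctrl]) / means[control]
    }
    row <- data.frame(gene = g, stringsAsFactors = FALSE)
    for (lv in base::levels(grp)) row[[paste0("mean_", lv)]] <- means[[lv]]
    row$fold_change_vs_control <- unname(fc)
    row$statistic <- stat
    row$p_value <- p
    row
  }))
  rownames(out) <- NULL
  out
}
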