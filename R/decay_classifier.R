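#' Cluster labels used by the decay classifier
#' @return Character vector of the six per-gene labels.
#' @export
cluster_levels <- function() {
  c("I", "II", "III", "IV", "UNCLASSIFIED", "NOT_MATERNAL")
}

#' Classifier configuration
#'
#' Thresholds of the fold-change rules. `log_margin = 1` encodes the 2-fold
#' criterion on the log2 scale; `maternal_fpkm_threshold = 2` is the FPKM
#' gate at the GV stage; `decay_ratio_threshold = 0.5` pre-selects decaying
#' transcripts for the ZGA-dependence comparison; `stabilization_margin = 1`
#' is the log2 drop below which decay is considered abolished under
#' transcription inhibition.
#'
#' @param maternal_fpkm_threshold GV-stage FPKM gate (strict `>`); default 2.
#' @param log_margin Fold-change margin on log2(FPKM + pseudocount); default 1.
#' @param pseudocount Added to mean FPKM before log2; default 1.
#' @param stage_triplet The three stages the cluster rules compare, in order
#'   (maternal stage, pre-ZGA stage, post-ZGA stage). Default human
#'   convention `c("GV", "zygote", "8-cell")`; use
#'   `c("GV", "zygote", "2-cell")` for the mouse convention.
#' @param decay_ratio_threshold Pseudocounted post/zygote FPKM ratio below
#'   which a transcript counts as decaying; default 0.5.
#' @param stabilization_margin Log2 drop threshold for "decay abolished";
#'   default 1.
#' @param zga_post_stage Post-ZGA stage of the inhibition comparison;
#'   default `"8-cell"` (human ZGA).
#' @param zga_ratio_orientation `"post_over_zygote"` (default) or
#'   `"zygote_over_post"`: orientation of the pre-selection ratio.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(maternal_fpkm_threshold = 2,
                              log_margin = 1,
                              pseudocount = 1,
                              stage_triplet = c("GV", "zygote", "8-cell"),
                              decay_ratio_threshold = 0.5,
                              stabilization_margin = 1,
                              zga_post_stage = "8-cell",
                              zga_ratio_orientation = c("post_over_zygote",
                                                        "zygote_over_post")) {
  zga_ratio_orientation <- match.arg(zga_ratio_orientation)
  num <- c(maternal_fpkm_threshold = maternal_fpkm_threshold,
           log_margin = log_margin, pseudocount = pseudocount,
           decay_ratio_threshold = decay_ratio_threshold,
           stabilization_margin = stabilization_margin)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all classifier thresholds must be finite and > 0", call. = FALSE)
  if (length(stage_triplet) != 3 || !all(stage_triplet %in% stage_levels()))
    stop("`stage_triplet` must be three labels from stage_levels()",
         call. = FALSE)
  structure(list(maternal_fpkm_threshold = maternal_fpkm_threshold,
                 log_margin = log_margin,
                 pseudocount = pseudocount,
                 stage_triplet = stage_triplet,
                 decay_ratio_threshold = decay_ratio_threshold,
                 stabilization_margin = stabilization_margin,
                 zga_post_stage = zga_post_stage,
                 zga_ratio_orientation = zga_ratio_orientation),
            class = "classifier_config")
}

#' Log-transform stage means
#'
#' E(stage) = log2(mean FPKM(stage) + pseudocount), replicates within a
#' stage averaged on the FPKM scale first.
#'
#' @param x A [stage_matrix()].
#' @param pseudocount Added before the log2; default 1 (so E >= 0).
#' @return Numeric matrix of E values, genes x stages.
#' @export
log_transform <- function(x, pseudocount = 1) {
  log2(stage_means(x) + pseudocount)
}

#' Select maternal transcripts by GV-stage expression
#'
#' Retains genes whose mean FPKM at the GV stage is strictly greater than
#' the threshold; the complement is labeled NOT_MATERNAL downstream.
#'
#' @param x A [stage_matrix()] containing a GV stage.
#' @param threshold FPKM gate; default 2.
#' @return Character vector of retained gene ids.
#' @export
select_maternal <- function(x, threshold = 2) {
  m <- stage_means(x)
  if (!"GV" %in% colnames(m)) stop("GV stage absent", call. = FALSE)
  rownames(m)[m[, "GV"] > threshold]
}

#' Apply the four cluster rules to E-value triples
#'
#' Vectorized over genes. With m the log margin, the rules are
#' \itemize{
#'   \item I:   E(GV) > E(zyg)+m and E(zyg) <= E(8c)+m — degraded before
#'     fertilization, stable after (M-decay candidates);
#'   \item II:  E(GV) <= E(zyg)+m and E(GV) > E(zyg)-m and E(zyg) > E(8c)+m
#'     — degraded zygote-to-8-cell (Z-decay candidates);
#'   \item III: E(GV) > E(zyg)+m and E(zyg) > E(8c)+m — continuously
#'     degraded;
#'   \item IV:  E(GV) <= E(zyg)+m and E(GV) > E(zyg)-m and
#'     E(zyg) <= E(8c)+m and E(zyg) > E(8c)-m — stable through the MZT;
#'   \item otherwise UNCLASSIFIED (e.g. up-regulated genes).
#' }
#' Inequalities are strict exactly where stated, so boundary genes are
#' deterministic.
#'
#' @param e_gv,e_zyg,e_post Numeric vectors of E values at the maternal,
#'   pre-ZGA and post-ZGA stages.
#' @param log_margin Margin m; default 1 (2-fold).
#' @return Factor with levels [cluster_levels()] (never NOT_MATERNAL here).
#' @export
cluster_rules <- function(e_gv, e_zyg, e_post, log_margin = 1) {
  m <- log_margin
  is1 <- e_gv > e_zyg + m & e_zyg <= e_post + m
  is2 <- e_gv <= e_zyg + m & e_gv > e_zyg - m & e_zyg > e_post + m
  is3 <- e_gv > e_zyg + m & e_zyg > e_post + m
  is4 <- e_gv <= e_zyg + m & e_gv > e_zyg - m &
    e_zyg <= e_post + m & e_zyg > e_post - m
  out <- rep("UNCLASSIFIED", length(e_gv))
  out[is4] <- "IV"
  out[is3] <- "III"
  out[is2] <- "II"
  out[is1] <- "I"
  factor(out, levels = cluster_levels())
}

#' Classify maternal transcript decay patterns
#'
#' Runs the full pipeline on one stage matrix: maternal selection at the GV
#' stage, the +pseudocount/log2 transform of stage means, and the Cluster
#' I-IV rules on the configured stage triplet. Every input gene receives
#' exactly one label, so cluster sizes always sum to the gene universe.
#'
#' @param x A [stage_matrix()] containing at least the three stages of
#'   `config$stage_triplet`.
#' @param config A [classifier_config()].
#' @return A data.frame of class `decay_classification` with columns `gene`,
#'   `cluster`, one `e_<stage>` column per triplet stage, `zga_dependent`
#'   and `morula_degraded` (both initialized to `"not_applicable"`).
#' @export
classify_decay <- function(x, config = classifier_config()) {
  trip <- config$stage_triplet
  e <- log_transform(x, config$pseudocount)
  missing <- setdiff(trip, colnames(e))
  if (length(missing))
    stop("required stage(s) absent: ", paste(missing, collapse = ", "),
         call. = FALSE)
  maternal <- select_maternal(x, config$maternal_fpkm_threshold)
  genes <- rownames(x$values)
  cluster <- factor(rep("NOT_MATERNAL", length(genes)),
                    levels = cluster_levels())
  idx <- genes %in% maternal
  cluster[idx] <- cluster_rules(e[idx, trip[1]], e[idx, trip[2]],
                                e[idx, trip[3]], config$log_margin)
  out <- data.frame(gene = genes, cluster = cluster,
                    stringsAsFactors = FALSE)
  for (s in trip) out[[paste0("e_", gsub("-", "", s))]] <- e[, s]
  out$zga_dependent <- "not_applicable"
  out$morula_degraded <- "not_applicable"
  attr(out, "config") <- config
  class(out) <- c("decay_classification", "data.frame")
  out
}

#' Morula-stage extension of Cluster IV
#'
#' Cluster IV transcripts are stable through the 8-cell stage; this flags
#' the subset additionally degraded between the 8-cell and morula stages,
#' by the same 2-fold rule as the main clustering:
#' E(8-cell) > E(morula) + log_margin.
#'
#' @param x A [stage_matrix()]; if the morula stage is absent all genes keep
#'   `morula_degraded = "not_applicable"`.
#' @param classification A `decay_classification` from [classify_decay()].
#' @param config A [classifier_config()].
#' @return The classification with `morula_degraded` set to `"degraded"` or
#'   `"stable"` for Cluster IV genes.
#' @export
classify_morula_extension <- function(x, classification,
                                      config = classifier_config()) {
  stopifnot(inherits(classification, "decay_classification"))
  e <- log_transform(x, config$pseudocount)
  if (!"morula" %in% colnames(e)) {
    classification$morula_degraded <- "not_applicable"
    return(classification)
  }
  post <- config$stage_triplet[3]
  if (!post %in% colnames(e))
    stop("stage '", post, "' absent", call. = FALSE)
  iv <- classification$cluster == "IV"
  g <- classification$gene[iv]
  drop8m <- e[g, post] - e[g, "morula"]
  classification$morula_degraded[iv] <-
    ifelse(drop8m > config$log_margin, "degraded", "stable")
  classification
}

#' Call ZGA dependence of Z-decay from a transcription-inhibition pair
#'
#' Compares matched control and alpha-amanitin-treated matrices. Cluster
#' II/III transcripts that decay in controls — pseudocounted FPKM ratio
#' (post-ZGA + 1)/(zygote + 1) below `decay_ratio_threshold` — are called
#' `dependent` when the treated-matrix log2 drop from zygote to the post-ZGA
#' stage falls below `stabilization_margin` while the control drop is at
#' least that margin (decay abolished by the transcription block), and
#' `independent` otherwise. All other genes keep `not_applicable`.
#'
#' @param control A [stage_matrix()] of untreated embryos with the zygote
#'   and post-ZGA stages.
#' @param treated A [stage_matrix()] of alpha-amanitin-treated embryos; its
#'   `meta$treatment` must flag every sample `"alpha-amanitin"`.
#' @param classification A `decay_classification`.
#' @param config A [classifier_config()]; `zga_post_stage` sets the post-ZGA
#'   stage (default 8-cell) and `zga_ratio_orientation` the ratio direction.
#' @return The classification with `zga_dependent` filled in for the
#'   selected Cluster II/III genes.
#' @export
zga_dependence <- function(control, treated, classification,
                           config = classifier_config()) {
  stopifnot(inherits(classification, "decay_classification"))
  if (is.null(treated$meta) || is.null(treated$meta$treatment) ||
      !all(treated$meta$treatment == "alpha-amanitin"))
    stop("treated matrix must flag every sample treatment = 'alpha-amanitin'",
         call. = FALSE)
  post <- config$zga_post_stage
  mc <- stage_means(control)
  mt <- stage_means(treated)
  for (nm in c("zygote", post)) {
    if (!nm %in% colnames(mc)) stop("control lacks stage '", nm, "'",
                                    call. = FALSE)
    if (!nm %in% colnames(mt)) stop("treated lacks stage '", nm, "'",
                                    call. = FALSE)
  }
  g <- classification$gene
  pc <- config$pseudocount
  ratio <- (mc[g, post] + pc) / (mc[g, "zygote"] + pc)
  if (config$zga_ratio_orientation == "zygote_over_post")
    ratio <- 1 / ratio
  selected <- classification$cluster %in% c("II", "III") &
    ratio < config$decay_ratio_threshold
  drop_ctrl <- log2(mc[g, "zygote"] + pc) - log2(mc[g, post] + pc)
  drop_trt <- log2(mt[g, "zygote"] + pc) - log2(mt[g, post] + pc)
  dep <- drop_trt < config$stabilization_margin &
    drop_ctrl >= config$stabilization_margin
  classification$zga_dependent <- ifelse(
    selected, ifelse(dep, "dependent", "independent"), "not_applicable")
  classification
}

#' Summarize a decay classification
#' @param object A `decay_classification`.
#' @param ... Unused.
#' @return Named integer vector of cluster sizes (plus morula/ZGA counts as
#'   attributes).
#' @export
summary.decay_classification <- function(object, ...) {
  out <- table(object$cluster)
  attr(out, "morula_degraded") <- sum(object$morula_degraded == "degraded")
  attr(out, "zga_dependent") <- sum(object$zga_dependent == "dependent")
  out
}
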