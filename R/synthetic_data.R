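#' Default class proportions of the synthetic stage matrix
#'
#' The observed composition of the 7271 selected human maternal transcripts:
#' Cluster I 2372, II 2259, III 1109, IV 1531 (proportions thereof), with no
#' up-regulated or non-maternal genes unless requested.
#'
#' @return Named numeric vector over
#'   \{I, II, III, IV, UNCLASSIFIED, NOT_MATERNAL\} summing to 1.
#' @export
default_class_proportions <- function() {
  p <- c(I = 2372, II = 2259, III = 1109, IV = 1531,
         UNCLASSIFIED = 0, NOT_MATERNAL = 0)
  p / sum(p)
}

#' Generate a stage-wise expression matrix with planted decay classes
#'
#' Genes draw a log-normal baseline at the GV stage; each planted class then
#' applies its deterministic fold drops at the planted stages, on the
#' pseudocounted scale so every planted drop is exactly log2(decay_fold) in
#' E = log2(FPKM + 1) units; finally multiplicative log-normal noise
#' (additive Gaussian of sd `noise_sd` on log2 FPKM) perturbs every sample
#' independently. Planted profiles per class:
#' \itemize{
#'   \item I: drop at GV -> zygote, then stable;
#'   \item II: stable to zygote, drop at zygote -> 8-cell;
#'   \item III: drops at both transitions;
#'   \item IV: stable throughout; a `morula_degraded_fraction` subset drops
#'     at 8-cell -> morula;
#'   \item UNCLASSIFIED: up-regulated (rise at GV -> zygote), matching no
#'     cluster rule;
#'   \item NOT_MATERNAL: uniform FPKM on (0, 1), below the GV gate.
#' }
#' Maternal baselines are truncated at log2 FPKM >= 4 so planted genes clear
#' the FPKM > 2 GV gate and every planted drop carries its full margin over
#' the 2-fold rule.
#'
#' @param n_genes Number of genes.
#' @param class_proportions Named proportions over the six labels, summing
#'   to 1 (tolerance 1e-9); default [default_class_proportions()].
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2-FPKM
#'   distribution at GV; defaults 5 and 1.2.
#' @param decay_fold Planted stage-to-stage fold change (> 2, i.e. beyond
#'   the rule margin); default 4.
#' @param noise_sd Gaussian noise sd on the log2 scale; default 0.25.
#' @param morula_degraded_fraction Fraction of Cluster IV genes planted to
#'   degrade between 8-cell and morula; default 176/1531.
#' @param n_replicates Samples per stage; default 1.
#' @param stages Stages to emit; default GV, zygote, 8-cell, morula.
#' @param seed Mandatory integer seed.
#' @return List: `matrix` (a [stage_matrix()]), `truth` (data.frame `gene`,
#'   `cluster`, `morula_degraded`, `baseline_log2`), `params`.
#' @export
generate_stage_matrix <- function(n_genes = 7271,
                                  class_proportions = default_class_proportions(),
                                  baseline_log2_mean = 5,
                                  baseline_log2_sd = 1.2,
                                  decay_fold = 4,
                                  noise_sd = 0.25,
                                  morula_degraded_fraction = 176 / 1531,
                                  n_replicates = 1,
                                  stages = c("GV", "zygote", "8-cell",
                                             "morula"),
                                  seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1", call. = FALSE)
  if (decay_fold <= 2)
    stop("decay_fold must exceed 2 (the rule margin)", call. = FALSE)
  labels <- cluster_levels()
  props <- class_proportions[labels]
  props[is.na(props)] <- 0
  rng <- local_rng(seed)
  cls <- sample(labels, n_genes, replace = TRUE, prob = props)
  genes <- sprintf("G%05d", seq_len(n_genes))

  # baseline on the log2 FPKM scale, truncated for maternal classes
  b <- stats::rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
  maternal <- cls != "NOT_MATERNAL"
  b[maternal] <- pmax(b[maternal], 4)
  d <- log2(decay_fold)

  morula_deg <- cls == "IV" &
    stats::runif(n_genes) < morula_degraded_fraction

  # per-stage true log2(FPKM + 1); drops applied on the pseudocounted scale
  e0 <- log2(2^b + 1)
  drops <- matrix(0, n_genes, length(stages),
                  dimnames = list(genes, stages))
  stage_after <- function(s) which(stages == s):length(stages)
  add_drop <- function(drops, rows, from_stage, amount) {
    if ("zygote" %in% stages && from_stage == "GV")
      cols <- stage_after("zygote")
    else if (from_stage == "zygote" && "8-cell" %in% stages)
      cols <- stage_after("8-cell")
    else if (from_stage == "8-cell" && "morula" %in% stages)
      cols <- stage_after("morula")
    else return(drops)
    drops[rows, cols] <- drops[rows, cols] + amount
    drops
  }
  drops <- add_drop(drops, cls == "I", "GV", d)
  drops <- add_drop(drops, cls == "II", "zygote", d)
  drops <- add_drop(drops, cls == "III", "GV", d)
  drops <- add_drop(drops, cls == "III", "zygote", d)
  drops <- add_drop(drops, morula_deg, "8-cell", d)
  drops <- add_drop(drops, cls == "UNCLASSIFIED", "GV", -d)  # up-regulated

  e_true <- pmax(e0 - drops, 0)
  fpkm_true <- 2^e_true - 1
  fpkm_true[cls == "NOT_MATERNAL", ] <- stats::runif(
    sum(cls == "NOT_MATERNAL") * length(stages))

  sample_names <- as.vector(t(outer(stages, seq_len(n_replicates),
                                    function(s, r) paste0(s, "_r", r))))
  stage_of <- rep(stages, each = n_replicates)
  names(stage_of) <- sample_names
  vals <- matrix(0, n_genes, length(sample_names),
                 dimnames = list(genes, sample_names))
  for (j in seq_along(sample_names)) {
    f <- fpkm_true[, stage_of[sample_names[j]]]
    noise <- if (noise_sd > 0) 2^stats::rnorm(n_genes, 0, noise_sd) else 1
    vals[, j] <- f * noise
  }
  rng$restore()

  truth <- data.frame(
    gene = genes, cluster = cls,
    morula_degraded = ifelse(cls == "IV",
                             ifelse(morula_deg, "degraded", "stable"),
                             "not_applicable"),
    baseline_log2 = b, stringsAsFactors = FALSE)
  params <- list(n_genes = n_genes, class_proportions = as.list(props),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 decay_fold = decay_fold, noise_sd = noise_sd,
                 morula_degraded_fraction = morula_degraded_fraction,
                 n_replicates = n_replicates, stages = stages, seed = seed)
  list(matrix = stage_matrix(vals, stage_of), truth = truth, params = params)
}

# Scoped RNG: seed without touching the caller's .Random.seed.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

#' Generate a matched control / alpha-amanitin pair
#'
#' Rebuilds zygote and post-ZGA stage profiles from a planted truth table.
#' In the treated matrix, Cluster II/III genes sampled as ZGA-dependent
#' (probability `zga_dependent_fraction`) lose their post-ZGA drop —
#' transcription inhibition abolishes their decay — while ZGA-independent
#' genes decay identically in both matrices.
#'
#' @param truth Truth data.frame from [generate_stage_matrix()] (columns
#'   `gene`, `cluster`, `baseline_log2`).
#' @param zga_dependent_fraction Probability that a Cluster II/III gene is
#'   ZGA-dependent; default 0.5.
#' @param decay_fold,noise_sd,n_replicates As in [generate_stage_matrix()].
#' @param post_stage Post-ZGA stage label; default `"8-cell"`.
#' @param seed Mandatory integer seed.
#' @return List: `control`, `treated` (both [stage_matrix()]; treated
#'   samples carry `treatment = "alpha-amanitin"` metadata), `truth` (input
#'   truth with a `zga_dependent` column), `params`.
#' @export
generate_amanitin_pair <- function(truth, zga_dependent_fraction = 0.5,
                                   decay_fold = 4, noise_sd = 0.25,
                                   n_replicates = 1, post_stage = "8-cell",
                                   seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  rng <- local_rng(seed)
  n <- nrow(truth)
  cls <- truth$cluster
  z_candidate <- cls %in% c("II", "III")
  dep <- z_candidate & stats::runif(n) < zga_dependent_fraction
  d <- log2(decay_fold)

  e0 <- log2(2^truth$baseline_log2 + 1)
  # zygote-stage E: cluster I/III already dropped once at fertilization
  e_zyg <- e0 - d * (cls %in% c("I", "III"))
  # post-ZGA drop applies to II and III in controls
  post_drop <- d * (cls %in% c("II", "III"))
  e_post_ctrl <- pmax(e_zyg - post_drop, 0)
  e_post_trt <- pmax(e_zyg - post_drop * !dep, 0)
  e_zyg <- pmax(e_zyg, 0)

  f_zyg <- 2^e_zyg - 1
  f_ctrl <- 2^e_post_ctrl - 1
  f_trt <- 2^e_post_trt - 1
  nm <- cls == "NOT_MATERNAL"
  f_zyg[nm] <- stats::runif(sum(nm)); f_ctrl[nm] <- stats::runif(sum(nm))
  f_trt[nm] <- stats::runif(sum(nm))

  build <- function(f_z, f_p, treated) {
    sn <- c(paste0("zygote_r", seq_len(n_replicates)),
            paste0(post_stage, "_r", seq_len(n_replicates)))
    stage_of <- rep(c("zygote", post_stage), each = n_replicates)
    names(stage_of) <- sn
    vals <- matrix(0, n, length(sn), dimnames = list(truth$gene, sn))
    for (j in seq_along(sn)) {
      f <- if (stage_of[j] == "zygote") f_z else f_p
      noise <- if (noise_sd > 0) 2^stats::rnorm(n, 0, noise_sd) else 1
      vals[, j] <- f * noise
    }
    meta <- data.frame(sample = sn,
                       treatment = if (treated) "alpha-amanitin" else "none",
                       stringsAsFactors = FALSE)
    stage_matrix(vals, stage_of, meta = meta)
  }
  control <- build(f_zyg, f_ctrl, treated = FALSE)
  treated <- build(f_zyg, f_trt, treated = TRUE)
  rng$restore()

  truth$zga_dependent <- ifelse(z_candidate,
                                ifelse(dep, "dependent", "independent"),
                                "not_applicable")
  list(control = control, treated = treated, truth = truth,
       params = list(zga_dependent_fraction = zga_dependent_fraction,
                     decay_fold = decay_fold, noise_sd = noise_sd,
                     n_replicates = n_replicates, post_stage = post_stage,
                     seed = seed))
}

#' Generate synthetic 3'-UTRs with class-specific lengths and motif rates
#'
#' Backgrounds are i.i.d. uniform A/C/G/T; planted CPE/PAS motifs are
#' inserted at random non-overlapping positions at Poisson counts
#' proportional to length. Z-decay UTRs are longer and carry twice the
#' motif rates of M-decay UTRs by default, emulating the observed contrast
#' between the classes. Chance background matches can add to the planted
#' counts, so the truth records the post-hoc scanned count (via
#' [count_motifs()]) as authoritative, alongside the planted count.
#'
#' @param classification A `decay_classification`, or any data.frame with
#'   `gene` and `cluster` columns.
#' @param length_meanlog Named list of per-class mean UTR length (nt) on the
#'   natural scale of a log-normal; default M-decay 500, Z-decay 1000,
#'   other 600.
#' @param length_sdlog sdlog of the length distribution; default 0.4.
#' @param cpe_rate,pas_rate Named lists of planted motifs per kilobase;
#'   defaults M-decay 4, Z-decay 8 (CPE) and M-decay 3, Z-decay 6 (PAS).
#' @param seed Mandatory integer seed.
#' @return List: `sequences` (named character), `truth` (data.frame with
#'   planted and scanned counts), `params`.
#' @export
generate_utrs <- function(classification,
                          length_meanlog = list("M-decay" = 500,
                                                "Z-decay" = 1000,
                                                other = 600),
                          length_sdlog = 0.4,
                          cpe_rate = list("M-decay" = 4, "Z-decay" = 8,
                                          other = 4),
                          pas_rate = list("M-decay" = 3, "Z-decay" = 6,
                                          other = 3),
                          seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  cl <- as.character(classification$cluster)
  decay_class <- ifelse(cl == "I", "M-decay",
                        ifelse(cl == "II", "Z-decay", "other"))
  genes <- classification$gene
  n <- length(genes)
  rng <- local_rng(seed)
  len <- as.integer(round(stats::rlnorm(
    n, log(unlist(length_meanlog)[decay_class]) - length_sdlog^2 / 2,
    length_sdlog)))
  len <- pmax(len, 20L)
  cpe <- cpe_motifs(); pas <- pas_motifs()
  seqs <- character(n)
  planted_cpe <- integer(n); planted_pas <- integer(n)
  # non-overlap guaranteed by a start-position grid with stride >= the
  # longest motif (7 nt)
  stride <- 8L
  for (i in seq_len(n)) {
    s <- sample(c("A", "C", "G", "T"), len[i], replace = TRUE)
    n_cpe <- stats::rpois(1, unlist(cpe_rate)[[decay_class[i]]] * len[i] / 1000)
    n_pas <- stats::rpois(1, unlist(pas_rate)[[decay_class[i]]] * len[i] / 1000)
    ins <- c(sample(cpe, n_cpe, replace = TRUE),
             sample(pas, n_pas, replace = TRUE))
    grid <- seq.int(1L, max(len[i] - stride + 1L, 1L), by = stride)
    n_place <- min(length(ins), length(grid))
    ins <- ins[seq_len(n_place)]
    pos <- sample(grid, n_place)
    for (j in seq_len(n_place)) {
      w <- nchar(ins[j])
      s[pos[j]:(pos[j] + w - 1L)] <- strsplit(ins[j], "")[[1]]
    }
    planted_cpe[i] <- sum(ins %in% cpe)
    planted_pas[i] <- sum(ins %in% pas)
    seqs[i] <- paste(s, collapse = "")
  }
  rng$restore()
  names(seqs) <- genes
  truth <- data.frame(gene = genes, decay_class = decay_class, length = len,
                      planted_cpe = planted_cpe, planted_pas = planted_pas,
                      cpe_count = count_motifs(seqs, cpe),
                      pas_count = count_motifs(seqs, pas),
                      stringsAsFactors = FALSE)
  list(sequences = seqs, truth = truth,
       params = list(length_meanlog = length_meanlog,
                     length_sdlog = length_sdlog, cpe_rate = cpe_rate,
                     pas_rate = pas_rate, seed = seed))
}

#' Generate an arrested-embryo cohort with planted M-decay defects
#'
#' Emulates qPCR-style relative marker levels in development-arrested
#' zygotes. Control embryos (meiotic-arrest controls, where maternal decay
#' proceeds normally) show degraded M-decay markers at baseline level 1;
#' embryos with a planted M-decay defect stabilize the marker panel at
#' `stabilized_fold` and down-shift the decay-machinery transcripts
#' (BTG4/CNOT7/CNOT6L-like) by `machinery_fold`; non-defective arrested
#' embryos follow the control distribution. Multiplicative log-normal noise
#' of sd `noise_sd` (log2 scale) applies per replicate.
#'
#' @param n_embryos Number of test embryos; default 200.
#' @param defect_spec Named proportions over \{m_decay, none\}; default
#'   50/50.
#' @param n_replicates qPCR replicates per embryo and per control; default 3.
#' @param n_controls Control embryos; default 4.
#' @param stabilized_fold Marker fold accumulation under a defect; default 8.
#' @param machinery_fold Machinery down-shift under a defect; default 0.25.
#' @param noise_sd Log2-scale noise sd; default 0.25.
#' @param seed Mandatory integer seed.
#' @return List: `embryos` (named list of marker x replicate matrices),
#'   `control` (marker x replicate matrix pooling the control embryos),
#'   `truth` (data.frame `embryo`, `defect`), `markers`, `machinery`,
#'   `params`.
#' @export
generate_arrested_cohort <- function(n_embryos = 200,
                                     defect_spec = c(m_decay = 0.5,
                                                     none = 0.5),
                                     n_replicates = 3, n_controls = 4,
                                     stabilized_fold = 8,
                                     machinery_fold = 0.25,
                                     noise_sd = 0.25, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (abs(sum(defect_spec) - 1) > 1e-9)
    stop("defect_spec proportions must sum to 1", call. = FALSE)
  markers <- paste0("MDECAY_M", 1:6)
  machinery <- c("BTG4", "CNOT7", "CNOT6L")
  panel <- c(markers, machinery)
  rng <- local_rng(seed)
  defects <- sample(names(defect_spec), n_embryos, replace = TRUE,
                    prob = defect_spec)
  noisy <- function(base, k) {
    m <- matrix(rep(base, k), nrow = length(base),
                dimnames = list(panel, paste0("rep", seq_len(k))))
    if (noise_sd > 0)
      m <- m * 2^matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))
    m
  }
  base_control <- stats::setNames(rep(1, length(panel)), panel)
  control <- do.call(cbind, lapply(seq_len(n_controls), function(i) {
    m <- noisy(base_control, n_replicates)
    colnames(m) <- paste0("ctrl", i, "_", colnames(m))
    m
  }))
  embryos <- lapply(seq_len(n_embryos), function(i) {
    base <- base_control
    if (defects[i] == "m_decay") {
      base[markers] <- stabilized_fold
      base[machinery] <- machinery_fold
    }
    noisy(base, n_replicates)
  })
  names(embryos) <- sprintf("embryo_%03d", seq_len(n_embryos))
  rng$restore()
  list(embryos = embryos, control = control,
       truth = data.frame(embryo = names(embryos), defect = defects,
                          stringsAsFactors = FALSE),
       markers = markers, machinery = machinery,
       params = list(n_embryos = n_embryos,
                     defect_spec = as.list(defect_spec),
                     n_replicates = n_replicates, n_controls = n_controls,
                     stabilized_fold = stabilized_fold,
                     machinery_fold = machinery_fold, noise_sd = noise_sd,
                     seed = seed))
}

#' Generate a qPCR Ct table from known relative levels
#'
#' Ct_gene = ref_ct - log2(level) + Gaussian noise, with the reference gene
#' fixed at `ref_ct`; inverting through [relative_expression()] recovers
#' the levels exactly at noise 0.
#'
#' @param levels Numeric genes x samples matrix of relative levels (> 0).
#' @param reference_gene Name of the reference gene row to add; default
#'   `"GAPDH"`.
#' @param ref_ct Reference-gene Ct; default 20.
#' @param noise_sd Gaussian Ct noise sd; default 0.
#' @param groups Optional sample -> group mapping, passed through.
#' @param seed Mandatory integer seed.
#' @return A [qpcr_table()].
#' @export
generate_ct_table <- function(levels, reference_gene = "GAPDH", ref_ct = 20,
                              noise_sd = 0, groups = NULL, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (any(levels <= 0)) stop("levels must be > 0", call. = FALSE)
  rng <- local_rng(seed)
  ct <- ref_ct - log2(levels)
  if (noise_sd > 0)
    ct <- ct + matrix(stats::rnorm(length(ct), 0, noise_sd), nrow(ct))
  ct <- rbind(ct, matrix(ref_ct, 1, ncol(ct),
                         dimnames = list(reference_gene, colnames(ct))))
  rng$restore()
  qpcr_table(ct, reference_gene, groups = groups)
}
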