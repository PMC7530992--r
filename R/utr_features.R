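#' Consensus CPE and PAS motif sets
#'
#' Cytoplasmic polyadenylation elements (CPE, consensus UUUUAU/UUUUAAU) and
#' polyadenylation signals (PAS, AAUAAA/AUUAAA), given in the DNA alphabet
#' (U -> T) because UTR sequences derive from genomic annotation.
#'
#' @return Character vector of motifs.
#' @export
cpe_motifs <- function() c("TTTTAT", "TTTTAAT")

#' @rdname cpe_motifs
#' @export
pas_motifs <- function() c("AATAAA", "ATTAAA")

#' Count motif occurrences in sequences
#'
#' Counts every start position at which any motif of the set matches
#' exactly; overlapping occurrences are all counted, and a position matching
#' several motifs counts once per motif. Scanning is strand-specific: the
#' given strand only, no reverse complement. `N` matches nothing.
#'
#' @param sequences Character vector of DNA/RNA sequences (U is normalized
#'   to T, case-insensitive).
#' @param motifs Non-empty character vector of exact motifs (A/C/G/T).
#' @return Integer vector of counts, one per sequence.
#' @export
count_motifs <- function(sequences, motifs) {
  if (length(motifs) == 0) stop("empty motif set", call. = FALSE)
  motifs <- chartr("U", "T", toupper(motifs))
  if (any(grepl("[^ACGT]", motifs)))
    stop("motifs must use the A/C/G/T alphabet", call. = FALSE)
  sequences <- chartr("U", "T", toupper(sequences))
  counts <- integer(length(sequences))
  for (m in motifs) {
    # lookahead so overlapping occurrences are all found
    hits <- gregexpr(paste0("(?=", m, ")"), sequences, perl = TRUE)
    counts <- counts + vapply(hits, function(h) sum(h > 0), integer(1))
  }
  counts
}

#' Expected per-nucleotide motif match rate under a uniform background
#'
#' Probability that a random position of an i.i.d. uniform A/C/G/T sequence
#' starts a match of any motif in the set: sum of 4^-length over the motifs.
#' Used to background-correct motif-rate estimates on synthetic UTRs.
#'
#' @param motifs Character vector of exact motifs.
#' @return Expected matches per nucleotide.
#' @export
motif_background_rate <- function(motifs) {
  sum(4^-nchar(chartr("U", "T", toupper(motifs))))
}

#' Annotate 3'-UTRs with length and motif counts, joined to decay classes
#'
#' M-decay transcripts are Cluster I (cleared before ZGA by maternal
#' factors); Z-decay transcripts are Cluster II (cleared after ZGA and
#' requiring zygotic transcription). Genes without a UTR annotation, and
#' genes with a zero-length UTR, are excluded from comparisons and reported
#' in attributes.
#'
#' @param sequences Named character vector of 5'->3' UTR sequences (e.g.
#'   from [read_utr_sequences()]).
#' @param classification A `decay_classification`.
#' @return Data.frame with columns `gene`, `cluster`, `decay_class`
#'   (`"M-decay"`, `"Z-decay"` or `"other"`), `length`, `cpe_count`,
#'   `pas_count`; attributes `unmatched` (classified genes without UTR) and
#'   `zero_length` (genes dropped for empty UTRs).
#' @export
annotate_utrs <- function(sequences, classification) {
  stopifnot(inherits(classification, "decay_classification"))
  genes <- intersect(classification$gene, names(sequences))
  unmatched <- setdiff(classification$gene, names(sequences))
  seqs <- sequences[genes]
  zero_len <- genes[nchar(seqs) == 0]
  keep <- nchar(seqs) > 0
  genes <- genes[keep]; seqs <- seqs[keep]
  cl <- classification$cluster[match(genes, classification$gene)]
  out <- data.frame(
    gene = genes,
    cluster = as.character(cl),
    decay_class = ifelse(cl == "I", "M-decay",
                         ifelse(cl == "II", "Z-decay", "other")),
    length = nchar(seqs),
    cpe_count = count_motifs(seqs, cpe_motifs()),
    pas_count = count_motifs(seqs, pas_motifs()),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "unmatched") <- unmatched
  attr(out, "zero_length") <- zero_len
  out
}

#' Compare a UTR feature between M-decay and Z-decay classes
#'
#' Two-sample two-tailed Student's t-test (pooled variance by default;
#' Welch behind the `welch` flag) on a UTR feature, plus the per-class
#' summary statistics of the box plots: n, mean, SEM, median, and the
#' 2.5/25/75/97.5 percentiles.
#'
#' @param records Data.frame from [annotate_utrs()].
#' @param feature One of `"length"`, `"cpe_count"`, `"pas_count"`.
#' @param classes The two `decay_class` labels to compare; default M-decay
#'   vs Z-decay.
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   Student's test; default FALSE.
#' @return List of class `class_comparison`: `feature`, `summary` (per-class
#'   data.frame), `t_statistic`, `df`, `p_value`.
#' @export
compare_classes <- function(records,
                            feature = c("length", "cpe_count", "pas_count"),
                            classes = c("M-decay", "Z-decay"),
                            welch = FALSE) {
  feature <- match.arg(feature)
  if (length(classes) != 2) stop("exactly two classes required", call. = FALSE)
  vals <- lapply(classes, function(cl) records[[feature]][records$decay_class == cl])
  ns <- lengths(vals)
  if (any(ns < 2))
    stop("class '", classes[ns < 2][1], "' has fewer than 2 genes",
         call. = FALSE)
  tt <- two_sample_t(vals[[1]], vals[[2]], welch = welch)
  qs <- c(0.025, 0.25, 0.75, 0.975)
  summ <- do.call(rbind, lapply(seq_along(classes), function(i) {
    v <- vals[[i]]
    q <- stats::quantile(v, qs, names = FALSE, type = 7)
    data.frame(class = classes[i], n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), median = stats::median(v),
               q2.5 = q[1], q25 = q[2], q75 = q[3], q97.5 = q[4],
               stringsAsFactors = FALSE)
  }))
  structure(list(feature = feature, summary = summ,
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 welch = welch),
            class = "class_comparison")
}

# Two-sample two-tailed t-test via stats::t.test, with the zero-variance
# degenerate case resolved deterministically: equal means -> t = 0, p = 1;
# unequal means -> t = +/-Inf, p = 0.
two_sample_t <- function(x, y, welch = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    d <- mean(x) - mean(y)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                parameter = length(x) + length(y) - 2,
                p.value = if (d == 0) 1 else 0))
  }
  tt <- stats::t.test(x, y, var.equal = !welch, alternative = "two.sided")
  list(statistic = unname(tt$statistic), parameter = unname(tt$parameter),
       p.value = tt$p.value)
}

#' @export
print.class_comparison <- function(x, ...) {
  cat(sprintf("%s: %s t-test, t = %.4g, df = %.4g, p = %.4g\n",
              x$feature, if (x$welch) "Welch" else "Student's (pooled)",
              x$t_statistic, x$df, x$p_value))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
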