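#' Controlled vocabulary of developmental stages
#'
#' Stage labels recognized throughout the package, ordered by developmental
#' time: germinal-vesicle (GV) and metaphase-II (MII) oocytes, then zygote
#' through blastocyst.
#'
#' @return Character vector of the eight stage labels.
#' @export
stage_levels <- function() {
  c("GV", "MII", "zygote", "2-cell", "4-cell", "8-cell", "morula", "blastocyst")
}

#' Recognized sample treatments
#' @return Character vector of treatment labels.
#' @export
treatment_levels <- function() {
  c("none", "alpha-amanitin", "verteporfin")
}

#' Construct a stage-wise expression matrix
#'
#' The substrate of all decay classification: a genes x samples matrix of
#' FPKM values, with every sample assigned to one developmental stage and
#' optional per-sample metadata (patient, genotype, treatment).
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames). All values must be finite and non-negative.
#' @param stages Named character vector mapping every sample (name) to a
#'   stage label from [stage_levels()].
#' @param meta Optional data.frame of per-sample attributes with a `sample`
#'   column; may carry `patient`, `genotype`, `treatment`.
#' @return An object of class `stage_matrix`.
#' @export
stage_matrix <- function(values, stages, meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-finite or negative FPKM at gene '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  }
  samples <- colnames(values)
  missing_stage <- setdiff(samples, names(stages))
  if (length(missing_stage))
    stop("sample(s) without a stage: ", paste(missing_stage, collapse = ", "),
         call. = FALSE)
  stages <- stages[samples]
  unknown <- setdiff(unique(stages), stage_levels())
  if (length(unknown))
    stop("unknown stage label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(meta)) {
    if (!is.data.frame(meta) || is.null(meta$sample))
      stop("`meta` must be a data.frame with a `sample` column", call. = FALSE)
    meta <- meta[match(samples, meta$sample), , drop = FALSE]
    if (anyNA(meta$sample))
      stop("`meta` does not cover every sample", call. = FALSE)
    if (!is.null(meta$treatment)) {
      bad_t <- setdiff(unique(meta$treatment), treatment_levels())
      if (length(bad_t))
        stop("unknown treatment(s): ", paste(bad_t, collapse = ", "),
             call. = FALSE)
    }
    rownames(meta) <- NULL
  }
  structure(list(values = values, stages = stages, meta = meta),
            class = "stage_matrix")
}

#' @export
print.stage_matrix <- function(x, ...) {
  cat(sprintf("stage_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(factor(x$stages, levels = stage_levels()))
  tab <- tab[tab > 0]
  cat("samples per stage:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.stage_matrix <- function(x) dim(x$values)

#' Per-stage mean FPKM
#'
#' Aggregates replicate samples within each stage by the arithmetic mean of
#' FPKM, the aggregation applied before any log transform.
#'
#' @param x A [stage_matrix()].
#' @return Numeric matrix, genes x stages (stages in developmental order).
#' @export
stage_means <- function(x) {
  stopifnot(inherits(x, "stage_matrix"))
  stages_present <- intersect(stage_levels(), unique(x$stages))
  out <- vapply(stages_present, function(s) {
    cols <- which(x$stages == s)
    rowMeans(x$values[, cols, drop = FALSE])
  }, numeric(nrow(x$values)))
  out <- matrix(out, nrow = nrow(x$values),
                dimnames = list(rownames(x$values), stages_present))
  out
}

#' Read a stage-wise FPKM expression matrix from TSV
#'
#' Expects a tab-separated file: first column gene ids, header row of sample
#' names, numeric FPKM values in the body. Validation is strict: duplicate
#' gene ids, samples without a stage assignment, and negative or non-numeric
#' values are hard errors naming the offender.
#'
#' @param path Path to the TSV file.
#' @param stage_map Named character vector mapping each sample name to a
#'   stage label.
#' @param meta Optional per-sample metadata data.frame (see [stage_matrix()]).
#' @return A [stage_matrix()].
#' @export
read_expression_matrix <- function(path, stage_map, meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus >= 1 sample",
                         call. = FALSE)
  genes <- df[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  body <- df[, -1, drop = FALSE]
  vals <- suppressWarnings(
    vapply(body, function(col) as.numeric(col), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(genes, colnames(body)))
  bad <- which(is.na(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("invalid FPKM value '%s' at gene '%s', sample '%s'",
                 body[i, j], genes[i], colnames(body)[j]), call. = FALSE)
  }
  stage_matrix(vals, stage_map, meta = meta)
}

#' Write an expression matrix to TSV
#' @param x A [stage_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "stage_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- 3'-UTR sequences -------------------------------------------------------

#' Read 3'-UTR sequences from FASTA, or extract them from a genome + BED
#'
#' Two modes. (1) `fasta_path` alone: a FASTA of per-gene UTR sequences keyed
#' by gene id. (2) `fasta_path` + `bed_path`: `fasta_path` is a genome FASTA
#' and `bed_path` a BED6 file of UTR intervals (0-based half-open); sequences
#' are extracted, minus-strand intervals reverse-complemented, so every
#' returned sequence reads 5'->3' of the transcript.
#'
#' In both modes sequences are upper-cased and RNA alphabet normalized to DNA
#' (U -> T); characters outside \{A, C, G, T, N\} are an error. When a gene
#' has several annotated UTRs, the longest is kept and the choice recorded in
#' the `multi_utr` attribute.
#'
#' @param fasta_path FASTA of UTRs, or a genome FASTA when `bed_path` given.
#' @param bed_path Optional BED6 file (chrom, start, end, name, score, strand).
#' @return Named character vector of UTR sequences (names are gene ids), with
#'   attribute `multi_utr` listing genes for which the longest of several
#'   annotated UTRs was kept.
#' @export
read_utr_sequences <- function(fasta_path, bed_path = NULL) {
  if (!file.exists(fasta_path)) stop("file not found: ", fasta_path,
                                     call. = FALSE)
  fa <- Biostrings::readBStringSet(fasta_path)
  raw <- toupper(as.character(fa))
  names(raw) <- sub("\\s.*$", "", names(fa))
  raw <- chartr("U", "T", raw)
  check_dna_alphabet(raw)

  if (is.null(bed_path)) {
    return(keep_longest_utr(raw))
  }

  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand")[1:6])
  if (any(bed$start >= bed$end))
    stop("BED interval with start >= end at line ",
         which(bed$start >= bed$end)[1], call. = FALSE)
  if (!all(bed$strand %in% c("+", "-")))
    stop("BED strand must be '+' or '-'", call. = FALSE)
  missing_chrom <- setdiff(unique(bed$chrom), names(raw))
  if (length(missing_chrom))
    stop("chromosome(s) absent from genome FASTA: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  seqs <- character(nrow(bed))
  for (i in seq_len(nrow(bed))) {
    chrom_seq <- raw[[bed$chrom[i]]]
    if (bed$end[i] > nchar(chrom_seq))
      stop(sprintf("BED interval %s:%d-%d outside chromosome bounds (%d nt)",
                   bed$chrom[i], bed$start[i], bed$end[i], nchar(chrom_seq)),
           call. = FALSE)
    s <- substr(chrom_seq, bed$start[i] + 1L, bed$end[i])
    if (bed$strand[i] == "-") s <- reverse_complement(s)
    seqs[i] <- s
  }
  names(seqs) <- bed$name
  keep_longest_utr(seqs)
}

check_dna_alphabet <- function(seqs) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence '", names(seqs)[bad][1],
         "' contains characters outside the A/C/G/T/N alphabet",
         call. = FALSE)
  invisible(seqs)
}

reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

keep_longest_utr <- function(seqs) {
  if (!anyDuplicated(names(seqs))) {
    attr(seqs, "multi_utr") <- character(0)
    return(seqs)
  }
  ord <- order(names(seqs), -nchar(seqs))
  seqs <- seqs[ord]
  dup_genes <- unique(names(seqs)[duplicated(names(seqs))])
  out <- seqs[!duplicated(names(seqs))]
  attr(out, "multi_utr") <- dup_genes
  out
}

# ---- qPCR Ct tables ---------------------------------------------------------

#' Construct a qPCR Ct table
#'
#' @param ct Numeric matrix of cycle-threshold values, genes x samples
#'   (typical range 10-40). All values must be finite.
#' @param reference_gene Identifier of the endogenous reference gene
#'   (e.g. GAPDH); must have a Ct in every sample.
#' @param groups Optional named character vector mapping samples to
#'   biological groups.
#' @return An object of class `qpcr_table`.
#' @export
qpcr_table <- function(ct, reference_gene, groups = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix", call. = FALSE)
  if (!reference_gene %in% rownames(ct))
    stop("reference gene '", reference_gene, "' absent from Ct table",
         call. = FALSE)
  ref_na <- colnames(ct)[!is.finite(ct[reference_gene, ])]
  if (length(ref_na))
    stop("reference gene '", reference_gene, "' has no Ct in sample(s): ",
         paste(ref_na, collapse = ", "), call. = FALSE)
  if (any(!is.finite(ct)))
    stop("Ct table contains non-finite values; use `undetermined = \"ceiling\"` ",
         "in read_ct_table() to impute", call. = FALSE)
  if (!is.null(groups)) {
    missing_grp <- setdiff(colnames(ct), names(groups))
    if (length(missing_grp))
      stop("sample(s) without a group: ", paste(missing_grp, collapse = ", "),
           call. = FALSE)
    groups <- groups[colnames(ct)]
  }
  structure(list(ct = ct, reference_gene = reference_gene, groups = groups),
            class = "qpcr_table")
}

#' Read a qPCR Ct table from TSV
#'
#' First column gene ids, header row of sample names, Ct values in the body.
#' The literal value `Undetermined` (no amplification) is an error by
#' default, or imputed at a ceiling Ct when `undetermined = "ceiling"`.
#'
#' @param path Path to the TSV file.
#' @param reference_gene Reference gene id (must be present in every sample).
#' @param groups Optional named character vector, sample -> biological group.
#' @param undetermined `"error"` (default) or `"ceiling"`.
#' @param ceiling_ct Ct used to impute `Undetermined` wells (default 40).
#' @return A [qpcr_table()].
#' @export
read_ct_table <- function(path, reference_gene, groups = NULL,
                          undetermined = c("error", "ceiling"),
                          ceiling_ct = 40) {
  undetermined <- match.arg(undetermined)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  genes <- df[[1]]
  body <- df[, -1, drop = FALSE]
  is_und <- vapply(body, function(col) tolower(col) == "undetermined",
                   logical(nrow(df)))
  vals <- suppressWarnings(
    vapply(body, function(col) as.numeric(col), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df), dimnames = list(genes, colnames(body)))
  is_und <- matrix(is_und, nrow = nrow(df))
  if (any(is_und)) {
    if (undetermined == "error") {
      idx <- which(is_und, arr.ind = TRUE)[1, ]
      stop(sprintf("Undetermined Ct at gene '%s', sample '%s'",
                   genes[idx[1]], colnames(body)[idx[2]]), call. = FALSE)
    }
    vals[is_und] <- ceiling_ct
  }
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("invalid Ct value '%s' at gene '%s', sample '%s'",
                 body[i, j], genes[i], colnames(body)[j]), call. = FALSE)
  }
  qpcr_table(vals, reference_gene, groups = groups)
}

# ---- result writers/readers -------------------------------------------------

#' Write an analysis result to disk
#'
#' Round-trip stable: reading a written object back with the matching reader
#' reproduces it exactly.
#'
#' @param x A `decay_classification` data.frame or a `defect_call`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_results <- function(x, path, format = c("tsv", "json")) {
  UseMethod("write_results")
}

#' @export
write_results.decay_classification <- function(x, path,
                                               format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  df$cluster <- as.character(df$cluster)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' @export
write_results.defect_call <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv")
    stop("defect calls carry nested evidence; use format = \"json\"",
         call. = FALSE)
  obj <- list(id = x$id, call = x$call,
              evidence = x$evidence,
              parameters = x$parameters)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read back a written decay classification
#' @param path Path written by [write_results()].
#' @param format `"tsv"` or `"json"`.
#' @return A `decay_classification` data.frame.
#' @export
read_classification <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
  } else {
    df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  df$cluster <- factor(df$cluster, levels = cluster_levels())
  class(df) <- c("decay_classification", "data.frame")
  df
}

#' Read back a written defect call
#' @param path JSON path written by [write_results()].
#' @return A `defect_call`.
#' @export
read_defect_call <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(id = obj$id, call = obj$call,
                 evidence = as.data.frame(obj$evidence),
                 parameters = obj$parameters),
            class = "defect_call")
}
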