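# Independent oracles, kept deliberately naive so they never share code
# paths with the implementation they check.

# Exhaustive position-by-position motif scan.
brute_count_motifs <- function(s, motifs) {
  s <- chartr("U", "T", toupper(s))
  total <- 0L
  for (m in motifs) {
    w <- nchar(m)
    if (nchar(s) < w) next
    starts <- seq_len(nchar(s) - w + 1L)
    total <- total + sum(substring(s, starts, starts + w - 1L) == m)
  }
  total
}

# Upper-tail hypergeometric probability by enumerating every possible draw
# of |B| elements from the universe (set A fixed as the first `a` elements).
enum_hyper_tail <- function(u, a, b, k) {
  if (b == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(u, b)
  overlaps <- colSums(draws <= a)
  mean(overlaps >= k)
}

# Pooled-variance two-sample t statistic and two-sided p, from the closed
# form.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# One-way ANOVA F from manual between/within sums of squares.
anova_f_oracle <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ss_within <- sum(tapply(values, groups, function(v) {
    sum((v - mean(v))^2)
  }))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# Tiny TSV fixture writers.
write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_fasta_fixture <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

# A minimal validated stage matrix from an FPKM triple per gene.
triple_matrix <- function(fpkm, stages = c("GV", "zygote", "8-cell")) {
  vals <- matrix(fpkm, ncol = length(stages), byrow = TRUE,
                 dimnames = list(paste0("g", seq_len(length(fpkm) / length(stages))),
                                 paste0(stages, "_s")))
  stage_matrix(vals, setNames(stages, colnames(vals)))
}
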