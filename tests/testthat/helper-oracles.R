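# Independent brute-force oracles and small fixture builders.

# O(n^2) all-pairs convergence: a clone is convergent if any other clone
# shares its (v_gene, cdr3_aa); statistic = summed frequency of such clones.
brute_convergence <- function(repertoire) {
  cl <- repertoire$clones[repertoire$clones$productive, , drop = FALSE]
  n <- nrow(cl)
  idx <- seq_len(n)
  flagged <- vapply(idx, function(i) {
    any(cl$v_gene == cl$v_gene[i] & cl$cdr3_aa == cl$cdr3_aa[i] & idx != i)
  }, logical(1))
  sum(cl$frequency[flagged])
}

# Mann-Whitney pair-count AUC with half credit for ties
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive-threshold Youden point (ties -> higher specificity)
youden_brute <- function(scores, labels) {
  best <- NULL
  for (t in sort(unique(scores), decreasing = TRUE)) {
    pos <- scores >= t
    sens <- sum(pos & labels == 1) / sum(labels == 1)
    spec <- 1 - sum(pos & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(t = t, j = j, sens = sens, spec = spec)
    }
  }
  best
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

# n distinct CDR3 amino-acid junctions
unique_aa <- function(n) {
  stopifnot(n <= 400)
  i <- seq_len(n) - 1L
  paste0("C", AA20[i %/% 20 + 1L], AA20[i %% 20 + 1L], "SF")
}

# small random repertoire with deliberate (v_gene, cdr3_aa) collisions
random_repertoire <- function(n_clones, seed) {
  set.seed(seed)
  aa_pool <- replicate(max(3L, n_clones %/% 4L), paste0(
    "C", paste(sample(c("A", "S", "G", "L", "Q", "Y", "E"), 6, TRUE),
               collapse = ""), "F"))
  aa <- sample(aa_pool, n_clones, replace = TRUE)
  v <- sample(c("TRBV5-1", "TRBV12-3", "TRBV19", "TRBV28"), n_clones, TRUE)
  nt <- back_translate_test(aa)
  clones <- data.frame(cdr3_nt = nt, cdr3_aa = aa, v_call = v,
                       read_count = sample(1:500, n_clones, TRUE),
                       productive = TRUE, stringsAsFactors = FALSE)
  tcr_repertoire(clones, sample_id = paste0("r", seed))
}

# independent back-translation used only to build fixtures
back_translate_test <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  vapply(strsplit(aa, ""), function(ch) {
    paste(vapply(ch, function(a) sample(by_aa[[a]], 1), character(1)),
          collapse = "")
  }, character(1))
}

# write a clonotype table from raw rows (bypassing the package writer)
write_raw_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
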