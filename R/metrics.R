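#' Shannon diversity of a clone frequency vector
#'
#' \eqn{-\sum_i p_i \log_2 p_i}, in bits. The input must already be a
#' normalised frequency vector; no silent rescaling is performed.
#'
#' @param frequencies Numeric vector of clone frequencies, all > 0, summing
#'   to 1 within 1e-6.
#' @return Shannon diversity in bits (0 for a monoclonal repertoire).
#' @examples
#' shannon_diversity(c(0.5, 0.5))  # 1 bit
#' @export
shannon_diversity <- function(frequencies) {
  .check_freqs(frequencies)
  -sum(frequencies * log2(frequencies))
}

#' Evenness (normalised Shannon entropy)
#'
#' Shannon diversity divided by \eqn{\log_2 N}, where \eqn{N} is the number
#' of detected clones.
#'
#' @inheritParams shannon_diversity
#' @return Evenness in [0, 1].
#' @export
evenness <- function(frequencies) {
  .check_freqs(frequencies)
  if (length(frequencies) < 2L) {
    stop("evenness is undefined for a single-clone repertoire")
  }
  shannon_diversity(frequencies) / log2(length(frequencies))
}

#' Clonality of a clone frequency vector
#'
#' Clonality is 1 minus the normalised Shannon entropy (evenness): 0 for a
#' perfectly even repertoire, approaching 1 as the repertoire becomes
#' monoclonal.
#'
#' @inheritParams shannon_diversity
#' @return Clonality in [0, 1].
#' @export
clonality <- function(frequencies) {
  1 - evenness(frequencies)
}

.check_freqs <- function(frequencies) {
  if (!is.numeric(frequencies) || !length(frequencies)) {
    stop("'frequencies' must be a non-empty numeric vector")
  }
  if (any(frequencies <= 0)) stop("all frequencies must be > 0")
  if (abs(sum(frequencies) - 1) > 1e-6) {
    stop("frequencies do not sum to 1 (no silent rescaling is applied)")
  }
  invisible(frequencies)
}

#' TCR convergence of a repertoire
#'
#' TCR convergence is the aggregate frequency of clones — unique TCRB
#' nucleotide rearrangements — sharing an allele-stripped V gene and CDR3
#' amino-acid sequence with at least one other clone. Clones are grouped by
#' the key \code{(v_gene, cdr3_aa)}; groups with >= 2 nucleotide-distinct
#' members are convergent, and the statistic sums the frequencies of all
#' their members.
#'
#' @param repertoire A \code{\link{tcr_repertoire}}.
#' @param productive_only Restrict grouping to productive clones (default).
#' @return A list of class \code{tcr_convergence}: \code{statistic} (the
#'   aggregate frequency, in [0, 1]) and \code{groups}, a data.frame with one
#'   row per convergent group (\code{v_gene}, \code{cdr3_aa}, \code{size},
#'   \code{aggregate_frequency}, and a list column \code{members} of member
#'   nucleotide sequences).
#' @export
convergence <- function(repertoire, productive_only = TRUE) {
  stopifnot(inherits(repertoire, "tcr_repertoire"))
  cl <- repertoire$clones
  use <- if (productive_only) cl$productive else rep(TRUE, nrow(cl))
  cl <- cl[use, , drop = FALSE]
  key <- paste(cl$v_gene, cl$cdr3_aa, sep = "\r")
  sizes <- table(key)
  conv_keys <- names(sizes)[sizes >= 2L]
  in_group <- key %in% conv_keys
  stat <- sum(cl$frequency[in_group])
  if (length(conv_keys)) {
    idx <- split(which(in_group), key[in_group])
    groups <- data.frame(
      v_gene = vapply(idx, function(i) cl$v_gene[i[1]], character(1)),
      cdr3_aa = vapply(idx, function(i) cl$cdr3_aa[i[1]], character(1)),
      size = lengths(idx),
      aggregate_frequency = vapply(idx, function(i) sum(cl$frequency[i]),
                                   numeric(1)),
      stringsAsFactors = FALSE)
    groups$members <- lapply(idx, function(i) cl$cdr3_nt[i])
    groups <- groups[order(-groups$aggregate_frequency), , drop = FALSE]
    rownames(groups) <- NULL
  } else {
    groups <- data.frame(v_gene = character(), cdr3_aa = character(),
                         size = integer(), aggregate_frequency = numeric(),
                         stringsAsFactors = FALSE)
    groups$members <- list()
  }
  structure(list(statistic = stat, groups = groups),
            class = "tcr_convergence")
}

#' @export
print.tcr_convergence <- function(x, ...) {
  cat("TCR convergence: ", signif(x$statistic, 4), " (",
      nrow(x$groups), " convergent group",
      if (nrow(x$groups) != 1) "s", ")\n", sep = "")
  invisible(x)
}

#' Jaccard overlap between two repertoires
#'
#' Clonal overlap as the Jaccard index |A intersect B| / |A union B| over
#' clone identity keys. The default key is the nucleotide-level clone
#' identity \code{(cdr3_nt, v_gene)}; an amino-acid-level mode
#' (\code{(cdr3_aa, v_gene)}) is available for cross-platform comparisons
#' where nucleotide sequences are not comparable.
#'
#' @param rep_a,rep_b \code{\link{tcr_repertoire}} objects.
#' @param level \code{"nt"} (default) or \code{"aa"}.
#' @return Jaccard index in [0, 1]; symmetric in its arguments.
#' @export
jaccard_overlap <- function(rep_a, rep_b, level = c("nt", "aa")) {
  stopifnot(inherits(rep_a, "tcr_repertoire"),
            inherits(rep_b, "tcr_repertoire"))
  level <- match.arg(level)
  keyfun <- function(r) {
    s <- if (level == "nt") r$clones$cdr3_nt else r$clones$cdr3_aa
    unique(paste(s, r$clones$v_gene, sep = "\r"))
  }
  a <- keyfun(rep_a); b <- keyfun(rep_b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Summarise a repertoire's features
#'
#' Computes the repertoire features used throughout the package: number of
#' clones, Shannon diversity (bits), evenness, clonality (= 1 - evenness),
#' TCR convergence, and the number of convergent groups.
#'
#' @param repertoire A \code{\link{tcr_repertoire}}.
#' @param productive_only Passed to \code{\link{convergence}}.
#' @return A one-row data.frame of class \code{repertoire_summary} with
#'   columns \code{sample_id}, \code{n_clones}, \code{total_reads},
#'   \code{shannon_bits}, \code{evenness}, \code{clonality},
#'   \code{convergence}, \code{n_convergent_groups}.
#' @export
repertoire_summary <- function(repertoire, productive_only = TRUE) {
  stopifnot(inherits(repertoire, "tcr_repertoire"))
  f <- repertoire$clones$frequency
  conv <- convergence(repertoire, productive_only = productive_only)
  h <- shannon_diversity(f)
  ev <- if (length(f) >= 2L) evenness(f) else NA_real_
  out <- data.frame(
    sample_id = repertoire$sample_id,
    n_clones = nrow(repertoire$clones),
    total_reads = repertoire$total_reads,
    shannon_bits = h,
    evenness = ev,
    clonality = 1 - ev,
    convergence = conv$statistic,
    n_convergent_groups = nrow(conv$groups),
    stringsAsFactors = FALSE)
  class(out) <- c("repertoire_summary", "data.frame")
  out
}

#' @exportS3Method base::summary
summary.tcr_repertoire <- function(object, ...) {
  repertoire_summary(object, ...)
}
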