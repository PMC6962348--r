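#' Probability that a random CDR3 substitution is synonymous
#'
#' Full enumeration over the standard codon table: each of the 61 sense
#' codons admits 9 single-base substitutions (549 in total); the returned
#' value is the fraction whose product codon encodes the same amino acid.
#' Substitutions producing a stop codon count as non-synonymous. The result
#' is close to 1/4, which is why roughly a quarter of substitution
#' sequencing errors masquerade as convergent nucleotide variants.
#'
#' Two weightings of the enumeration are available. \code{"codon"} weights
#' all 61 sense codons equally — the conventional back-of-the-codon-table
#' estimate of ~1/4. \code{"amino_acid"} weights the 20 amino acids equally
#' and the codons uniformly within each amino acid, which is exactly the
#' codon distribution produced by this package's uniform back-translation,
#' so it is the matching value when fitting the error model to repertoires
#' simulated here (degenerate 6-codon amino acids are down-weighted,
#' giving ~0.19).
#'
#' @param weighting \code{"codon"} (default) or \code{"amino_acid"}.
#' @return A single fraction (approximately 0.25 or 0.19).
#' @export
synonymous_substitution_prob <- function(weighting = c("codon",
                                                       "amino_acid")) {
  weighting <- match.arg(weighting)
  tab <- .codons()
  bases <- c("A", "C", "G", "T")
  syn_frac <- vapply(tab$sense_codons, function(codon) {
    aa <- tab$codon_to_aa[[codon]]
    s <- strsplit(codon, "")[[1]]
    n_syn <- 0L
    for (pos in 1:3) {
      for (b in setdiff(bases, s[pos])) {
        mut <- s; mut[pos] <- b
        if (tab$codon_to_aa[[paste(mut, collapse = "")]] == aa) {
          n_syn <- n_syn + 1L
        }
      }
    }
    n_syn / 9
  }, numeric(1))
  if (weighting == "codon") {
    mean(syn_frac)
  } else {
    mean(vapply(tab$aa_to_codons,
                function(cs) mean(syn_frac[cs]), numeric(1)))
  }
}

#' Error-model configuration
#'
#' Parameters of the substitution-error artifact model: the per-base
#' substitution error rate, the probability that a random CDR3 substitution
#' is synonymous (default 1/4, see
#' \code{\link{synonymous_substitution_prob}}), and the minimum number of
#' reads an artifact must attain to be reported as a clone.
#'
#' @param error_rate Substitutions per sequenced base, in (0, 1) (0 allowed
#'   for the no-error limit).
#' @param synonymous_prob Fraction of substitutions that are synonymous.
#' @param artifact_read_threshold Minimum artifact reads (>= 1).
#' @return An object of class \code{error_model_config}.
#' @export
error_model_config <- function(error_rate,
                               synonymous_prob = 0.25,
                               artifact_read_threshold = 1L) {
  stopifnot(is.numeric(error_rate), length(error_rate) == 1L,
            error_rate >= 0, error_rate < 1,
            synonymous_prob > 0, synonymous_prob < 1,
            artifact_read_threshold >= 1)
  structure(list(error_rate = error_rate,
                 synonymous_prob = synonymous_prob,
                 artifact_read_threshold = as.integer(artifact_read_threshold)),
            class = "error_model_config")
}

#' Probability a clone spawns a reported synonymous artifact
#'
#' The model considers four factors: the clone's effective CDR3 length (amino
#' acids after anchor elimination, hence \eqn{3 \times} that many nucleotide
#' positions), its read count, the per-base substitution error rate, and the
#' probability that a substitution is synonymous. With per-base
#' synonymous-error probability \eqn{q = error\_rate \times synonymous\_prob}
#' and \eqn{B = reads \times 3 \times effective\ length} sequenced CDR3
#' bases, the probability that at least one synonymous errored base call
#' occurs — creating a nucleotide-distinct, amino-acid-identical artifact —
#' is \eqn{1 - (1 - q)^B}. For an artifact read threshold \eqn{t > 1} the
#' binomial tail \eqn{P(X \ge t)}, \eqn{X \sim Bin(B, q)}, is used. The
#' result is monotone increasing in reads, length, and error rate.
#'
#' @param read_count Reads per clone (vectorised).
#' @param effective_length Effective CDR3 length in amino acids (vectorised).
#' @param config An \code{\link{error_model_config}}.
#' @return Per-clone artifact probability in [0, 1].
#' @export
clone_artifact_probability <- function(read_count, effective_length, config) {
  stopifnot(inherits(config, "error_model_config"),
            all(read_count >= 1), all(effective_length >= 1))
  q <- config$error_rate * config$synonymous_prob
  B <- read_count * 3 * effective_length
  if (q == 0) return(rep(0, length(B)))
  t <- config$artifact_read_threshold
  if (t == 1L) {
    -expm1(B * log1p(-q))
  } else {
    stats::pbinom(t - 1, size = round(B), prob = q, lower.tail = FALSE)
  }
}

#' Predicted artifact-driven convergence of a repertoire
#'
#' Expected convergence attributable to substitution sequencing errors:
#' the frequency-weighted sum of per-clone artifact probabilities,
#' \eqn{\sum_i f_i P_i} over all productive clones. Artifact clones' own
#' (O(error rate)) frequencies are not added by default. When a repertoire
#' carries genuine convergent groups whose frequency should not be
#' attributed to error, \code{exclude_grouped = TRUE} restricts the sum to
#' clones outside observed convergent groups; for fitting the error rate
#' against observed convergence the full sum is the right quantity, since
#' in an error-dominated dataset the observed groups are themselves the
#' artifact signal.
#'
#' @param repertoire A \code{\link{tcr_repertoire}}.
#' @param config An \code{\link{error_model_config}}.
#' @param exclude_grouped Exclude clones already in an observed convergent
#'   group (default FALSE).
#' @param include_artifact_frequency Additionally count the expected
#'   frequency mass of the artifact reads themselves (default FALSE).
#' @return Predicted convergence in [0, 1].
#' @export
predicted_convergence <- function(repertoire, config,
                                  exclude_grouped = FALSE,
                                  include_artifact_frequency = FALSE) {
  stopifnot(inherits(repertoire, "tcr_repertoire"),
            inherits(config, "error_model_config"))
  cl <- repertoire$clones
  use <- cl$productive & nchar(cl$cdr3_aa) >= 3L
  if (exclude_grouped) {
    key <- paste(cl$v_gene, cl$cdr3_aa, sep = "\r")
    sizes <- table(key)
    use <- use & !(key %in% names(sizes)[sizes >= 2L])
  }
  cl <- cl[use, , drop = FALSE]
  if (!nrow(cl)) return(0)
  len <- effective_cdr3_length(cl$cdr3_aa)
  p <- clone_artifact_probability(pmax(cl$read_count, 1), len, config)
  out <- sum(cl$frequency * p)
  if (include_artifact_frequency) {
    q <- config$error_rate * config$synonymous_prob
    p_read <- -expm1(3 * len * log1p(-q))
    out <- out + sum(cl$frequency * p_read)
  }
  min(out, 1)
}

#' Fit the substitution error rate by Spearman grid search
#'
#' For each candidate error rate, computes the model-predicted convergence of
#' every sample and the Spearman correlation between predicted and observed
#' convergence across the cohort; the fitted rate maximises that correlation
#' (ties broken toward the smaller rate). Grid points where the correlation
#' is undefined (constant predicted or observed vector) are recorded as
#' \code{NA} and skipped.
#'
#' @param repertoires List of \code{\link{tcr_repertoire}} objects (>= 5).
#' @param observed Numeric vector of observed convergence values, one per
#'   repertoire.
#' @param grid Sorted vector of candidate error rates; the default is
#'   log-spaced at 13 points per decade over [1e-5, 1e-2], the plausible
#'   range of residual per-base substitution error rates.
#' @param synonymous_prob Passed to \code{\link{error_model_config}}.
#' @param ... Passed to \code{\link{predicted_convergence}}.
#' @return An object of class \code{error_rate_fit}: list with \code{grid},
#'   \code{correlation_per_rate}, \code{best_rate}, \code{best_correlation},
#'   \code{predicted} (matrix, samples x grid), \code{observed}.
#' @export
fit_error_rate <- function(repertoires, observed,
                           grid = error_rate_grid(),
                           synonymous_prob = 0.25, ...) {
  stopifnot(length(repertoires) == length(observed),
            length(repertoires) >= 5L, length(grid) >= 1L,
            !is.unsorted(grid))
  pred <- vapply(grid, function(e) {
    cfg <- error_model_config(e, synonymous_prob = synonymous_prob)
    vapply(repertoires, predicted_convergence, numeric(1), config = cfg, ...)
  }, numeric(length(repertoires)))
  pred <- matrix(pred, nrow = length(repertoires))
  cors <- apply(pred, 2, function(p) {
    if (stats::sd(p) == 0 || stats::sd(observed) == 0) return(NA_real_)
    stats::cor(p, observed, method = "spearman")
  })
  if (all(is.na(cors))) {
    stop("Spearman correlation undefined at every grid point ",
         "(constant predicted or observed convergence)")
  }
  best <- which.max(cors)  # first maximum = smallest rate on a sorted grid
  structure(list(grid = grid, correlation_per_rate = cors,
                 best_rate = grid[best], best_correlation = cors[best],
                 predicted = pred, observed = observed),
            class = "error_rate_fit")
}

#' Default error-rate grid
#'
#' Log-spaced candidate substitution error rates, 13 points per decade over
#' \code{[grid_min, grid_max]}.
#'
#' @param grid_min,grid_max Grid endpoints (errors per base).
#' @param points_per_decade Grid density.
#' @return Sorted numeric vector of rates.
#' @export
error_rate_grid <- function(grid_min = 1e-5, grid_max = 1e-2,
                            points_per_decade = 13) {
  step <- 1 / (points_per_decade - 1)
  10^seq(log10(grid_min), log10(grid_max), by = step)
}

#' @exportS3Method base::print
print.error_rate_fit <- function(x, ...) {
  cat("Substitution error-rate fit (Spearman grid search)\n")
  cat("  grid: ", length(x$grid), " rates in [",
      format(min(x$grid)), ", ", format(max(x$grid)), "]\n", sep = "")
  cat("  best rate:        ", format(x$best_rate, digits = 3), " per base\n",
      sep = "")
  cat("  best correlation: ", round(x$best_correlation, 3), "\n", sep = "")
  if (any(is.na(x$correlation_per_rate))) {
    cat("  undefined at ", sum(is.na(x$correlation_per_rate)),
        " grid point(s)\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.error_rate_fit <- function(x, ...) {
  plot(x$grid, x$correlation_per_rate, log = "x", type = "b", pch = 16,
       xlab = "substitution error rate (per base)",
       ylab = "Spearman correlation (predicted vs observed convergence)",
       ...)
  graphics::abline(v = x$best_rate, lty = 2)
  invisible(x)
}
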