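#' Simulation configuration
#'
#' Parameters of the synthetic TCRB repertoire generator. Defaults emulate
#' the peripheral-blood repertoires the package's statistics are designed
#' for: tens of thousands of clones, 1-2 M reads, clonality in the
#' 0.05-0.38 range, and convergence frequencies of order 0.002-0.09.
#'
#' @param n_clones Number of unique clones (rearrangements).
#' @param depth Total sequencing reads, apportioned over clones.
#' @param clonality_target Desired repertoire clonality in [0, 1); the
#'   frequency-skew exponent is calibrated by bisection to hit it within
#'   0.01.
#' @param n_true_groups Number of planted convergent groups (ignored when
#'   \code{convergence_target} is given).
#' @param convergence_target Optional aggregate planted-group frequency;
#'   groups are planted until it is (approximately) reached.
#' @param group_size_distribution Named probabilities over group sizes
#'   \code{2:4}.
#' @param cdr3_aa_length_distribution Named probabilities over CDR3
#'   amino-acid lengths 8-20 (junction including both anchors); the default
#'   is a discretised normal centred on 14-15 residues.
#' @param v_gene_pool Character vector of V-gene names; usage weights are
#'   Zipf-like (\code{weight[i] = 1/i}).
#' @param error_rate Per-base substitution error probability applied by
#'   read-level error injection (0 disables it).
#' @param seed Integer seed; the simulation is a pure function of
#'   (config, seed).
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_clones = 30000L,
                              depth = 1500000L,
                              clonality_target = 0.2,
                              n_true_groups = 50L,
                              convergence_target = NULL,
                              group_size_distribution =
                                c(`2` = 0.7, `3` = 0.2, `4` = 0.1),
                              cdr3_aa_length_distribution = NULL,
                              v_gene_pool = sprintf("TRBV%d", 1:40),
                              error_rate = 0,
                              seed = 1L) {
  if (is.null(cdr3_aa_length_distribution)) {
    lens <- 8:20
    w <- exp(-((lens - 14.5)^2) / (2 * 2.2^2))
    cdr3_aa_length_distribution <- stats::setNames(w / sum(w), lens)
  }
  cfg <- structure(list(
    n_clones = as.integer(n_clones), depth = as.integer(depth),
    clonality_target = clonality_target,
    n_true_groups = as.integer(n_true_groups),
    convergence_target = convergence_target,
    group_size_distribution = group_size_distribution,
    cdr3_aa_length_distribution = cdr3_aa_length_distribution,
    v_gene_pool = v_gene_pool,
    error_rate = error_rate, seed = as.integer(seed)),
    class = "simulation_config")
  max_size <- max(as.integer(names(cfg$group_size_distribution)))
  if (is.null(convergence_target) &&
      cfg$n_true_groups * max_size > cfg$n_clones) {
    stop("n_true_groups x max group size exceeds n_clones")
  }
  if (cfg$depth < cfg$n_clones) stop("depth must be >= n_clones")
  stopifnot(clonality_target >= 0, clonality_target < 1,
            error_rate >= 0, error_rate < 1)
  cfg
}

# rank-frequency power law p_i ~ i^(-s); returns normalised frequencies
.power_law_freqs <- function(n, s) {
  w <- seq_len(n)^(-s)
  w / sum(w)
}

# deterministic apportionment of `depth` reads over frequencies, >= 1 each
.apportion_reads <- function(freqs, depth) {
  n <- length(freqs)
  counts <- floor(freqs * depth)
  rem <- depth - sum(counts)
  if (rem > 0) {
    frac <- freqs * depth - counts
    counts[order(-frac)[seq_len(rem)]] <- counts[order(-frac)[seq_len(rem)]] + 1
  }
  short <- counts == 0
  if (any(short)) {
    counts[short] <- 1
    excess <- sum(counts) - depth
    counts[1] <- counts[1] - excess  # rank-1 clone absorbs the correction
    if (counts[1] < 1) stop("depth too small to give every clone a read")
  }
  counts
}

# calibrate the skew exponent so realised (apportioned) clonality hits the
# target within 0.01
.calibrate_skew <- function(n, depth, target, tol = 0.005, s_max = 6) {
  realised <- function(s) {
    counts <- .apportion_reads(.power_law_freqs(n, s), depth)
    clonality(counts / depth)
  }
  lo <- 0; hi <- s_max
  if (realised(hi) < target) stop("unattainable clonality target ", target)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    c_mid <- realised(mid)
    if (abs(c_mid - target) < tol) return(mid)
    if (c_mid < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# random CDR3 amino-acid junctions: C ... F with random interior
.random_cdr3_aa <- function(n, lengths) {
  interior <- lengths - 2L
  letters_needed <- sum(interior)
  draw <- sample(.AA_LETTERS, letters_needed, replace = TRUE)
  idx <- rep.int(seq_len(n), interior)
  mids <- vapply(split(draw, idx), paste, character(1), collapse = "")
  paste0("C", mids, "F")
}

# back-translate amino-acid strings by uniform random codon choice
.back_translate <- function(aa_strings) {
  tab <- .codons()
  chars <- strsplit(aa_strings, "")
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  codons <- character(length(flat))
  for (a in unique(flat)) {
    pos <- which(flat == a)
    pool <- tab$aa_to_codons[[a]]
    codons[pos] <- pool[sample.int(length(pool), length(pos), replace = TRUE)]
  }
  idx <- rep.int(seq_along(aa_strings), lens)
  vapply(split(codons, idx), paste, character(1), collapse = "")
}

#' Simulate a TCRB repertoire with planted ground truth
#'
#' Generates a clone frequency vector from a rank-frequency power law whose
#' exponent is calibrated by bisection until the realised clonality is
#' within 0.01 of \code{clonality_target}; draws V genes (Zipf-weighted) and
#' CDR3 amino-acid junctions; back-translates each junction to a nucleotide
#' sequence by random codon choice; plants convergent groups by rewriting
#' selected clones into synonymous nucleotide variants (identical V gene and
#' amino-acid sequence, pairwise-distinct nucleotides); and, if
#' \code{error_rate > 0}, applies read-level substitution-error injection.
#' Deterministic given the config seed.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list: \code{repertoire} (a \code{\link{tcr_repertoire}}) and
#'   \code{truth} (class \code{synthetic_truth}) with fields
#'   \code{planted_groups} (data.frame: \code{v_gene}, \code{cdr3_aa},
#'   \code{size}, \code{aggregate_frequency}, list column \code{members}),
#'   \code{true_convergence}, \code{artifact_clones},
#'   \code{realized_convergence_with_errors}, \code{dropped_reads}.
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_clones
  s <- .calibrate_skew(n, config$depth, config$clonality_target)
  counts <- .apportion_reads(.power_law_freqs(n, s), config$depth)
  freqs <- counts / config$depth

  vw <- 1 / seq_along(config$v_gene_pool)
  v_gene <- sample(config$v_gene_pool, n, replace = TRUE, prob = vw)
  lens <- as.integer(sample(names(config$cdr3_aa_length_distribution), n,
                            replace = TRUE,
                            prob = config$cdr3_aa_length_distribution))
  aa <- .random_cdr3_aa(n, lens)
  # enforce unique (v_gene, cdr3_aa) among background clones
  repeat {
    dup <- duplicated(paste(v_gene, aa, sep = "\r"))
    if (!any(dup)) break
    aa[dup] <- .random_cdr3_aa(sum(dup), nchar(aa[dup]))
  }

  planted <- .plant_groups(config, freqs, v_gene, aa)
  v_gene <- planted$v_gene; aa <- planted$aa

  nt <- .back_translate(aa)
  # planted group members must be nucleotide-distinct within their group
  for (g in planted$groups) {
    repeat {
      dup <- duplicated(nt[g])
      if (!any(dup)) break
      nt[g[dup]] <- .back_translate(aa[g[dup]])
    }
  }

  clones <- data.frame(cdr3_nt = nt, cdr3_aa = aa,
                       v_call = paste0(v_gene, "*01"),
                       read_count = counts, productive = TRUE,
                       stringsAsFactors = FALSE)
  rep_out <- tcr_repertoire(clones, sample_id = paste0("sim", config$seed),
                            dialect = "synthetic")
  pg <- if (length(planted$groups)) {
    data.frame(
      v_gene = vapply(planted$groups, function(g) v_gene[g[1]], character(1)),
      cdr3_aa = vapply(planted$groups, function(g) aa[g[1]], character(1)),
      size = lengths(planted$groups),
      aggregate_frequency = vapply(planted$groups,
                                   function(g) sum(freqs[g]), numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(v_gene = character(), cdr3_aa = character(), size = integer(),
               aggregate_frequency = numeric(), stringsAsFactors = FALSE)
  }
  pg$members <- lapply(planted$groups, function(g) nt[g])
  truth <- structure(list(
    planted_groups = pg,
    true_convergence = sum(pg$aggregate_frequency),
    artifact_clones = NULL,
    realized_convergence_with_errors = NA_real_,
    dropped_reads = 0L), class = "synthetic_truth")

  if (config$error_rate > 0) {
    inj <- inject_errors(rep_out, config$error_rate,
                         seed = sample.int(.Machine$integer.max, 1))
    rep_out <- inj$repertoire
    truth$artifact_clones <- inj$truth$artifact_clones
    truth$dropped_reads <- inj$truth$dropped_reads
    truth$realized_convergence_with_errors <-
      convergence(rep_out)$statistic
  }
  list(repertoire = rep_out, truth = truth)
}

# choose clone slots to rewrite into convergent groups; returns updated
# v_gene/aa vectors and the list of member index vectors
.plant_groups <- function(config, freqs, v_gene, aa) {
  sizes_avail <- as.integer(names(config$group_size_distribution))
  groups <- list()
  used <- logical(length(freqs))
  if (!is.null(config$convergence_target)) {
    remaining <- config$convergence_target
    guard <- 0L
    while (remaining > min(freqs[!used]) * 2 && guard < 10000L) {
      guard <- guard + 1L
      k <- sample(sizes_avail, 1, prob = config$group_size_distribution)
      cand <- which(!used & freqs <= remaining / (k - 0.5))
      if (length(cand) < k) break
      g <- if (length(cand) == k) cand else sample(cand, k)
      if (sum(freqs[g]) > remaining * 1.5) next
      groups[[length(groups) + 1L]] <- g
      used[g] <- TRUE
      remaining <- remaining - sum(freqs[g])
    }
  } else if (config$n_true_groups > 0L) {
    for (i in seq_len(config$n_true_groups)) {
      k <- sample(sizes_avail, 1, prob = config$group_size_distribution)
      cand <- which(!used)
      if (length(cand) < k) break
      g <- sample(cand, k)
      groups[[length(groups) + 1L]] <- g
      used[g] <- TRUE
    }
  }
  for (g in groups) {
    v_gene[g] <- v_gene[g[1]]
    aa[g] <- aa[g[1]]
  }
  list(groups = groups, v_gene = v_gene, aa = aa)
}

#' Multinomially subsample a repertoire to a given read depth
#'
#' Models finite sequencing depth: draws \code{depth} reads from the clone
#' frequency distribution; clones drawn zero times are absent from the
#' output and frequencies are renormalised.
#'
#' @param repertoire A \code{\link{tcr_repertoire}}.
#' @param depth Number of reads to draw (>= 1).
#' @param seed Integer seed.
#' @return A \code{\link{tcr_repertoire}} at the new depth.
#' @export
sample_reads <- function(repertoire, depth, seed = 1L) {
  stopifnot(inherits(repertoire, "tcr_repertoire"), depth >= 1)
  set.seed(seed)
  cl <- repertoire$clones
  counts <- as.numeric(stats::rmultinom(1, depth, cl$frequency))
  keep <- counts > 0
  cl <- cl[keep, , drop = FALSE]
  cl$read_count <- counts[keep]
  tcr_repertoire(cl, sample_id = repertoire$sample_id,
                 dialect = repertoire$dialect)
}

#' Inject read-level substitution sequencing errors
#'
#' Emulates residual per-base substitution errors: within the anchor-trimmed
#' CDR3 window of each read, every base is substituted independently with
#' probability \code{error_rate} (uniform choice among the three alternative
#' bases). Errored reads are regrouped into clones by their mutated
#' nucleotide sequence: synonymous mutations create amino-acid-identical,
#' nucleotide-distinct artifact clones that inflate convergence;
#' non-synonymous mutations create new amino-acid clones; mutations
#' introducing a stop codon are dropped as non-productive. The truth table
#' records every artifact's parent clone. Anchor codons are left untouched:
#' they are templated, conserved bases whose miscalls would break junction
#' recognition upstream of clonotype calling, and the artifact model uses
#' the same anchor-trimmed length convention.
#'
#' Reads with a single substitution (the overwhelming majority at realistic
#' error rates) are aggregated with a multinomial draw over the \code{3W}
#' possible single-base variants of a \code{W}-base window; multi-hit reads
#' are realised individually.
#'
#' @param repertoire A \code{\link{tcr_repertoire}} whose clones carry CDR3
#'   nucleotide junctions.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return List: \code{repertoire} (errored repertoire, frequencies
#'   renormalised over surviving reads) and \code{truth} with
#'   \code{artifact_clones} (data.frame: \code{cdr3_nt}, \code{v_gene},
#'   \code{parent_cdr3_nt}, \code{reads}, \code{synonymous}) and
#'   \code{dropped_reads}.
#' @export
inject_errors <- function(repertoire, error_rate, seed = 1L) {
  stopifnot(inherits(repertoire, "tcr_repertoire"),
            error_rate >= 0, error_rate < 1)
  cl <- repertoire$clones
  if (any(is.na(cl$cdr3_nt) | !nzchar(cl$cdr3_nt))) {
    stop("error injection requires nucleotide CDR3 sequences for all clones")
  }
  empty_truth <- list(artifact_clones = data.frame(
    cdr3_nt = character(), v_gene = character(),
    parent_cdr3_nt = character(), reads = numeric(),
    synonymous = logical(), stringsAsFactors = FALSE),
    dropped_reads = 0L)
  if (error_rate == 0) {
    return(list(repertoire = repertoire, truth = empty_truth))
  }
  set.seed(seed)
  L <- nchar(cl$cdr3_nt)
  W <- L - 6L  # anchor-trimmed window, in frame (codons 2..n-1)
  if (any(W < 3L)) stop("CDR3 too short for error injection")
  p_err <- -expm1(W * log1p(-error_rate))
  n_err <- stats::rbinom(nrow(cl), size = cl$read_count, prob = p_err)

  bases <- c("A", "C", "G", "T")
  # alt_lookup[b, r]: the r-th alternative base to base b
  alt_lookup <- t(vapply(bases, function(b) setdiff(bases, b),
                         character(3)))
  acc_parent <- integer(0)    # parent clone row index per variant
  acc_window <- character(0)  # mutated window sequence
  acc_reads <- numeric(0)

  p_single <- ifelse(p_err > 0,
                     W * error_rate * (1 - error_rate)^(W - 1) / p_err, 0)
  hit <- which(n_err > 0L)
  n_single <- stats::rbinom(length(hit), n_err[hit], p_single[hit])
  n_multi <- n_err[hit] - n_single

  # reads with exactly one substitution: aggregate identical
  # (clone, position, alternative) draws into one variant row
  if (sum(n_single) > 0) {
    cid <- rep.int(hit, n_single)
    pos <- floor(stats::runif(length(cid)) * W[cid]) + 1L
    alt_rank <- sample.int(3L, length(cid), replace = TRUE)
    o <- order(cid, pos, alt_rank)
    cid <- cid[o]; pos <- pos[o]; alt_rank <- alt_rank[o]
    first <- !duplicated(data.frame(cid, pos, alt_rank))
    reads <- tabulate(cumsum(first))
    cid <- cid[first]; pos <- pos[first]; alt_rank <- alt_rank[first]
    win <- substr(cl$cdr3_nt[cid], 4L, L[cid] - 3L)
    orig <- substring(win, pos, pos)
    substr(win, pos, pos) <- alt_lookup[cbind(match(orig, bases), alt_rank)]
    acc_parent <- c(acc_parent, cid)
    acc_window <- c(acc_window, win)
    acc_reads <- c(acc_reads, reads)
  }

  # multi-hit reads (rare): realised individually with distinct positions
  if (sum(n_multi) > 0) {
    cid <- rep.int(hit, n_multi)
    w2 <- W[cid]
    k <- integer(length(cid))
    for (wv in unique(w2)) {
      sel <- which(w2 == wv)
      kmax <- min(wv, 8L)
      pk <- stats::dbinom(2:kmax, wv, error_rate)
      k[sel] <- if (kmax == 2L) 2L else
        sample(2:kmax, length(sel), replace = TRUE, prob = pk)
    }
    pos_list <- lapply(seq_along(cid),
                       function(r) sample.int(w2[r], k[r]))
    win <- substr(cl$cdr3_nt[cid], 4L, L[cid] - 3L)
    for (j in seq_len(max(k))) {
      sel <- which(k >= j)
      pos <- vapply(pos_list[sel], `[`, integer(1), j)
      orig <- substring(win[sel], pos, pos)
      alt <- alt_lookup[cbind(match(orig, bases),
                              sample.int(3L, length(sel), replace = TRUE))]
      substr(win[sel], pos, pos) <- alt
    }
    acc_parent <- c(acc_parent, cid)
    acc_window <- c(acc_window, win)
    acc_reads <- c(acc_reads, rep(1, length(cid)))
  }

  # collapse duplicate (parent, mutated window) rows
  if (length(acc_parent)) {
    key <- paste(acc_parent, acc_window)
    o <- order(key)
    acc_parent <- acc_parent[o]; acc_window <- acc_window[o]
    acc_reads <- acc_reads[o]
    grp <- cumsum(!duplicated(key[o]))
    acc_reads <- as.numeric(rowsum(acc_reads, grp))
    first <- !duplicated(key[o])
    acc_parent <- acc_parent[first]; acc_window <- acc_window[first]
  }

  new_counts <- cl$read_count - n_err
  dropped <- 0L
  if (length(acc_parent)) {
    mid_aa <- translate_cdr3(acc_window)
    stop_hit <- has_stop(mid_aa)
    dropped <- sum(acc_reads[stop_hit])
    keep <- !stop_hit
    acc_parent <- acc_parent[keep]; acc_window <- acc_window[keep]
    acc_reads <- acc_reads[keep]; mid_aa <- mid_aa[keep]
  }
  if (length(acc_parent)) {
    parent_nt <- cl$cdr3_nt[acc_parent]
    parent_aa <- cl$cdr3_aa[acc_parent]
    Lp <- nchar(parent_nt)
    art_nt <- paste0(substr(parent_nt, 1L, 3L), acc_window,
                     substring(parent_nt, Lp - 2L))
    art_aa <- paste0(substr(parent_aa, 1L, 1L), mid_aa,
                     substring(parent_aa, nchar(parent_aa)))
    synonymous <- art_aa == parent_aa
    artifacts <- data.frame(cdr3_nt = art_nt,
                            cdr3_aa = art_aa,
                            v_call = cl$v_call[acc_parent],
                            v_gene = cl$v_gene[acc_parent],
                            parent_cdr3_nt = parent_nt,
                            read_count = acc_reads,
                            synonymous = synonymous,
                            stringsAsFactors = FALSE)
  } else {
    artifacts <- NULL
  }

  out <- cl[new_counts > 0, , drop = FALSE]
  out$read_count <- new_counts[new_counts > 0]
  if (!is.null(artifacts)) {
    out <- rbind(out[, c("cdr3_nt", "cdr3_aa", "v_call", "read_count",
                         "productive")],
                 data.frame(cdr3_nt = artifacts$cdr3_nt,
                            cdr3_aa = artifacts$cdr3_aa,
                            v_call = artifacts$v_call,
                            read_count = artifacts$read_count,
                            productive = TRUE, stringsAsFactors = FALSE))
  }
  rep_out <- tcr_repertoire(out, sample_id = repertoire$sample_id,
                            dialect = repertoire$dialect)
  truth <- empty_truth
  truth$dropped_reads <- as.integer(dropped)
  if (!is.null(artifacts)) {
    truth$artifact_clones <- artifacts[, c("cdr3_nt", "v_gene",
                                           "parent_cdr3_nt", "read_count",
                                           "synonymous")]
    names(truth$artifact_clones)[4] <- "reads"
  }
  list(repertoire = rep_out, truth = truth)
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-subject convergence and clonality targets from class-conditional
#' distributions calibrated to the responder / non-responder feature medians
#' and ranges the classifier is designed around (log-normal convergence with
#' medians 0.022 vs 0.008; truncated-normal clonality with means 0.24 vs
#' 0.133), simulates one repertoire per subject, and returns a labelled
#' feature table of measured (not target) features suitable for
#' \code{\link{lgocv}}.
#'
#' @param n_responders,n_nonresponders Subjects per class (>= 1).
#' @param seed Integer seed.
#' @param n_clones,depth Per-repertoire size; defaults are desk-scale (a few
#'   thousand clones) rather than full cohort scale so that cohort
#'   generation stays fast; pass larger values to emulate full-size
#'   repertoires.
#' @param error_rate Per-base substitution error rate applied to every
#'   subject (0 = clean data).
#' @param out_dir If non-NULL, clonotype tables (one per subject, in the
#'   requested dialect) and a \code{features.tsv} are written there.
#' @param dialect Dialect for written tables.
#' @return List: \code{features} (data.frame \code{sample_id},
#'   \code{convergence}, \code{clonality}, \code{response}),
#'   \code{repertoires}, \code{truths}, and the per-subject \code{targets}.
#' @export
generate_cohort <- function(n_responders, n_nonresponders, seed = 1L,
                            n_clones = 3000L, depth = 150000L,
                            error_rate = 0, out_dir = NULL,
                            dialect = "immunoseq") {
  stopifnot(n_responders >= 1, n_nonresponders >= 1)
  set.seed(seed)
  n <- n_responders + n_nonresponders
  response <- rep(c("responder", "non-responder"),
                  c(n_responders, n_nonresponders))
  conv_target <- ifelse(
    response == "responder",
    stats::rlnorm(n, meanlog = log(0.022), sdlog = 0.7),
    stats::rlnorm(n, meanlog = log(0.008), sdlog = 0.55))
  conv_target <- pmin(pmax(conv_target, 0.001), 0.12)
  clon_target <- ifelse(
    response == "responder",
    .rtruncnorm(n, 0.24, 0.08, 0.055, 0.376),
    .rtruncnorm(n, 0.133, 0.07, 0.055, 0.327))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  reps <- vector("list", n); truths <- vector("list", n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- simulation_config(n_clones = n_clones, depth = depth,
                             clonality_target = clon_target[i],
                             convergence_target = conv_target[i],
                             error_rate = error_rate,
                             seed = sub_seeds[i])
    sim <- simulate_repertoire(cfg)
    sim$repertoire$sample_id <- sprintf("subject%02d", i)
    reps[[i]] <- sim$repertoire
    truths[[i]] <- sim$truth
    s <- repertoire_summary(sim$repertoire)
    feats[[i]] <- data.frame(sample_id = sim$repertoire$sample_id,
                             convergence = s$convergence,
                             clonality = s$clonality,
                             response = response[i],
                             stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feats)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_clonotype_table(reps[[i]],
                            file.path(out_dir,
                                      paste0(features$sample_id[i], ".tsv")),
                            dialect = dialect)
    }
    utils::write.table(features, file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(features = features, repertoires = reps, truths = truths,
       targets = data.frame(sample_id = features$sample_id,
                            convergence_target = conv_target,
                            clonality_target = clon_target,
                            response = response,
                            stringsAsFactors = FALSE))
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  guard <- 0L
  while (any(bad) && guard < 1000L) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
    guard <- guard + 1L
  }
  pmin(pmax(out, lo), hi)
}

#' Simulate a cohort for error-rate calibration experiments
#'
#' Generates the cohort layout used to validate the error-rate grid fit by
#' parameter recovery: \code{n_samples} repertoires with no planted
#' convergence and clonality spread uniformly over [0.05, 0.35]. Half the
#' cohort has sequencing depth anti-correlated with clonality
#' (high-clonality samples shallow, low-clonality samples deep); the other
#' half has depth log-uniform and independent of clonality. A rank-based
#' (Spearman) fit can localise the error rate only where samples' predicted
#' convergence curves cross — near the model's saturation bend
#' \eqn{1/(3Lq)} in per-clone reads. The anti-correlated half produces
#' crossings at low rates (big saturated clones vs deep diffuse mass); the
#' independent half keeps shallow low-clonality samples in the cohort,
#' whose unsaturated small-clone mass is what distinguishes high rates.
#'
#' @param error_rate True per-base substitution rate injected into every
#'   sample.
#' @param seed Integer seed (kept below ~2e7; per-sample seeds derive from
#'   it deterministically).
#' @param n_samples Cohort size.
#' @param n_clones Clones per repertoire.
#' @return List: \code{repertoires}, \code{observed} (realised convergence
#'   per sample), \code{clonality_targets}, \code{depths}.
#' @export
error_recovery_cohort <- function(error_rate, seed = 1L, n_samples = 20L,
                                  n_clones = 2000L) {
  seed <- as.integer(seed %% 21000000L)
  set.seed(seed)
  clon <- stats::runif(n_samples, 0.05, 0.35)
  half <- seq_len(n_samples) <= n_samples / 2
  depths <- ifelse(half,
    10^(log10(1.2e6) - (clon - 0.05) / 0.30 * log10(18)) *
      10^stats::runif(n_samples, -0.25, 0.25),
    10^stats::runif(n_samples, log10(3e4), log10(1e6)))
  depths <- round(depths)
  reps <- vector("list", n_samples); obs <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    cfg <- simulation_config(n_clones = n_clones, depth = depths[i],
                             clonality_target = clon[i], n_true_groups = 0L,
                             error_rate = error_rate,
                             seed = seed * 100L + i)
    sim <- simulate_repertoire(cfg)
    reps[[i]] <- sim$repertoire
    obs[i] <- if (error_rate > 0) {
      sim$truth$realized_convergence_with_errors
    } else {
      convergence(sim$repertoire)$statistic
    }
  }
  list(repertoires = reps, observed = obs, clonality_targets = clon,
       depths = depths)
}
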