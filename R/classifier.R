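#' Fit the logistic-regression response model
#'
#' Unregularised maximum-likelihood logistic regression (binomial GLM fitted
#' by iteratively reweighted least squares) of clinical response on
#' repertoire features — by default TCR convergence and clonality. No
#' feature standardisation is applied. On perfectly separable data the fit
#' returns with \code{converged = FALSE}-style saturated probabilities; the
#' separation warning from the underlying IRLS is captured on the object.
#'
#' @param features data.frame with columns \code{response} (binary: logical,
#'   0/1, or a two-level factor/character with positive level
#'   \code{"responder"}) and the predictor columns.
#' @param predictors Character vector of feature column names; default
#'   \code{c("convergence", "clonality")}.
#' @return Object of class \code{tcr_logistic}: the underlying \code{glm}
#'   fit plus \code{intercept}, \code{coefficients}, \code{converged},
#'   \code{n_iterations}, \code{predictors}, \code{separation}.
#' @export
fit_logistic <- function(features, predictors = c("convergence", "clonality")) {
  y <- .as_binary_response(features$response)
  if (length(unique(y)) < 2L) {
    stop("degenerate labels: both responders and non-responders are required")
  }
  missing_cols <- setdiff(predictors, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  X <- features[, predictors, drop = FALSE]
  if (any(!vapply(X, function(v) stats::sd(v) > 0, logical(1)))) {
    stop("constant feature: logistic fit is unidentifiable")
  }
  dat <- cbind(.response = y, X)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.response ~ ., family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  structure(list(fit = fit,
                 intercept = unname(stats::coef(fit)[1]),
                 coefficients = stats::coef(fit)[-1],
                 converged = fit$converged && !separation,
                 n_iterations = fit$iter,
                 predictors = predictors,
                 separation = separation),
            class = "tcr_logistic")
}

.as_binary_response <- function(response) {
  if (is.null(response)) stop("feature table lacks a 'response' column")
  if (is.logical(response)) return(as.integer(response))
  if (is.numeric(response)) {
    if (!all(response %in% c(0, 1))) stop("numeric response must be 0/1")
    return(as.integer(response))
  }
  r <- tolower(as.character(response))
  pos <- r %in% c("responder", "response", "r", "yes", "1", "true")
  neg <- r %in% c("non-responder", "nonresponder", "nr", "no", "0", "false")
  if (!all(pos | neg)) {
    stop("cannot interpret response labels: ",
         paste(unique(response[!(pos | neg)]), collapse = ", "))
  }
  as.integer(pos)
}

#' @export
print.tcr_logistic <- function(x, ...) {
  cat("Logistic response model (", paste(x$predictors, collapse = " + "),
      ")\n", sep = "")
  print(signif(stats::coef(x$fit), 4))
  if (!x$converged) cat("note: IRLS flagged non-convergence/separation\n")
  invisible(x)
}

#' @exportS3Method stats::coef
coef.tcr_logistic <- function(object, ...) stats::coef(object$fit)

#' @exportS3Method base::summary
summary.tcr_logistic <- function(object, ...) summary(object$fit)

#' @export
predict.tcr_logistic <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, newdata = newdata, type = "response"))
}

#' Leave-group-out cross-validation of the response classifier
#'
#' Repeated random class-stratified train/test splits: in each of
#' \code{n_splits} splits, \code{train_fraction} of each class (floor
#' rounding) trains a logistic model that then scores the held-out samples.
#' All held-out scores are pooled into one prediction set, on which the ROC
#' curve, AUC, and Youden-optimal operating point are computed.
#'
#' @param features data.frame with \code{sample_id}, \code{response}, and
#'   the predictor columns.
#' @param predictors Feature column names (one or both of
#'   \code{"convergence"}, \code{"clonality"}, or any numeric columns).
#' @param n_splits Number of random splits (default 2000).
#' @param train_fraction Fraction of each class used for training
#'   (default 0.75).
#' @param seed Integer seed; the whole procedure is reproducible from it.
#' @return Object of class \code{tcr_lgocv}: \code{pooled_predictions}
#'   (data.frame: \code{sample_id}, \code{split}, \code{score},
#'   \code{label}), \code{auc}, \code{roc} (a \code{\link{roc_curve}}),
#'   \code{operating_point}, \code{n_splits}, \code{train_fraction},
#'   \code{n_redrawn}, \code{predictors}, \code{seed}.
#' @export
lgocv <- function(features, predictors = c("convergence", "clonality"),
                  n_splits = 2000L, train_fraction = 0.75, seed = 1L) {
  y <- .as_binary_response(features$response)
  if (is.null(features$sample_id)) {
    features$sample_id <- paste0("s", seq_len(nrow(features)))
  }
  idx_pos <- which(y == 1L); idx_neg <- which(y == 0L)
  n_tr_pos <- floor(train_fraction * length(idx_pos))
  n_tr_neg <- floor(train_fraction * length(idx_neg))
  if (n_tr_pos < 1L || n_tr_neg < 1L ||
      n_tr_pos >= length(idx_pos) && n_tr_neg >= length(idx_neg)) {
    stop("too few samples per class for a ", train_fraction, " split")
  }
  set.seed(seed)
  n_held <- (length(idx_pos) - n_tr_pos) + (length(idx_neg) - n_tr_neg)
  ids <- character(n_splits * n_held)
  splits <- integer(n_splits * n_held)
  scores <- numeric(n_splits * n_held)
  labels <- integer(n_splits * n_held)
  n_redrawn <- 0L
  at <- 0L
  for (s in seq_len(n_splits)) {
    repeat {
      tr <- c(sample(idx_pos, n_tr_pos), sample(idx_neg, n_tr_neg))
      if (length(unique(y[tr])) == 2L) break
      n_redrawn <- n_redrawn + 1L
    }
    te <- setdiff(seq_along(y), tr)
    model <- fit_logistic(features[tr, , drop = FALSE], predictors)
    sc <- predict(model, features[te, , drop = FALSE])
    put <- at + seq_along(te)
    ids[put] <- features$sample_id[te]
    splits[put] <- s
    scores[put] <- sc
    labels[put] <- y[te]
    at <- at + length(te)
  }
  pooled <- data.frame(sample_id = ids, split = splits, score = scores,
                       label = labels, stringsAsFactors = FALSE)
  roc <- roc_curve(pooled$score, pooled$label)
  op <- youden_optimal(pooled$score, pooled$label)
  structure(list(pooled_predictions = pooled, auc = roc$auc, roc = roc,
                 operating_point = op, n_splits = n_splits,
                 train_fraction = train_fraction, n_redrawn = n_redrawn,
                 predictors = predictors, seed = seed),
            class = "tcr_lgocv")
}

#' @export
print.tcr_lgocv <- function(x, ...) {
  cat("Leave-group-out cross-validation (",
      paste(x$predictors, collapse = " + "), ")\n", sep = "")
  cat("  splits: ", x$n_splits, " at train fraction ", x$train_fraction,
      " (", nrow(x$pooled_predictions), " pooled predictions)\n", sep = "")
  cat("  pooled AUC: ", round(x$auc, 3), "\n", sep = "")
  op <- x$operating_point
  cat("  Youden operating point: threshold ", signif(op["threshold"], 3),
      ", sensitivity ", round(op["sensitivity"], 2),
      ", specificity ", round(op["specificity"], 2),
      ", PPV ", round(op["ppv"], 2), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.tcr_lgocv <- function(x, ...) {
  plot(1 - x$roc$specificity, x$roc$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = paste0("Pooled LGOCV ROC (AUC = ", round(x$auc, 2), ")"), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' ROC curve and AUC of a score vector
#'
#' Threshold sweep over the unique scores (predicting positive where
#' \code{score >= threshold}); the AUC is computed by the trapezoidal rule,
#' which with the midrank convention for tied scores equals the normalised
#' Mann-Whitney U statistic, and is invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores Numeric score vector (higher = more responder-like).
#' @param labels Binary labels (1 = responder / positive).
#' @return Object of class \code{roc_curve}: data.frame fields
#'   \code{threshold}, \code{sensitivity}, \code{specificity}, plus
#'   \code{auc}.
#' @export
roc_curve <- function(scores, labels) {
  labels <- .as_binary_response(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("ROC requires both classes to be present")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0L) / n0,
                 numeric(1))
  # midrank Mann-Whitney AUC (= trapezoid over the tie-collapsed curve)
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(threshold = c(Inf, thr),
                 sensitivity = c(0, sens),
                 specificity = c(1, spec),
                 auc = auc),
            class = "roc_curve")
}

#' @rdname roc_curve
#' @export
roc_auc <- function(scores, labels) roc_curve(scores, labels)$auc

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve: ", length(x$threshold), " thresholds, AUC = ",
      round(x$auc, 4), "\n", sep = "")
  invisible(x)
}

#' Youden-optimal operating point
#'
#' Sweeps every candidate threshold (predict positive where
#' \code{score >= threshold}) and returns the one maximising Youden's
#' J = sensitivity + specificity - 1. Ties are broken toward the higher
#' specificity (i.e. the higher threshold); the positive predictive value is
#' computed from the confusion matrix at the chosen threshold.
#'
#' @inheritParams roc_curve
#' @return Named numeric vector: \code{threshold}, \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{youden_j}.
#' @export
youden_optimal <- function(scores, labels) {
  labels <- .as_binary_response(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  best <- NULL
  for (t in thr) {
    pos <- scores >= t
    tp <- sum(pos & labels == 1L); fp <- sum(pos & labels == 0L)
    sens <- tp / n1; spec <- 1 - fp / n0
    j <- sens + spec - 1
    if (is.null(best) || j > best["youden_j"] + 1e-12 ||
        (abs(j - best["youden_j"]) <= 1e-12 && spec > best["specificity"])) {
      ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      best <- c(threshold = t, sensitivity = sens, specificity = spec,
                ppv = ppv, youden_j = j)
    }
  }
  best
}
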