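#' Pair-density prior probability of a functional interaction
#'
#' The prior P(FI) is the number of known positive pairs divided by the number
#' of possible unordered pairs over the proteins of the positive set,
#' C(n_proteins, 2). It is computed from pair density, not from the
#' positive:negative ratio of the training sample, so the score scale does
#' not depend on how many negatives were drawn.
#'
#' @param n_positive_pairs number of positive (filtered) FI pairs.
#' @param n_proteins number of distinct proteins in those pairs.
#' @return prior probability in (0, 1].
#' @export
#' @examples
#' compute_prior(3, 4)  # 3 / C(4,2) = 0.5
compute_prior <- function(n_positive_pairs, n_proteins) {
  if (n_proteins < 2) stop("need at least two proteins")
  total <- choose(n_proteins, 2)
  if (n_positive_pairs < 0 || n_positive_pairs > total) {
    stop("n_positive_pairs must lie in [0, C(n_proteins, 2)]")
  }
  n_positive_pairs / total
}

#' Sample negative training pairs
#'
#' Draws `n` distinct unordered pairs uniformly from the protein universe of
#' the positive set, excluding the known positives (unlabeled random pairs
#' are overwhelmingly non-interacting, and removing the known positives
#' removes the residual label noise at negligible cost).
#'
#' @param universe character vector of proteins.
#' @param positives positive pair set (keys, matrix, data.frame or
#'   [fi_table()]).
#' @param n number of negative pairs.
#' @param seed optional integer seed; the draw is reproducible under it.
#' @return two-column character matrix of canonical pairs.
#' @export
sample_negative_pairs <- function(universe, positives, n, seed = NULL) {
  if (inherits(positives, "fi_table")) {
    positives <- pair_keys(positives$protein_a, positives$protein_b)
  }
  pos <- as_pair_keys(positives)
  with_seed(seed, sample_pairs(universe, n, exclude = pos))
}

# coerce a feature input (matrix or build_feature_matrix() data.frame) to a
# logical matrix with the nine canonical columns
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    missing <- setdiff(FI_FEATURES, names(x))
    if (length(missing) > 0L) {
      stop("missing feature column(s): ", paste(missing, collapse = ", "))
    }
    x <- as.matrix(x[, FI_FEATURES, drop = FALSE])
  }
  storage.mode(x) <- "logical"
  if (ncol(x) != length(FI_FEATURES)) {
    stop("feature matrix must have exactly ", length(FI_FEATURES), " columns")
  }
  colnames(x) <- FI_FEATURES
  x
}

#' Train the naive Bayes functional-interaction classifier
#'
#' Estimates per-feature class-conditional probabilities
#' theta\[i, c\] = P(feature i TRUE | class c) with Laplace add-one smoothing,
#' `(count + 1) / (class size + 2)`, which keeps every conditional strictly
#' inside (0, 1). The scoring prior is supplied separately (see
#' [compute_prior()]); the negative:positive ratio of the training sample
#' only affects the conditional estimates.
#'
#' @param positives,negatives feature matrices (logical matrix or
#'   [build_feature_matrix()] output), one row per training pair.
#' @param prior prior probability P(FI) used at scoring time.
#' @param threshold score cutoff for [predict_fis()] (default 0.50).
#' @return an object of class `"nbc_model"`: list with `prior`, `theta` (9 x 2
#'   matrix, columns `fi`, `not_fi`), `threshold`, `features`, `n_pos`,
#'   `n_neg`.
#' @export
train_nbc <- function(positives, negatives, prior, threshold = 0.5) {
  pos <- as_feature_matrix(positives)
  neg <- as_feature_matrix(negatives)
  if (nrow(pos) == 0L || nrow(neg) == 0L) {
    stop("both training classes must be non-empty")
  }
  if (prior <= 0 || prior >= 1) stop("prior must lie strictly in (0, 1)")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  theta <- cbind(fi = (colSums(pos) + 1) / (nrow(pos) + 2),
                 not_fi = (colSums(neg) + 1) / (nrow(neg) + 2))
  rownames(theta) <- FI_FEATURES
  structure(list(prior = prior, theta = theta, threshold = threshold,
                 features = FI_FEATURES, n_pos = nrow(pos), n_neg = nrow(neg)),
            class = "nbc_model")
}

#' @export
print.nbc_model <- function(x, ...) {
  cat("Naive Bayes FI classifier\n")
  cat(sprintf("  prior P(FI) = %.4g, threshold = %.2f\n", x$prior, x$threshold))
  cat(sprintf("  trained on %d positives / %d negatives\n", x$n_pos, x$n_neg))
  print(round(x$theta, 4))
  invisible(x)
}

#' Score protein pairs with a trained classifier
#'
#' Returns the posterior probability that a pair is a functional interaction:
#' `pi L1 / (pi L1 + (1 - pi) L0)` where `Lc` is the product over features of
#' `theta[i, c]` (feature TRUE) or `1 - theta[i, c]` (feature FALSE).
#' Likelihoods are accumulated in log space for numerical stability.
#'
#' @param model an `"nbc_model"`.
#' @param features feature matrix (logical matrix or
#'   [build_feature_matrix()] output); one row per pair.
#' @return numeric vector of posterior probabilities.
#' @export
score_pairs <- function(model, features) {
  v <- as_feature_matrix(features)
  lth <- log(model$theta)
  lth1m <- log(1 - model$theta)
  l1 <- v %*% lth[, "fi"] + (!v) %*% lth1m[, "fi"]
  l0 <- v %*% lth[, "not_fi"] + (!v) %*% lth1m[, "not_fi"]
  s1 <- log(model$prior) + as.vector(l1)
  s0 <- log1p(-model$prior) + as.vector(l0)
  1 / (1 + exp(s0 - s1))
}

#' @rdname score_pairs
#' @param feature_vector a single logical vector of nine features.
#' @export
score_pair <- function(model, feature_vector) {
  score_pairs(model, matrix(feature_vector, nrow = 1))
}

#' Evaluate a classifier by ROC analysis on an independent test set
#'
#' Computes the true-positive and false-positive rate at every distinct score
#' (classifying a pair as positive when its score is >= the cutoff), the area
#' under the curve by the trapezoid rule, and sensitivity/specificity at the
#' model's operating threshold.
#'
#' @param model an `"nbc_model"`.
#' @param test_pos,test_neg feature matrices of positive and negative test
#'   pairs.
#' @return object of class `"roc_result"`: list with `points` (data.frame
#'   `threshold`, `fpr`, `tpr`), `auc`, `sensitivity`, `specificity`,
#'   `threshold`.
#' @export
evaluate_roc <- function(model, test_pos, test_neg) {
  sp <- score_pairs(model, test_pos)
  sn <- score_pairs(model, test_neg)
  if (length(sp) == 0L || length(sn) == 0L) {
    stop("both test classes must be non-empty")
  }
  cuts <- sort(unique(c(sp, sn)), decreasing = TRUE)
  tpr <- vapply(cuts, function(t) mean(sp >= t), numeric(1))
  fpr <- vapply(cuts, function(t) mean(sn >= t), numeric(1))
  points <- data.frame(threshold = c(Inf, cuts), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc,
                 sensitivity = mean(sp >= model$threshold),
                 specificity = mean(sn < model$threshold),
                 threshold = model$threshold),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f; at threshold %.2f sensitivity = %.3f, specificity = %.3f\n",
              x$auc, x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Predict functional interactions for candidate pairs
#'
#' Emits the candidate pairs whose score reaches the model threshold.
#' Candidates with no true feature are never predicted, whatever their score:
#' a prediction must rest on at least one piece of positive evidence.
#'
#' @param model an `"nbc_model"`.
#' @param candidates [build_feature_matrix()] output (pair columns plus the
#'   nine features).
#' @param threshold optional override of `model$threshold`.
#' @return an [fi_table()] with provenance `"predicted"` and a `score`
#'   column.
#' @export
predict_fis <- function(model, candidates, threshold = model$threshold) {
  v <- as_feature_matrix(candidates)
  scores <- score_pairs(model, v)
  keep <- rowSums(v) >= 1 & scores >= threshold
  out <- fi_table(candidates$protein_a[keep], candidates$protein_b[keep],
                  provenance = "predicted", direction = "undirected",
                  sources = "nbc")
  out$score <- scores[keep]
  out
}

#' Serialize / load a trained classifier as JSON
#'
#' @param model an `"nbc_model"`.
#' @param path file path.
#' @return `write_nbc_model()`: `path` invisibly; `read_nbc_model()`: an
#'   `"nbc_model"`.
#' @export
write_nbc_model <- function(model, path) {
  obj <- list(prior = model$prior,
              threshold = model$threshold,
              features = model$features,
              theta_fi = unname(model$theta[, "fi"]),
              theta_not_fi = unname(model$theta[, "not_fi"]),
              n_pos = model$n_pos, n_neg = model$n_neg,
              generator = paste0("finet ", utils::packageVersion("finet")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nbc_model
#' @export
read_nbc_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- cbind(fi = obj$theta_fi, not_fi = obj$theta_not_fi)
  rownames(theta) <- obj$features
  structure(list(prior = obj$prior, theta = theta, threshold = obj$threshold,
                 features = obj$features, n_pos = obj$n_pos, n_neg = obj$n_neg),
            class = "nbc_model")
}
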