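#' Leave-one-out multinomial classification of population membership
#'
#' For each sample, fits a multinomial logistic regression of population
#' label on the marker dosages of all other samples and predicts the
#' left-out sample's population as the argmax of the predicted class
#' probabilities. Because highly informative markers often separate the
#' populations perfectly (where the unpenalized maximum-likelihood
#' estimate diverges), a small L2 penalty is always applied; it leaves the
#' argmax predictions unchanged. The reference category of the logit
#' parameterization is the last population in sorted label order; this
#' choice does not affect the predicted probabilities.
#'
#' @param g a labeled [genotype_matrix()], typically restricted to the
#'   top-ranked markers via [subset_markers()]; every population must have
#'   at least 2 samples.
#' @param ridge L2 weight-decay penalty (1e-4 by default).
#' @param max_iter iteration cap per fit.
#' @return A list of class `classification_result`: `n_markers_used`,
#'   `confusion` (k x k, rows = truth, columns = prediction), `accuracy`,
#'   `accuracy_ci95` (exact Clopper-Pearson), `per_class_auc`
#'   (one-vs-rest, from the confusion counts), `mauc` and
#'   `class_proportions`.
#' @export
loocv_classify <- function(g, ridge = 1e-4, max_iter = 500) {
  stopifnot(inherits(g, "genotype_matrix"))
  labels <- g$population_labels
  if (is.null(labels)) stop("population labels are required")
  pops <- sort(unique(labels))
  k <- length(pops)
  if (k < 2L) stop("need at least two populations")
  if (any(table(labels) < 2L)) {
    stop("every population needs at least 2 samples for LOOCV")
  }
  x <- impute_marker_means(g$codes)
  colnames(x) <- paste0("m", seq_len(ncol(x)))
  # last sorted population as the reference category of the logit
  y <- factor(labels, levels = c(pops[k], pops[-k]))
  dat <- data.frame(.pop = y, x, check.names = FALSE)
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- nnet::multinom(.pop ~ ., data = dat[-i, , drop = FALSE],
                          decay = ridge, maxit = max_iter, trace = FALSE)
    if (!is.null(fit$convergence) && fit$convergence != 0) {
      stop("convergence error: multinomial fit did not converge ",
           "(sample ", g$sample_ids[i], " left out)")
    }
    pr <- predict(fit, newdata = dat[i, , drop = FALSE], type = "probs")
    if (k == 2L) {
      # nnet returns P(second level) for the binomial case
      pr <- stats::setNames(c(1 - pr, pr), levels(y))
    }
    pred[i] <- names(pr)[which.max(pr)]
  }
  confusion <- table(factor(labels, levels = pops),
                     factor(pred, levels = pops))
  confusion <- unclass(confusion)
  correct <- sum(diag(confusion))
  acc <- correct / n
  ci <- stats::binom.test(correct, n)$conf.int
  cls_n <- rowSums(confusion)
  per_auc <- vapply(seq_len(k), function(i) {
    m <- cls_n[i]                      # actual positives
    nn <- n - m                        # actual negatives
    x_fp <- sum(confusion[-i, i])      # predicted i, truly other
    fn <- sum(confusion[i, -i])        # truly i, predicted other
    binary_auc(nn, m, x_fp + fn, x_fp)
  }, numeric(1))
  names(per_auc) <- pops
  props <- cls_n / n
  structure(list(
    n_markers_used = ncol(g$codes),
    confusion = confusion,
    accuracy = acc,
    accuracy_ci95 = as.numeric(ci),
    per_class_auc = per_auc,
    mauc = mauc(per_auc, props),
    class_proportions = props
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "LOOCV classification on %d marker(s): accuracy %.4f (95%% CI %.4f-%.4f), mAUC %.4f\n",
    x$n_markers_used, x$accuracy, x$accuracy_ci95[1], x$accuracy_ci95[2],
    x$mauc))
  print(x$confusion)
  invisible(x)
}

#' Confusion-count AUC for a binary classifier
#'
#' The closed-form area under the ROC curve of a hard classifier summarized
#' by its confusion counts: AUC = 1 - 0.5 * (x / n + (e - x) / m), where n
#' and m are the numbers of actual negatives and positives, e the total
#' classification errors, and x the false positives (so e - x are the
#' false negatives).
#'
#' @param n_true_negative,m_true_positive class sizes (both > 0).
#' @param e_errors total misclassifications.
#' @param x_false_positives how many of the errors are false positives.
#' @return The AUC in [0, 1].
#' @export
binary_auc <- function(n_true_negative, m_true_positive, e_errors,
                       x_false_positives) {
  n <- n_true_negative
  m <- m_true_positive
  e <- e_errors
  x <- x_false_positives
  if (n <= 0 || m <= 0) stop("undefined-class error: empty class")
  stopifnot(x >= 0, x <= e, x <= n, e - x <= m)
  1 - 0.5 * (x / n + (e - x) / m)
}

#' Multiclass AUC as a weighted sum of one-vs-rest AUCs
#'
#' @param per_class_auc per-class one-vs-rest AUC values.
#' @param class_proportions class weights on the simplex.
#' @return The weighted multiclass AUC.
#' @export
mauc <- function(per_class_auc, class_proportions) {
  stopifnot(length(per_class_auc) == length(class_proportions))
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stop("input error: class proportions must lie on the simplex")
  }
  sum(per_class_auc * class_proportions)
}

#' Overlap of top-N marker sets across ranking methods
#'
#' Assigns each marker in the union of the methods' top-N sets a binary
#' membership vector (one digit per method, 1 = selected by that method)
#' and tabulates the membership patterns, mirroring the standard
#' upset-style comparison of feature-selection methods.
#'
#' @param rankings a named list of `marker_ranking` data frames over the
#'   same marker universe.
#' @param n size of each top set.
#' @return A list of class `topn_overlap`: `membership` (data frame of
#'   marker_id, one 0/1 column per method, and the `pattern` string),
#'   `pattern_counts` (named integer vector), `pairwise` (matrix of
#'   top-set intersection sizes) and `n`.
#' @export
topn_overlap <- function(rankings, n) {
  stopifnot(length(rankings) >= 2)
  methods <- names(rankings) %||%
    vapply(rankings, function(r) r$method[1], character(1))
  if (is.null(names(rankings))) names(rankings) <- methods
  universe <- sort(rankings[[1]]$marker_id)
  for (r in rankings[-1]) {
    if (!identical(sort(r$marker_id), universe)) {
      stop("input error: rankings do not share a marker universe")
    }
  }
  stopifnot(n >= 1, n <= length(universe))
  tops <- lapply(rankings, top_markers, n = n)
  union_ids <- sort(unique(unlist(tops)))
  memb <- vapply(tops, function(ids) as.integer(union_ids %in% ids),
                 integer(length(union_ids)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1)
  colnames(memb) <- methods
  pattern <- apply(memb, 1, paste, collapse = "")
  pairwise <- matrix(NA_integer_, length(tops), length(tops),
                     dimnames = list(methods, methods))
  for (i in seq_along(tops)) {
    for (j in seq_along(tops)) {
      pairwise[i, j] <- length(intersect(tops[[i]], tops[[j]]))
    }
  }
  structure(list(
    membership = data.frame(marker_id = union_ids, memb,
                            pattern = pattern, stringsAsFactors = FALSE),
    pattern_counts = table(pattern),
    pairwise = pairwise,
    n = n
  ), class = "topn_overlap")
}

#' Pairwise correlation of ancestry estimates across methods
#'
#' Pearson correlation of one designated ancestry column between every
#' pair of Q matrices (e.g. the African-ancestry column estimated from
#' different marker rankings).
#'
#' @param estimates a named list of n x K ancestry matrices over the same
#'   individuals (aligned by row name when named).
#' @param ancestry_column column to compare (name or index).
#' @return A symmetric correlation matrix with unit diagonal; pairs
#'   involving a zero-variance column are `NA` and flagged via the
#'   `zero_variance` attribute.
#' @export
q_correlations <- function(estimates, ancestry_column) {
  stopifnot(length(estimates) >= 2)
  nm <- names(estimates) %||% paste0("method", seq_along(estimates))
  ref_rows <- rownames(estimates[[1]])
  cols <- vapply(estimates, function(q) {
    q <- as.matrix(q)
    if (nrow(q) != nrow(as.matrix(estimates[[1]]))) {
      stop("input error: estimates cover different individuals")
    }
    if (!is.null(ref_rows) && !is.null(rownames(q)) &&
        all(ref_rows %in% rownames(q))) {
      q <- q[ref_rows, , drop = FALSE]
    }
    q[, ancestry_column]
  }, numeric(nrow(as.matrix(estimates[[1]]))))
  colnames(cols) <- nm
  zero_var <- apply(cols, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(cols))
  diag(r) <- 1
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r) <- 1
  attr(r, "zero_variance") <- nm[zero_var]
  r
}
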