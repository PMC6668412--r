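# Mean-impute missing dosages per marker (columns); constant-NA columns
# become 0. Machine-learning scorers cannot take NA predictors.
impute_marker_means <- function(codes) {
  x <- codes
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  x
}

#' PCA loading scores
#'
#' Scores each marker by the largest magnitude of its loadings on the
#' first two principal components of the column-centered dosage matrix:
#' b_j = max(|a_1j|, |a_2j|). Markers that drive the dominant axes of
#' genetic variation (typically population structure) receive high
#' scores. Genotypes are not variance-scaled; missing dosages are imputed
#' to the marker mean before the decomposition. Eigenvector signs are
#' canonicalized (largest-magnitude loading positive), which does not
#' affect scores but stabilizes serialized loadings.
#'
#' @param g a [genotype_matrix()] with at least 3 samples and 2 markers.
#' @return A `marker_ranking` data frame with attributes `loadings`
#'   (an L x 2 matrix) and `explained_variance_fraction`.
#' @export
pca_scores <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  x <- impute_marker_means(g$codes)
  if (nrow(x) < 3L || ncol(x) < 2L) {
    stop("need at least 3 samples and 2 markers")
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = 0)
  if (sum(sv$d > max(sv$d) * 1e-10) < 2L) {
    stop("rank-deficiency error: fewer than 2 nonzero singular values")
  }
  a <- sv$v[, 1:2, drop = FALSE]
  for (i in 1:2) {
    top <- which.max(abs(a[, i]))
    if (a[top, i] < 0) a[, i] <- -a[, i]
  }
  score <- pmax(abs(a[, 1]), abs(a[, 2]))
  out <- new_ranking("PCA", g$marker_ids, score, g$chrom, g$bp)
  attr(out, "loadings") <- a
  attr(out, "explained_variance_fraction") <- (sv$d^2 / sum(sv$d^2))[1:2]
  out
}

#' Random-forest Gini importance scores
#'
#' Trains a random-forest classifier of population membership on the
#' dosage matrix and scores each marker by its mean decrease in Gini
#' impurity, normalized to sum to 1. Samples are processed in a canonical
#' order (sorted by sample id) so that the result depends only on the data
#' and the seed, not on input row order.
#'
#' @param g a labeled [genotype_matrix()].
#' @param n_trees number of trees in the ensemble (500 by default).
#' @param seed integer seed; the forest is bit-reproducible given it.
#' @return A `marker_ranking` data frame.
#' @export
rf_scores <- function(g, n_trees = 500, seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  labels <- g$population_labels
  if (is.null(labels)) stop("population labels are required")
  if (length(unique(labels)) < 2L) {
    stop("degenerate-label error: need at least two population labels")
  }
  ord <- order(g$sample_ids, method = "radix")
  x <- impute_marker_means(g$codes)[ord, , drop = FALSE]
  y <- factor(labels[ord])
  fit <- with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = n_trees,
                               importance = FALSE))
  imp <- fit$importance[, "MeanDecreaseGini"]
  total <- sum(imp)
  score <- if (total > 0) imp / total else imp
  new_ranking("RF", g$marker_ids, unname(score), g$chrom, g$bp)
}

#' Linear SVM weight scores
#'
#' Fits k one-versus-rest linear maximum-margin classifiers (population j
#' against all others) on the dosage matrix and scores each marker by the
#' average absolute weight across the k classifiers,
#' omega_j = (1/k) sum_i |w_ij|. Markers with large weights define the
#' separating hyperplanes and therefore discriminate populations well.
#'
#' @param g a labeled [genotype_matrix()] with k >= 2 populations.
#' @param regularization soft-margin cost constant C (1.0 by default).
#' @return A `marker_ranking` data frame with attribute `weights`
#'   (k x L matrix of hyperplane weights).
#' @export
svm_scores <- function(g, regularization = 1.0) {
  stopifnot(inherits(g, "genotype_matrix"))
  labels <- g$population_labels
  if (is.null(labels)) stop("population labels are required")
  pops <- sort(unique(labels))
  if (length(pops) < 2L) stop("need at least two populations")
  ord <- order(g$sample_ids, method = "radix")
  x <- impute_marker_means(g$codes)[ord, , drop = FALSE]
  labels <- labels[ord]
  w <- matrix(0, length(pops), ncol(x),
              dimnames = list(pops, g$marker_ids))
  for (j in seq_along(pops)) {
    y <- factor(ifelse(labels == pops[j], "pos", "rest"),
                levels = c("pos", "rest"))
    fit <- e1071::svm(x = x, y = y, kernel = "linear",
                      cost = regularization, scale = FALSE)
    wj <- drop(crossprod(fit$coefs, fit$SV))
    # the dual solver orients the hyperplane by order of appearance of the
    # labels, not by factor level; canonicalize so the decision value
    # increases toward population j
    pos <- labels == pops[j]
    if (mean(x[pos, , drop = FALSE] %*% wj) <
        mean(x[!pos, , drop = FALSE] %*% wj)) {
      wj <- -wj
    }
    w[j, ] <- wj
  }
  score <- colMeans(abs(w))
  out <- new_ranking("SVM", g$marker_ids, unname(score), g$chrom, g$bp)
  attr(out, "weights") <- w
  out
}
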