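#' Supervised maximum-likelihood ancestry proportions
#'
#' Estimates each individual's global ancestry proportion vector q on the
#' K-simplex by maximizing the binomial admixture log-likelihood
#' sum_l [ g_l log(sum_k q_k f_kl) + (2 - g_l) log(sum_k q_k (1 - f_kl)) ]
#' with the reference allele frequencies f_kl held fixed (supervised
#' projection, the analogue of running a cluster program with anchored
#' reference populations). Optimization uses the standard multiplicative
#' EM update, which is monotone in the log-likelihood and preserves the
#' simplex; iterations start from the uniform vector and stop when no
#' individual's log-likelihood improves by more than `tol`.
#'
#' @param g a [genotype_matrix()] restricted to the marker subset of
#'   interest; missing genotypes are skipped per individual.
#' @param ft a [pop_freq_table()] covering the same markers (extra markers
#'   are ignored). Frequencies are clamped to [1e-6, 1 - 1e-6] to avoid
#'   log(0) at fixed alleles.
#' @param tol convergence tolerance on the per-individual log-likelihood
#'   gain.
#' @param max_iter iteration cap.
#' @return An n x K matrix of ancestry proportions (rows on the simplex),
#'   with individual ids as row names and population names as column
#'   names. Attributes: `loglik` (total log-likelihood per iteration),
#'   `n_iter`, and `flat` (TRUE when the frequencies carry no ancestry
#'   information and the uniform vector was returned).
#' @export
estimate_q <- function(g, ft, tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(ft, "pop_freq_table"))
  if (ncol(g$codes) == 0L) stop("input error: empty marker subset")
  idx <- match(g$marker_ids, ft$marker_ids)
  if (anyNA(idx)) {
    stop("input error: markers absent from the frequency table: ",
         paste(utils::head(g$marker_ids[is.na(idx)], 5), collapse = ", "))
  }
  K <- length(ft$population_names)
  stopifnot(K >= 2)
  fk <- t(ft$f[idx, , drop = FALSE])          # K x L
  fk <- pmin(pmax(fk, 1e-6), 1 - 1e-6)
  n <- nrow(g$codes)
  L <- ncol(g$codes)
  if (max(apply(fk, 2, function(x) diff(range(x)))) < 1e-9) {
    warning("flat likelihood: frequencies identical across populations; ",
            "returning uniform ancestry proportions")
    q <- matrix(1 / K, n, K,
                dimnames = list(g$sample_ids, ft$population_names))
    attr(q, "flat") <- TRUE
    attr(q, "n_iter") <- 0L
    attr(q, "loglik") <- numeric(0)
    return(q)
  }
  gm <- g$codes
  storage.mode(gm) <- "double"
  miss <- is.na(gm)
  gm[miss] <- 0
  g2 <- 2 - gm
  g2[miss] <- 0
  lprime <- rowSums(!miss)
  if (any(lprime == 0)) {
    stop("input error: individual(s) with no non-missing genotypes: ",
         paste(utils::head(g$sample_ids[lprime == 0], 5), collapse = ", "))
  }
  q <- matrix(1 / K, n, K)
  fk1 <- 1 - fk
  loglik_of <- function(q) {
    p1 <- q %*% fk
    p2 <- q %*% fk1
    rowSums(gm * log(p1) + g2 * log(p2))
  }
  ll <- loglik_of(q)
  trace <- sum(ll)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p1 <- q %*% fk
    p2 <- q %*% fk1
    t1 <- (gm / p1) %*% t(fk)
    t2 <- (g2 / p2) %*% t(fk1)
    q <- q * (t1 + t2) / (2 * lprime)
    q <- q / rowSums(q)
    ll_new <- loglik_of(q)
    if (any(!is.finite(ll_new))) {
      stop("numerical error: non-finite likelihood during EM")
    }
    trace <- c(trace, sum(ll_new))
    gain <- max(ll_new - ll)
    ll <- ll_new
    if (gain < tol || iter >= max_iter) break
  }
  dimnames(q) <- list(g$sample_ids, ft$population_names)
  attr(q, "loglik") <- trace
  attr(q, "n_iter") <- iter
  attr(q, "flat") <- FALSE
  q
}

# Aligns an estimate to a truth matrix by row and column names when present.
align_q <- function(qhat, qtrue) {
  qhat <- as.matrix(qhat)
  qtrue <- as.matrix(qtrue)
  if (nrow(qhat) != nrow(qtrue) || ncol(qhat) != ncol(qtrue)) {
    stop("input error: ancestry matrices have mismatched shapes")
  }
  if (!is.null(rownames(qhat)) && !is.null(rownames(qtrue)) &&
      all(rownames(qtrue) %in% rownames(qhat))) {
    qhat <- qhat[rownames(qtrue), , drop = FALSE]
  }
  if (!is.null(colnames(qhat)) && !is.null(colnames(qtrue)) &&
      all(colnames(qtrue) %in% colnames(qhat))) {
    qhat <- qhat[, colnames(qtrue), drop = FALSE]
  }
  list(qhat = qhat, qtrue = qtrue)
}

#' Root mean square error of two-way ancestry estimates
#'
#' RMSE over individuals of one designated ancestry column:
#' sqrt( (1/n) * sum_i (qhat_i - q_i)^2 ). In two-way admixture the other
#' column is its complement, so a single column summarizes the error.
#'
#' @param qhat,qtrue n x 2 ancestry matrices (estimate and simulated
#'   truth); rows and columns are aligned by name when named.
#' @param ancestry_col which column to compare (name or index; default
#'   the second, the high-proportion ancestry under the default
#'   simulation).
#' @return A single non-negative number.
#' @export
rmse_two_way <- function(qhat, qtrue, ancestry_col = 2) {
  al <- align_q(qhat, qtrue)
  if (ncol(al$qtrue) != 2L) stop("input error: two-way RMSE requires K = 2")
  d <- al$qhat[, ancestry_col] - al$qtrue[, ancestry_col]
  sqrt(mean(d^2))
}

#' Root mean square error of multi-way ancestry estimates
#'
#' RMSE pooled over individuals and ancestries:
#' sqrt( (1/(nK)) * sum_i sum_k (qhat_ik - q_ik)^2 ).
#'
#' @param qhat,qtrue n x K ancestry matrices, aligned by name when named.
#' @return A single non-negative number.
#' @export
rmse_three_way <- function(qhat, qtrue) {
  al <- align_q(qhat, qtrue)
  sqrt(mean((al$qhat - al$qtrue)^2))
}
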