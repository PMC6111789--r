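#' Principal component analysis of genotypes (additive coding)
#'
#' Missing codes are imputed to the locus mean, loci are mean-centered
#' (additive 0/1/2 coding, no variance standardization by default) and
#' sample scores are taken from the leading eigenvectors of the sample
#' covariance. The sign convention fixes each component so its
#' largest-magnitude locus loading is positive.
#'
#' @param m a [diplo_matrix()].
#' @param n_components number of components (default 5).
#' @param scale. standardize loci to unit variance before the
#'   decomposition.
#' @return list with `scores` (samples x components), `var_explained`
#'   (percentages) and `loadings` (loci x components).
#' @export
pca_genotypes <- function(m, n_components = 5, scale. = FALSE) {
  stopifnot(inherits(m, "diplo_matrix"))
  X <- t(m$codes)                                  # samples x loci
  if (n_components > min(dim(X)))
    stop_param("n_components exceeds min(samples, loci)")
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  keep <- apply(X, 2, stats::var) > 0 | !scale.
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  k <- seq_len(n_components)
  scores <- pc$x[, k, drop = FALSE]
  loadings <- pc$rotation[, k, drop = FALSE]
  for (j in k) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  rownames(scores) <- rownames(X)
  list(scores = scores, var_explained = ve[k], loadings = loadings)
}

#' Evanno delta-K from admixture log-likelihood tables
#'
#' The second-order rate of change of the estimated log probability of the
#' data across successive K, normalized by the across-run standard
#' deviation:
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`.
#' Undefined at the smallest and largest K and wherever the run standard
#' deviation is zero.
#'
#' @param tbl data.frame with columns `K`, `run`, `logL` (>= 2 replicate
#'   runs per K, contiguous K range).
#' @return data.frame with `K`, `mean_logL`, `sd_logL`, `delta_k`,
#'   `defined`.
#' @export
evanno_delta_k <- function(tbl) {
  stopifnot(all(c("K", "run", "logL") %in% names(tbl)))
  Ks <- sort(unique(tbl$K))
  if (!identical(Ks, seq(min(Ks), max(Ks)))) {
    if (any(diff(Ks) != 1)) stop_param("K range must be contiguous")
  }
  runs_per_k <- tapply(tbl$run, tbl$K, length)
  if (any(runs_per_k < 2))
    stop_param("at least 2 replicate runs per K are required")
  mu <- tapply(tbl$logL, tbl$K, mean)[as.character(Ks)]
  sdv <- tapply(tbl$logL, tbl$K, stats::sd)[as.character(Ks)]
  n <- length(Ks)
  dk <- rep(NA_real_, n)
  defined <- rep(FALSE, n)
  for (i in seq(2, n - 1)) {
    if (sdv[i] > 0) {
      dk[i] <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1]) / sdv[i]
      defined[i] <- TRUE
    }
  }
  data.frame(K = Ks, mean_logL = as.numeric(mu), sd_logL = as.numeric(sdv),
             delta_k = dk, defined = defined)
}

#' Assign samples to clusters by ancestry-coefficient threshold
#'
#' A sample is assigned to the cluster whose ancestry proportion `q`
#' reaches the threshold (default 0.65); if several qualify (possible only
#' for thresholds at or below 0.5) the largest wins; otherwise the sample
#' is labeled admixed.
#'
#' @param q samples x clusters ancestry-proportion matrix (rows sum to 1).
#' @param threshold minimum q for assignment.
#' @return list with `assignments` (sample, cluster or "admixed", max_q)
#'   and `counts` (per cluster + admixed, with percentages).
#' @export
assign_clusters <- function(q, threshold = 0.65) {
  q <- as.matrix(q)
  if (any(q < 0 | q > 1)) stop_param("q values must lie in [0, 1]")
  if (any(abs(rowSums(q) - 1) > 1e-6))
    stop_param("q rows must sum to 1")
  if (threshold <= 0.5)
    warning("threshold <= 0.5: several clusters could qualify; the largest wins",
            call. = FALSE)
  if (is.null(colnames(q))) colnames(q) <- paste0("C", seq_len(ncol(q)))
  if (is.null(rownames(q))) rownames(q) <- paste0("S", seq_len(nrow(q)))
  best <- max.col(q, ties.method = "first")
  max_q <- q[cbind(seq_len(nrow(q)), best)]
  cluster <- ifelse(max_q >= threshold, colnames(q)[best], "admixed")
  assignments <- data.frame(sample = rownames(q), cluster = cluster,
                            max_q = max_q, stringsAsFactors = FALSE)
  lv <- c(colnames(q), "admixed")
  cnt <- table(factor(cluster, levels = lv))
  counts <- data.frame(cluster = lv, n = as.integer(cnt),
                       percent = round(100 * as.integer(cnt) / nrow(q), 1),
                       stringsAsFactors = FALSE)
  stopifnot(sum(counts$n) == nrow(q))
  list(assignments = assignments, counts = counts)
}
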