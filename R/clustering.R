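#' PCA of a genotype matrix
#'
#' Missing entries are imputed with the per-locus mean dosage, columns are
#' centered (optionally scaled), and principal axes are extracted. Axis
#' signs follow the convention that the largest-magnitude loading on each
#' axis is positive, so scores are fully deterministic.
#'
#' @param g a [genotype_matrix()] or a plain numeric matrix.
#' @param n_axes number of axes to return; truncated (with a warning) at
#'   the matrix rank.
#' @param scale scale columns to unit variance (default FALSE; monomorphic
#'   columns make scaling ill-defined)?
#' @return list with `scores` (individuals x axes), `loadings`,
#'   `explained` (proportion of variance per axis), `center`.
#' @export
genotype_pca <- function(g, n_axes = 10L, scale = FALSE) {
  mat <- if (inherits(g, "genotype_matrix")) g$genotypes else as.matrix(g)
  if (nrow(mat) < 2) stopf("need at least 2 individuals")
  storage.mode(mat) <- "double"
  if (anyNA(mat)) {
    mu <- colMeans(mat, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(mat), arr.ind = TRUE)
    mat[idx] <- mu[idx[, 2]]
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale)
  pos <- pc$sdev^2 > max(pc$sdev^2) * 1e-12
  rank <- sum(pos)
  if (n_axes > rank) {
    warnf("requested %d axes but rank is %d; truncating", n_axes, rank)
    n_axes <- rank
  }
  keep <- seq_len(n_axes)
  load <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  flip <- vapply(keep, function(j) {
    l <- load[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  rownames(scores) <- if (inherits(g, "genotype_matrix")) g$individual_ids else rownames(mat)
  list(scores = scores, loadings = load,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[keep],
       center = pc$center)
}

#' K-means scan with BIC model selection
#'
#' Runs k-means with multiple restarts for each candidate `k` and scores
#' models with `BIC(k) = n log(WSS/n) + k log(n)` (the spherical-cluster
#' form used for genetic cluster identification). The best `k` minimizes
#' BIC; ties break toward the smaller `k`. An empty cluster triggers a
#' logged restart with a derived seed.
#'
#' @param scores numeric matrix of PCA scores (individuals x axes).
#' @param k_min,k_max candidate range (`k_max` < number of individuals).
#' @param seed integer seed.
#' @param nstart random restarts per `k`.
#' @return list with `bic_by_k` (named numeric), `best_k`, and
#'   `assignments` (cluster labels at `best_k`).
#' @export
kmeans_bic_scan <- function(scores, k_min = 1L, k_max = 8L, seed, nstart = 20L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k_max >= n) stopf("k_max must be smaller than the number of individuals")
  ks <- seq.int(k_min, k_max)
  with_seed(seed, {
    bic <- stats::setNames(numeric(length(ks)), ks)
    assign_by_k <- vector("list", length(ks))
    for (i in seq_along(ks)) {
      k <- ks[i]
      if (k == 1L) {
        wss <- sum(scale(scores, scale = FALSE)^2)
        assign_by_k[[i]] <- rep(1L, n)
      } else {
        fit <- NULL
        for (attempt in 1:5) {
          fit <- tryCatch(stats::kmeans(scores, centers = k, nstart = nstart,
                                        iter.max = 50),
                          error = function(e) NULL)
          if (!is.null(fit) && length(unique(fit$cluster)) == k) break
          message(sprintf("kmeans_bic_scan: empty cluster at k=%d, restarting", k))
          set.seed(derive_seed(seed, k * 100L + attempt))
        }
        if (is.null(fit)) stopf("k-means failed to converge at k = %d", k)
        wss <- fit$tot.withinss
        assign_by_k[[i]] <- fit$cluster
      }
      bic[i] <- n * log(wss / n) + k * log(n)
    }
    best <- ks[which.min(bic)]  # which.min takes the first of ties -> smaller k
    list(bic_by_k = bic, best_k = best,
         assignments = assign_by_k[[match(best, ks)]])
  })
}

#' Discriminant analysis of principal components
#'
#' Fits a linear discriminant analysis on the first `n_pcs` retained PCA
#' axes, with cluster membership probabilities computed as the softmax of
#' negative one-half squared Mahalanobis distances to the cluster centroids
#' in discriminant space (where the pooled within-class covariance is
#' spherical, so Euclidean distance is Mahalanobis distance). The a-score
#' (mean over clusters of observed reassignment rate minus permuted-label
#' reassignment rate) quantifies discrimination beyond overfitting and can
#' drive the choice of `n_pcs` via [optimize_n_pcs()].
#'
#' @param scores PCA score matrix.
#' @param assignments cluster labels (>= 2 clusters).
#' @param n_pcs number of leading axes to retain.
#' @param compute_a_score compute the a-score (default TRUE)?
#' @param n_perm label permutations for the a-score null.
#' @param seed seed for the a-score permutations.
#' @return a `cluster_model`: `n_pcs_retained`, `k`, `assignments`,
#'   `membership_probabilities` (rows sum to 1), `a_score`, `lda`
#'   (the underlying fit), `centroids`.
#' @export
dapc_fit <- function(scores, assignments, n_pcs = ncol(scores),
                     compute_a_score = TRUE, n_perm = 10L, seed = 1L) {
  scores <- as.matrix(scores)
  assignments <- as.factor(assignments)
  if (nlevels(assignments) < 2) stopf("need at least 2 clusters")
  if (n_pcs > ncol(scores)) stopf("n_pcs exceeds the available axes")
  x <- scores[, seq_len(n_pcs), drop = FALSE]
  fit <- MASS::lda(x, grouping = assignments)
  ld <- as.matrix(x) %*% fit$scaling
  cent <- apply(ld, 2, function(col) tapply(col, assignments, mean))
  cent <- matrix(cent, nrow = nlevels(assignments),
                 dimnames = list(levels(assignments), colnames(ld)))
  memb <- membership_from_distances(ld, cent)
  a <- NA_real_
  if (compute_a_score) {
    reassign_rate <- function(labels) {
      f <- MASS::lda(x, grouping = labels)
      pred <- stats::predict(f, x)$class
      vapply(levels(labels), function(cl) {
        mean(pred[labels == cl] == cl)
      }, numeric(1))
    }
    obs <- reassign_rate(assignments)
    perm <- with_seed(seed, {
      replicate(n_perm, {
        reassign_rate(factor(sample(as.character(assignments)),
                             levels = levels(assignments)))
      })
    })
    a <- mean(obs - rowMeans(perm))
  }
  structure(
    list(n_pcs_retained = n_pcs, k = nlevels(assignments),
         assignments = assignments, membership_probabilities = memb,
         a_score = a, lda = fit, centroids = cent),
    class = "cluster_model"
  )
}

membership_from_distances <- function(ld, centroids) {
  d2 <- outer(rowSums(ld^2), rep(1, nrow(centroids))) -
    2 * ld %*% t(centroids) +
    outer(rep(1, nrow(ld)), rowSums(centroids^2))
  logw <- -0.5 * d2
  logw <- logw - apply(logw, 1, max)
  w <- exp(logw)
  memb <- w / rowSums(w)
  colnames(memb) <- rownames(centroids)
  memb
}

#' Choose the number of retained PCs by a-score
#'
#' Evaluates [dapc_fit()] over a grid of `n_pcs` values and returns the one
#' with the highest a-score.
#'
#' @inheritParams dapc_fit
#' @param grid candidate `n_pcs` values.
#' @return list with `best_n_pcs` and `a_scores`.
#' @export
optimize_n_pcs <- function(scores, assignments, grid = NULL, n_perm = 10L, seed = 1L) {
  grid <- grid %||% unique(pmin(ncol(scores), c(2, 5, 10, 20, 40)))
  a <- vapply(grid, function(np) {
    dapc_fit(scores, assignments, n_pcs = np, n_perm = n_perm, seed = seed)$a_score
  }, numeric(1))
  list(best_n_pcs = grid[which.max(a)], a_scores = stats::setNames(a, grid))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("DAPC model: k = %d clusters, %d PCs retained, a-score = %s\n",
              x$k, x$n_pcs_retained,
              ifelse(is.na(x$a_score), "not computed", sprintf("%.3f", x$a_score))))
  print(table(x$assignments))
  invisible(x)
}
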