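# Presence-only niche model algorithms. Each fit returns an object of
# class c("nm_<algorithm>", "niche_model") whose predict() method maps a
# climate-vector matrix to suitabilities in [0, 1].

#' Fit a presence-only niche model
#'
#' Algorithm contracts:
#' \describe{
#'   \item{bioclim}{per-variable percentile envelope: suitability is the
#'     minimum over variables of `2 min(F(x), 1 - F(x))`, with `F` the
#'     training ECDF (1 at the training median, 0 outside the range).}
#'   \item{domain}{Gower similarity to the closest training point:
#'     `max_t (1 - mean_v |x_v - t_v| / range_v)`, ranges from the training
#'     presences; clipped to `[0, 1]`. Zero-range variables are dropped
#'     with a warning.}
#'   \item{enfa}{ecological-niche factor analysis: marginality axis
#'     `m = (mean_presence - mean_background) / (1.96 sd_background)` plus
#'     specialization axes from the eigenstructure of the presence
#'     covariance orthogonal to `m`; suitability is the upper-tail
#'     percentile of the Mahalanobis distance to the presence centroid in
#'     factor space (centroid scores 1).}
#'   \item{maxent}{penalized presence/background discrimination with an
#'     exponential (logistic) model over linear + quadratic features
#'     (ridge-regularized), a functional stand-in for the reference maximum
#'     entropy implementation.}
#'   \item{ocsvm}{one-class support vector machine with radial kernel
#'     (`nu = 0.1`); decision values rescaled to `[0, 1]` by the training
#'     minimum/maximum and clipped.}
#' }
#'
#' @param presences matrix of training presence climate vectors (>= 5
#'   rows).
#' @param background matrix of background climate vectors (required by
#'   `enfa` and `maxent`).
#' @param algorithm one of `"bioclim"`, `"domain"`, `"enfa"`, `"maxent"`,
#'   `"ocsvm"`.
#' @param nu one-class SVM `nu` (default 0.1).
#' @param lambda ridge penalty for the maxent-like model (default 0.01).
#' @param seed seed for any stochastic fitting step.
#' @return a `niche_model`; use `predict(model, newdata)` for
#'   suitabilities.
#' @export
fit_niche_model <- function(presences, background = NULL,
                            algorithm = c("bioclim", "domain", "enfa",
                                          "maxent", "ocsvm"),
                            nu = 0.1, lambda = 0.01, seed = 1L) {
  algorithm <- match.arg(algorithm)
  presences <- as.matrix(presences)
  if (nrow(presences) < 5) stopf("need at least 5 training presences")
  if (algorithm %in% c("enfa", "maxent") && is.null(background)) {
    stopf("%s requires a background sample", algorithm)
  }
  model <- switch(
    algorithm,
    bioclim = list(train = presences),
    domain = {
      rng <- apply(presences, 2, function(v) diff(range(v)))
      if (any(rng == 0)) {
        warnf("domain: dropping zero-range variable(s): %s",
              paste(colnames(presences)[rng == 0], collapse = ", "))
      }
      list(train = presences[, rng > 0, drop = FALSE], range = rng[rng > 0])
    },
    enfa = fit_enfa(presences, as.matrix(background)),
    maxent = fit_maxent_like(presences, as.matrix(background), lambda, seed),
    ocsvm = fit_ocsvm(presences, nu, seed)
  )
  structure(c(model, list(algorithm = algorithm, variables = colnames(presences))),
            class = c(paste0("nm_", algorithm), "niche_model"))
}

fit_enfa <- function(pres, bg, ridge = 1e-8) {
  mu_bg <- colMeans(bg)
  sd_bg <- apply(bg, 2, stats::sd)
  if (any(sd_bg == 0)) stopf("enfa: background variable with zero variance")
  zp <- scale(pres, center = mu_bg, scale = sd_bg)
  m <- colMeans(zp) / 1.96
  p <- ncol(zp)
  if (sqrt(sum(m^2)) < 1e-12) {
    basis <- diag(p)
  } else {
    u1 <- m / sqrt(sum(m^2))
    # specialization: eigenvectors of presence covariance restricted to the
    # orthogonal complement of the marginality axis
    proj <- diag(p) - tcrossprod(u1)
    covp <- stats::cov(zp) + ridge * diag(p)
    eg <- eigen(proj %*% covp %*% proj, symmetric = TRUE)
    basis <- cbind(u1, eg$vectors[, seq_len(p - 1), drop = FALSE])
  }
  fp <- zp %*% basis
  centroid <- colMeans(fp)
  sds <- pmax(apply(fp, 2, stats::sd), 1e-8)
  d_train <- sqrt(colSums(((t(fp) - centroid) / sds)^2))
  list(mu_bg = mu_bg, sd_bg = sd_bg, marginality = m, basis = basis,
       centroid = centroid, factor_sd = sds, train_dist = d_train)
}

fit_maxent_like <- function(pres, bg, lambda, seed) {
  x <- rbind(pres, bg)
  feats <- cbind(x, x^2)
  colnames(feats) <- c(colnames(x), paste0(colnames(x), "_sq"))
  y <- c(rep(1, nrow(pres)), rep(0, nrow(bg)))
  fit <- with_seed(seed, {
    glmnet::glmnet(feats, y, family = "binomial", alpha = 0,
                   lambda = c(1, 0.1, lambda))
  })
  list(fit = fit, lambda = lambda)
}

fit_ocsvm <- function(pres, nu, seed) {
  # fit in the feature space as given (PCA axes already carry the climate
  # data's variance structure; re-standardizing by the training sd would
  # turn low-variance axes into high-precision location fingerprints)
  gamma <- 1 / (ncol(pres) * mean(apply(pres, 2, stats::var)))
  fit <- with_seed(seed, {
    e1071::svm(pres, type = "one-classification", kernel = "radial",
               nu = nu, gamma = gamma, scale = FALSE)
  })
  dv <- attr(stats::predict(fit, pres, decision.values = TRUE), "decision.values")
  list(fit = fit, dec_min = min(dv), dec_max = max(dv))
}

#' Predict suitability from a fitted niche model
#'
#' @param object a `niche_model`.
#' @param newdata matrix of climate vectors (same variables as training).
#' @param ... unused.
#' @return numeric vector of suitabilities in `[0, 1]`.
#' @export
predict.niche_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  switch(
    object$algorithm,
    bioclim = {
      s <- matrix(1, nrow(newdata), ncol(object$train))
      for (j in seq_len(ncol(object$train))) {
        Fj <- stats::ecdf(object$train[, j])(newdata[, j])
        s[, j] <- 2 * pmin(Fj, 1 - Fj)
      }
      apply(s, 1, min)
    },
    domain = {
      train <- object$train
      vars <- colnames(train)
      x <- newdata[, vars, drop = FALSE]
      best <- rep(-Inf, nrow(x))
      for (t in seq_len(nrow(train))) {
        scaled <- sweep(abs(sweep(x, 2, train[t, ], "-")), 2, object$range, "/")
        best <- pmax(best, 1 - rowMeans(scaled))
      }
      pmin(pmax(best, 0), 1)
    },
    enfa = {
      z <- scale(newdata, center = object$mu_bg, scale = object$sd_bg)
      fp <- z %*% object$basis
      d <- sqrt(colSums(((t(fp) - object$centroid) / object$factor_sd)^2))
      vapply(d, function(di) mean(object$train_dist >= di), numeric(1))
    },
    maxent = {
      feats <- cbind(newdata, newdata^2)
      as.numeric(stats::predict(object$fit, feats, s = object$lambda,
                                type = "response"))
    },
    ocsvm = {
      dv <- attr(stats::predict(object$fit, newdata, decision.values = TRUE),
                 "decision.values")
      pmin(pmax((as.numeric(dv) - object$dec_min) /
                  max(object$dec_max - object$dec_min, 1e-12), 0), 1)
    }
  )
}

#' Maximum sensitivity + specificity threshold
#'
#' Scans every candidate threshold (the unique presence and pseudo-absence
#' suitability values) and returns the one maximizing sensitivity plus
#' specificity (`sens(t) = mean(presence >= t)`,
#' `spec(t) = mean(absence < t)`); ties break toward the lower (more
#' inclusive) threshold.
#'
#' @param presence_scores suitability at presences (>= 1).
#' @param absence_scores suitability at pseudo-absences (>= 1).
#' @return the threshold, with the scan table as attribute `"scan"`.
#' @export
max_sss_threshold <- function(presence_scores, absence_scores) {
  stopifnot(length(presence_scores) >= 1, length(absence_scores) >= 1)
  cand <- sort(unique(c(presence_scores, absence_scores)))
  sens <- vapply(cand, function(t) mean(presence_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(absence_scores < t), numeric(1))
  ss <- sens + spec
  best <- cand[which.max(ss)]  # first maximum = lowest threshold
  attr(best, "scan") <- data.frame(threshold = cand, sensitivity = sens,
                                   specificity = spec)
  best
}

#' Evaluate a thresholded prediction with the D statistic
#'
#' `TPR` is the fraction of test presences at or above the threshold; `pi`
#' is the fraction of non-masked cells at or above it; `D = TPR (1 - pi)`
#' weights the true positive rate by the inverse of the proportional
#' predicted area, so a model that predicts everywhere scores 0.
#'
#' @param test_scores suitability at test presences (>= 1).
#' @param cell_scores suitability over all non-masked cells.
#' @param threshold suitability cutoff.
#' @return list with `tpr`, `predicted_area_fraction`, `d_stat`,
#'   `threshold`.
#' @export
evaluate_prediction <- function(test_scores, cell_scores, threshold) {
  if (length(test_scores) < 1) stopf("need at least 1 test presence")
  if (length(cell_scores) < 1) stopf("all cells are masked")
  tpr <- mean(test_scores >= threshold)
  pi_hat <- mean(cell_scores >= threshold)
  list(tpr = tpr, predicted_area_fraction = pi_hat,
       d_stat = tpr * (1 - pi_hat), threshold = threshold)
}

#' Committee consensus of binary maps
#'
#' @param maps list of binary (0/1 or logical) matrices on one grid.
#' @param votes_required votes needed for a consensus presence; default
#'   majority, `ceiling(A / 2)` of `A` maps.
#' @return logical consensus matrix.
#' @export
ensemble_consensus <- function(maps, votes_required = NULL) {
  stopifnot(length(maps) >= 1)
  dims <- vapply(maps, dim, integer(2))
  if (length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1) {
    stopf("maps disagree on grid size")
  }
  votes_required <- votes_required %||% ceiling(length(maps) / 2)
  votes <- Reduce(`+`, lapply(maps, function(m) {
    m2 <- m * 1
    m2[is.na(m2)] <- 0
    m2
  }))
  out <- votes >= votes_required
  out[is.na(maps[[1]])] <- NA
  out
}
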