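#' PCA reduction of a climate stack
#'
#' Standardizes each variable over the non-masked cells of the
#' current-climate stack (z-scores), drops constant layers with a warning,
#' and extracts `n_axes` principal axes. The loadings, centers and scales
#' are stored so past climates can be projected into the same axis space.
#'
#' @param current a [climate_stack()] of present-day variables.
#' @param n_axes number of axes to retain (default 5).
#' @return a `climate_pca`: `loadings`, `center`, `scale`, `explained`
#'   (non-increasing), `variables`, and `axes` (a [climate_stack()] of axis
#'   scores at the current time).
#' @export
climate_pca <- function(current, n_axes = 5L) {
  stopifnot(inherits(current, "climate_stack"))
  sm <- stack_matrix(current, keep_mask = TRUE)
  x <- sm$values
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping constant layer(s): %s", paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(x) < n_axes) stopf("only %d usable variables for %d axes", ncol(x), n_axes)
  ctr <- colMeans(x)
  z <- scale(x, center = ctr, scale = sds)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  keep <- seq_len(n_axes)
  load <- pc$rotation[, keep, drop = FALSE]
  flip <- vapply(keep, function(j) sign(load[which.max(abs(load[, j])), j]), numeric(1))
  load <- sweep(load, 2, flip, "*")
  scores <- z %*% load
  expl <- (pc$sdev^2 / sum(pc$sdev^2))[keep]
  axes <- scores_to_stack(scores, sm$mask, current$grid, current$time)
  structure(list(loadings = load, center = ctr, scale = sds,
                 explained = expl, variables = colnames(x), axes = axes),
            class = "climate_pca")
}

scores_to_stack <- function(scores, mask, grid, time) {
  vars <- lapply(seq_len(ncol(scores)), function(j) {
    m <- matrix(NA_real_, grid$nrows, grid$ncols)
    m[mask] <- scores[, j]
    m
  })
  names(vars) <- sprintf("axis%d", seq_len(ncol(scores)))
  climate_stack(vars, grid = grid, time = time)
}

#' Project an anchor climate onto fitted PCA axes
#'
#' Standardizes the anchor's variables with the *current* climate's centers
#' and scales (so axis scores are comparable across times) and applies the
#' fitted loadings. Masked cells stay masked.
#'
#' @param anchor a [climate_stack()] with the same variables and grid.
#' @param pca a `climate_pca` from [climate_pca()].
#' @return a [climate_stack()] of axis scores at the anchor's time.
#' @export
project_anchor <- function(anchor, pca) {
  stopifnot(inherits(anchor, "climate_stack"), inherits(pca, "climate_pca"))
  missing_vars <- setdiff(pca$variables, names(anchor$variables))
  if (length(missing_vars)) {
    stopf("anchor lacks variable(s): %s", paste(missing_vars, collapse = ", "))
  }
  sm <- stack_matrix(anchor, keep_mask = TRUE)
  x <- sm$values[, pca$variables, drop = FALSE]
  z <- scale(x, center = pca$center, scale = pca$scale)
  scores_to_stack(z %*% pca$loadings, sm$mask, anchor$grid, anchor$time)
}

#' Fit the per-cell forcing interpolation
#'
#' Ordinary least squares, per cell and per axis, of axis score on the
#' forcing value at the anchor times. With anchors that are exactly affine
#' in the forcing the fit is exact and hindcasts reproduce the anchors to
#' machine precision.
#'
#' @param axis_stacks list of axis [climate_stack()]s (>= 2, with distinct
#'   forcing values at their times).
#' @param forcing data.frame with `time_ky` (strictly increasing) and
#'   `d18o`.
#' @return a `forcing_model`: per-axis `intercept`/`slope` matrices,
#'   `forcing`, `grid`, `axis_names`, `anchor_times`.
#' @export
fit_forcing_interpolation <- function(axis_stacks, forcing) {
  if (length(axis_stacks) < 2) stopf("need >= 2 anchors with distinct forcing values")
  check_forcing(forcing)
  times <- vapply(axis_stacks, function(s) s$time, numeric(1))
  f <- forcing_at(forcing, times)
  if (length(unique(f)) < 2) stopf("need >= 2 anchors with distinct forcing values")
  grid <- axis_stacks[[1]]$grid
  axis_names <- names(axis_stacks[[1]]$variables)
  fc <- f - mean(f)
  ss <- sum(fc^2)
  intercept <- slope <- vector("list", length(axis_names))
  names(intercept) <- names(slope) <- axis_names
  for (ax in axis_names) {
    ys <- lapply(axis_stacks, function(s) s$variables[[ax]])
    ybar <- Reduce(`+`, ys) / length(ys)
    sl <- Reduce(`+`, Map(function(y, w) (y - ybar) * w, ys, fc)) / ss
    slope[[ax]] <- sl
    intercept[[ax]] <- ybar - sl * mean(f)
  }
  structure(list(intercept = intercept, slope = slope, forcing = forcing,
                 grid = grid, axis_names = axis_names, anchor_times = times),
            class = "forcing_model")
}

check_forcing <- function(forcing) {
  stopifnot(is.data.frame(forcing), all(c("time_ky", "d18o") %in% names(forcing)))
  if (any(diff(forcing$time_ky) <= 0)) stopf("forcing times must be strictly increasing")
  invisible(forcing)
}

forcing_at <- function(forcing, times) {
  rng <- range(forcing$time_ky)
  if (any(times < rng[1] | times > rng[2])) {
    stopf("time(s) outside the forcing domain [%g, %g]: %s", rng[1], rng[2],
          paste(times[times < rng[1] | times > rng[2]], collapse = ", "))
  }
  stats::approx(forcing$time_ky, forcing$d18o, xout = times)$y
}

#' Hindcast axis stacks over a time grid
#'
#' `axis(t) = intercept + slope * d18o(t)` per cell.
#'
#' @param model a `forcing_model`.
#' @param times ky BP values inside the forcing domain (default
#'   [default_time_grid()]).
#' @return list of axis [climate_stack()]s, one per time.
#' @export
hindcast_axes <- function(model, times = default_time_grid()) {
  stopifnot(inherits(model, "forcing_model"))
  f <- forcing_at(model$forcing, times)
  lapply(seq_along(times), function(i) {
    vars <- lapply(model$axis_names, function(ax) {
      model$intercept[[ax]] + model$slope[[ax]] * f[i]
    })
    names(vars) <- model$axis_names
    climate_stack(vars, grid = model$grid, time = times[i])
  })
}

#' Default hindcast time grid
#'
#' 1-ky steps from the present to 600 ky BP and 2-ky steps from 602 to
#' 786 ky BP: 601 + 93 = 694 time slices.
#'
#' @return numeric vector of times in ky BP.
#' @export
default_time_grid <- function() c(0:600, seq(602, 786, by = 2))

#' Split occurrences into training and testing sets
#'
#' Random split without replacement; the training set gets
#' `round(train_fraction * n)` points and the test set the remainder.
#'
#' @param occurrences data.frame of occurrence points (>= 4 rows).
#' @param train_fraction training share (default 0.7).
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_occurrences <- function(occurrences, train_fraction = 0.7, seed) {
  n <- nrow(occurrences)
  if (n < 4) stopf("need at least 4 occurrence points")
  n_train <- round(train_fraction * n)
  with_seed(seed, {
    idx <- sample.int(n, n_train)
    list(train = occurrences[idx, , drop = FALSE],
         test = occurrences[-idx, , drop = FALSE])
  })
}

#' Climate values at occurrence points
#'
#' @param stack a [climate_stack()].
#' @param points data.frame with `lon` and `lat`.
#' @return matrix (points x variables); errors if a point falls outside the
#'   grid or on a masked cell.
#' @export
extract_climate <- function(stack, points) {
  stopifnot(inherits(stack, "climate_stack"))
  idx <- cell_index(stack$grid, points$lon, points$lat)
  out <- vapply(stack$variables, function(m) m[idx], numeric(nrow(idx)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(idx))
  colnames(out) <- names(stack$variables)
  if (anyNA(out)) stopf("%d point(s) fall on masked cells", sum(rowSums(is.na(out)) > 0))
  out
}

#' Grid-cell de-duplication of occurrence points
#'
#' Keeps at most one point per grid cell (the first), emulating the
#' standardization used to avoid oversampling specific environmental
#' conditions.
#'
#' @param occurrences data.frame with `lon`, `lat`.
#' @param grid grid geometry (list with `nrows`, `ncols`, `xll`, `yll`,
#'   `cellsize`).
#' @return de-duplicated data.frame.
#' @export
dedupe_occurrences <- function(occurrences, grid) {
  idx <- cell_index(grid, occurrences$lon, occurrences$lat)
  keep <- !duplicated(paste(idx[, 1], idx[, 2]))
  occurrences[keep, , drop = FALSE]
}
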