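#' Run the full paleodistribution ensemble
#'
#' End-to-end engine: PCA reduction of the current climate, projection of
#' the anchor climates onto the same axes, per-cell ordinary least squares
#' of axis score on the d18O forcing, hindcasting over a dense time grid,
#' presence-only model fitting on a 70/30 occurrence split with a seeded
#' uniform background sample, max-sensitivity+specificity thresholding,
#' D-statistic evaluation at the present, and a committee consensus binary
#' map per time slice.
#'
#' @param current a [climate_stack()] of present-day climate variables.
#' @param anchors list of anchor [climate_stack()]s (same variables; their
#'   `time` fields place them on the forcing curve). Should include the
#'   present.
#' @param forcing data.frame with `time_ky`, `d18o`.
#' @param occurrences data.frame with `lon`, `lat` (grid-deduplicated
#'   internally).
#' @param n_axes PCA axes retained (default 5).
#' @param algorithms committee members (default all five).
#' @param time_grid hindcast times (default [default_time_grid()]).
#' @param background_n background sample size (default 10000, capped at
#'   the number of non-masked cells).
#' @param votes_required committee rule (default majority).
#' @param train_fraction training share of occurrences (default 0.7).
#' @param keep_maps keep per-time consensus matrices (default TRUE).
#' @param seed integer seed driving the split, background sample, and any
#'   stochastic fit.
#' @return an `ensemble_series`: `times`, `consensus` (list of logical
#'   matrices, if kept), `area_fraction` (consensus area per time),
#'   `area_by_algorithm` (times x algorithms), `evaluation` (per-algorithm
#'   threshold, TPR, pi, D at present), `pca`, `forcing_model`, `grid`,
#'   `votes_required`, `seed`.
#' @export
run_paleo_enm <- function(current, anchors, forcing, occurrences,
                          n_axes = 5L,
                          algorithms = c("bioclim", "domain", "enfa",
                                         "maxent", "ocsvm"),
                          time_grid = default_time_grid(),
                          background_n = 10000L, votes_required = NULL,
                          train_fraction = 0.7, keep_maps = TRUE, seed) {
  stopifnot(inherits(current, "climate_stack"))
  check_forcing(forcing)
  pca <- climate_pca(current, n_axes = n_axes)
  axis_anchors <- lapply(anchors, project_anchor, pca = pca)
  fmod <- fit_forcing_interpolation(axis_anchors, forcing)

  present_axes <- pca$axes
  cells <- stack_matrix(present_axes, keep_mask = TRUE)
  n_cells <- nrow(cells$values)
  bg_idx <- with_seed(derive_seed(seed, 1L), {
    if (background_n >= n_cells) seq_len(n_cells)
    else sample.int(n_cells, background_n)
  })
  background <- cells$values[bg_idx, , drop = FALSE]

  occurrences <- dedupe_occurrences(occurrences, current$grid)
  split <- split_occurrences(occurrences, train_fraction, seed = derive_seed(seed, 2L))
  train_x <- extract_climate(present_axes, split$train)
  test_x <- extract_climate(present_axes, split$test)

  models <- list(); thresholds <- numeric(0); eval_rows <- list()
  for (alg in algorithms) {
    alg_seed <- derive_seed(seed, 10L + match(alg, algorithms))
    m <- fit_niche_model(train_x, background, algorithm = alg, seed = alg_seed)
    # memory-based similarity models score their own training points
    # perfectly, which would drive the max-SSS threshold to the degenerate
    # top value; score training presences leave-one-out instead
    train_scores <- if (alg == "domain") {
      vapply(seq_len(nrow(train_x)), function(i) {
        mi <- fit_niche_model(train_x[-i, , drop = FALSE], background,
                              algorithm = alg, seed = alg_seed)
        stats::predict(mi, train_x[i, , drop = FALSE])
      }, numeric(1))
    } else {
      stats::predict(m, train_x)
    }
    thr <- max_sss_threshold(train_scores, stats::predict(m, background))
    ev <- evaluate_prediction(stats::predict(m, test_x),
                              stats::predict(m, cells$values), thr)
    models[[alg]] <- m
    thresholds[alg] <- as.numeric(thr)
    eval_rows[[alg]] <- data.frame(algorithm = alg, threshold = as.numeric(thr),
                                   tpr = ev$tpr,
                                   predicted_area_fraction = ev$predicted_area_fraction,
                                   d_stat = ev$d_stat)
  }
  evaluation <- do.call(rbind, eval_rows)

  stacks <- hindcast_axes(fmod, time_grid)
  n_t <- length(time_grid)
  area_alg <- matrix(NA_real_, n_t, length(algorithms),
                     dimnames = list(NULL, algorithms))
  area_cons <- numeric(n_t)
  consensus <- if (keep_maps) vector("list", n_t) else NULL
  votes_required <- votes_required %||% ceiling(length(algorithms) / 2)
  for (i in seq_len(n_t)) {
    vals <- stack_matrix(stacks[[i]])
    bin_maps <- lapply(algorithms, function(alg) {
      s <- stats::predict(models[[alg]], vals)
      m <- matrix(NA, current$grid$nrows, current$grid$ncols)
      m[cells$mask] <- s >= thresholds[alg]
      m
    })
    for (a in seq_along(algorithms)) {
      area_alg[i, a] <- mean(bin_maps[[a]][cells$mask])
    }
    cons <- ensemble_consensus(bin_maps, votes_required)
    area_cons[i] <- mean(cons[cells$mask])
    if (keep_maps) consensus[[i]] <- cons
  }
  structure(
    list(times = time_grid, consensus = consensus, area_fraction = area_cons,
         area_by_algorithm = area_alg, evaluation = evaluation,
         thresholds = thresholds, models = models, pca = pca,
         forcing_model = fmod, grid = current$grid, mask = cells$mask,
         split = split, votes_required = votes_required, seed = seed),
    class = "ensemble_series"
  )
}

#' @export
print.ensemble_series <- function(x, ...) {
  cat(sprintf("ensemble_series: %d time slices, %d algorithms, committee >= %d votes\n",
              length(x$times), ncol(x$area_by_algorithm), x$votes_required))
  print(x$evaluation, row.names = FALSE)
  invisible(x)
}

#' Marine-isotope-stage table
#'
#' @param stages data.frame with columns `name`, `start_ky`, `end_ky`,
#'   `type` (`"glacial"` or `"interglacial"`); stages must be
#'   non-overlapping and contiguous.
#' @return a validated `mis_table`.
#' @export
mis_table <- function(stages) {
  stopifnot(all(c("name", "start_ky", "end_ky", "type") %in% names(stages)))
  stages <- stages[order(stages$start_ky), , drop = FALSE]
  if (!all(stages$type %in% c("glacial", "interglacial"))) {
    stopf("stage type must be glacial or interglacial")
  }
  if (any(stages$end_ky <= stages$start_ky)) stopf("stages must have end > start")
  if (nrow(stages) > 1 &&
      any(abs(stages$start_ky[-1] - stages$end_ky[-nrow(stages)]) > 1e-9)) {
    stopf("stages must be contiguous and non-overlapping")
  }
  structure(stages, class = c("mis_table", "data.frame"))
}

#' Packaged marine isotope stage boundaries
#'
#' Reads the stage table shipped with the package (19 stages, 0-790 ky BP,
#' odd stages interglacial and even stages glacial, boundaries as commonly
#' tabulated from the benthic d18O stack). Supply your own table to
#' [mis_table()] to override.
#'
#' @return a `mis_table`.
#' @export
load_mis_table <- function() {
  path <- system.file("extdata", "mis_stages.csv", package = "skyisland")
  mis_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Derive glacial/interglacial stages from a forcing curve
#'
#' Splits the forcing domain into contiguous runs above (glacial) or below
#' (interglacial) a d18O threshold. The default threshold is the 30th
#' percentile of the curve: over the late Pleistocene, interglacial
#' (odd-numbered) stages occupy roughly the warmest third of time, while
#' most of each sawtooth cycle is spent in intermediate-to-full glacial
#' states.
#'
#' @param forcing data.frame with `time_ky`, `d18o`.
#' @param threshold d18O cut between states (default the 30th percentile).
#' @return a `mis_table`.
#' @export
classify_stages <- function(forcing, threshold = NULL) {
  check_forcing(forcing)
  threshold <- threshold %||% stats::quantile(forcing$d18o, 0.3)
  glac <- forcing$d18o >= threshold
  runs <- rle(glac)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  stages <- data.frame(
    name = sprintf("S%d", seq_along(runs$values)),
    start_ky = forcing$time_ky[starts],
    end_ky = c(forcing$time_ky[utils::head(ends, -1) + 1],
               forcing$time_ky[length(forcing$time_ky)] + 1e-9),
    type = ifelse(runs$values, "glacial", "interglacial")
  )
  mis_table(stages)
}

stage_type_of <- function(mis, times) {
  type <- character(length(times))
  for (i in seq_along(times)) {
    hit <- which(times[i] >= mis$start_ky & times[i] < mis$end_ky)
    if (!length(hit)) {
      # allow the final boundary itself
      hit <- which(abs(times[i] - mis$end_ky) < 1e-9)
      if (!length(hit)) stopf("time slice %g ky not covered by the stage table", times[i])
    }
    type[i] <- mis$type[hit[1]]
  }
  type
}

#' Glacial and interglacial composites of an ensemble series
#'
#' For each period type and cell, the frequency of predicted presence
#' across all time slices of that type, plus a binary composite at
#' `freq_threshold`.
#'
#' @param series an `ensemble_series` with kept consensus maps.
#' @param mis a `mis_table` covering the series' time grid.
#' @param freq_threshold presence-frequency cut for the binary composites
#'   (default 0.5).
#' @return list with `glacial`/`interglacial` (each `frequency` matrix and
#'   `binary` matrix), `mean_area` (mean consensus area fraction per
#'   type), and `n_slices` per type.
#' @export
mis_aggregate <- function(series, mis, freq_threshold = 0.5) {
  stopifnot(inherits(series, "ensemble_series"), inherits(mis, "mis_table"))
  if (is.null(series$consensus)) stopf("series was run with keep_maps = FALSE")
  type <- stage_type_of(mis, series$times)
  out <- list()
  for (ty in c("glacial", "interglacial")) {
    idx <- which(type == ty)
    if (!length(idx)) stopf("no time slices of type %s", ty)
    freq <- Reduce(`+`, lapply(series$consensus[idx], function(m) {
      m2 <- m * 1; m2[is.na(m2)] <- 0; m2
    })) / length(idx)
    freq[is.na(series$consensus[[1]])] <- NA
    out[[ty]] <- list(frequency = freq, binary = freq >= freq_threshold,
                      n_slices = length(idx))
  }
  out$mean_area <- c(glacial = mean(series$area_fraction[type == "glacial"]),
                     interglacial = mean(series$area_fraction[type == "interglacial"]))
  out$n_slices <- c(glacial = out$glacial$n_slices,
                    interglacial = out$interglacial$n_slices)
  out
}

#' Areas, overlap, and corridor connectivity of two binary range maps
#'
#' Areas are reported in cells and in square kilometres (cell width scaled
#' by the cosine of each row's latitude). The corridor flag is `TRUE` when
#' one 8-connected component of the union of suitable cells touches both
#' species' core ranges (each core = the largest component of that
#' species' own map).
#'
#' @param map_a,map_b binary/logical matrices on one grid.
#' @param grid grid geometry (list with `nrows`, `ncols`, `xll`, `yll`,
#'   `cellsize`).
#' @return list with `area_cells`, `area_km2`, `overlap_cells`,
#'   `overlap_km2`, `corridor`.
#' @export
range_metrics <- function(map_a, map_b, grid) {
  stopifnot(all(dim(map_a) == dim(map_b)))
  a <- !is.na(map_a) & map_a > 0
  b <- !is.na(map_b) & map_b > 0
  lat <- grid$yll + (grid$nrows - seq_len(grid$nrows) + 0.5) * grid$cellsize
  cell_km2 <- (grid$cellsize * 111.320 * cos(lat * pi / 180)) *
    (grid$cellsize * 110.574)
  km2 <- function(m) sum(rowSums(m) * cell_km2)
  res <- list(
    area_cells = c(a = sum(a), b = sum(b)),
    area_km2 = c(a = km2(a), b = km2(b)),
    overlap_cells = sum(a & b),
    overlap_km2 = km2(a & b),
    corridor = FALSE
  )
  if (!any(a) || !any(b)) return(res)
  comp_a <- label_components(a)
  comp_b <- label_components(b)
  core_a <- comp_a == which.max(tabulate(comp_a[a]))
  core_a[!a] <- FALSE
  core_b <- comp_b == which.max(tabulate(comp_b[b]))
  core_b[!b] <- FALSE
  u <- label_components(a | b)
  touching <- intersect(unique(u[core_a]), unique(u[core_b]))
  res$corridor <- length(touching) >= 1
  res
}

# 8-connected component labelling of a logical matrix (0 = background)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% nr) + 1L
      cl <- ((cur - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        idx <- (cc - 1L) * nr + rr
        if (mask[idx] && lab[idx] == 0L) {
          lab[idx] <- nxt
          queue <- c(queue, idx)
        }
      }
    }
  }
  lab
}
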