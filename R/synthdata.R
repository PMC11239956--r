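#' Simulate nested Balding-Nichols genotypes
#'
#' Draws a diploid biallelic genotype matrix under a two-level island model:
#' per-locus ancestral allele frequencies are Uniform(0.1, 0.9); group
#' frequencies are Beta-distributed around the ancestral frequency with
#' differentiation `fct_target`; population frequencies are Beta-distributed
#' around their group frequency with differentiation `fsc_target`; genotypes
#' are Binomial(2, p_pop). A target of 0 at either level passes the frequency
#' through unchanged. Missing entries are introduced completely at random.
#'
#' The Beta parameterisation is the Balding-Nichols one:
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and variance
#' `F p (1-p)`, so realized Weir-Cockerham F_ST converges to the target as
#' the number of loci grows.
#'
#' @param n_groups,pops_per_group,inds_per_pop,n_loci design counts (all
#'   >= 1).
#' @param fct_target between-group differentiation in `[0, 1)`.
#' @param fsc_target between-population-within-group differentiation in
#'   `[0, 1)`; `fct_target + fsc_target` must be < 1.
#' @param missing_rate per-entry missingness probability in `[0, 1)`.
#' @param seed integer; fully determines the output.
#' @return a [genotype_matrix()] with populations `g<i>p<j>` and groups
#'   `g<i>`.
#' @export
simulate_hierarchical_genotypes <- function(n_groups = 2L, pops_per_group = 3L,
                                            inds_per_pop = 20L, n_loci = 2000L,
                                            fct_target = 0.30, fsc_target = 0.02,
                                            missing_rate = 0, seed) {
  stopifnot(n_groups >= 1, pops_per_group >= 1, inds_per_pop >= 1, n_loci >= 1)
  if (fct_target < 0 || fct_target >= 1 || fsc_target < 0 || fsc_target >= 1 ||
      fct_target + fsc_target >= 1) {
    stopf("fct_target and fsc_target must lie in [0,1) with fct + fsc < 1")
  }
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  n_pops <- n_groups * pops_per_group
  n_ind <- n_pops * inds_per_pop
  pop_of_ind <- rep(seq_len(n_pops), each = inds_per_pop)
  grp_of_pop <- rep(seq_len(n_groups), each = pops_per_group)

  with_seed(seed, {
    p0 <- stats::runif(n_loci, 0.1, 0.9)
    rbn <- function(p, f) {
      # vectorized Balding-Nichols draw; f = 0 passes p through
      if (f == 0) return(p)
      stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
    }
    p_grp <- matrix(rbn(rep(p0, each = n_groups), fct_target), nrow = n_groups)
    p_pop <- matrix(rbn(p_grp[grp_of_pop, ], fsc_target), nrow = n_pops)
    # clamp away from exact 0/1 so downstream estimators stay defined
    p_pop <- pmin(pmax(p_pop, 1e-12), 1 - 1e-12)
    geno <- matrix(stats::rbinom(n_ind * n_loci, 2L, p_pop[pop_of_ind, ]),
                   nrow = n_ind)
    if (missing_rate > 0) {
      geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
    }
    genotype_matrix(
      geno,
      population = sprintf("g%dp%d", grp_of_pop[pop_of_ind],
                           ((pop_of_ind - 1L) %% pops_per_group) + 1L),
      group = sprintf("g%d", grp_of_pop[pop_of_ind]),
      individual_ids = sprintf("g%dp%d_i%02d", grp_of_pop[pop_of_ind],
                               ((pop_of_ind - 1L) %% pops_per_group) + 1L,
                               ((seq_len(n_ind) - 1L) %% inds_per_pop) + 1L)
    )
  })
}

#' Simulate a two-species barcode alignment
#'
#' Generates aligned mtDNA-like sequences for two species labels, `A` and
#' `B`. With `shared = TRUE` the generator emulates incomplete lineage
#' sorting at a barcode locus: a plurality of the individuals of *both*
#' species carry the identical ancestral haplotype, and the remainder carry
#' haplotypes a few substitutions away, so intra- and interspecific distance
#' ranges overlap and no barcode gap exists. With `shared = FALSE` species B
#' descends from a diverged ancestor (`divergence` substitutions away),
#' producing a clean barcode gap.
#'
#' @param n_a,n_b numbers of sequences per species.
#' @param seq_len alignment length (>= 100; default 658, the standard COI
#'   barcode length).
#' @param shared logical; share the modal haplotype across species?
#' @param divergence substitutions separating the species-B ancestor when
#'   `shared = FALSE`.
#' @param max_subs maximum per-individual substitutions away from its
#'   ancestor (default 6).
#' @param seed integer seed.
#' @return a [dna_alignment()] with species labels `"A"`/`"B"`.
#' @export
simulate_barcode_alignment <- function(n_a, n_b, seq_len = 658L, shared = TRUE,
                                       divergence = 40L, max_subs = 6L, seed) {
  stopifnot(n_a >= 1, n_b >= 1)
  if (seq_len < 100L) stopf("seq_len must be >= 100")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    anc <- sample(bases, seq_len, replace = TRUE)
    mutate <- function(s, k) {
      if (k == 0L) return(s)
      pos <- sample.int(length(s), k)
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
      s
    }
    anc_b <- if (shared) anc else mutate(anc, divergence)
    gen_species <- function(n, ancestor) {
      # guarantee the ancestral haplotype is the plurality haplotype
      n_keep <- ceiling(0.6 * n)
      k <- c(rep(0L, n_keep),
             if (n > n_keep) sample.int(max_subs, n - n_keep, replace = TRUE))
      lapply(k, function(ki) mutate(ancestor, ki))
    }
    seqs_a <- gen_species(n_a, anc)
    seqs_b <- gen_species(n_b, anc_b)
    mat <- do.call(rbind, c(seqs_a, seqs_b))
    dna_alignment(mat,
                  ids = c(sprintf("A_%02d", seq_len(n_a)),
                          sprintf("B_%02d", seq_len(n_b))),
                  species = rep(c("A", "B"), c(n_a, n_b)))
  })
}

#' Synthetic glacial-interglacial forcing curve
#'
#' A periodic benthic-d18O-like curve sampled at 1-ky steps over
#' `[0, t_max]`. The dominant cycle is a sawtooth, as in the late
#' Pleistocene benthic stack: slow build-up of ice over ~80% of each cycle
#' (rising d18O back in time from the modern interglacial) and a rapid
#' deglaciation, plus a weaker obliquity-paced harmonic. Glacial maxima sit
#' `amplitude` per-mil above the modern (t = 0) value of 3.2, with the
#' first maximum at 21 ky BP.
#'
#' @param period dominant cycle length in ky (default 100).
#' @param amplitude glacial-interglacial d18O range in per mil (default 1.8).
#' @param t_max last time in ky BP (default 790, so both a ~787-ky anchor and
#'   a 786-ky hindcast grid end fall inside the domain).
#' @return data.frame with columns `time_ky`, `d18o`.
#' @export
synthetic_forcing <- function(period = 100, amplitude = 1.8, t_max = 790) {
  t <- 0:t_max
  x <- t %% period
  rise <- 0.21 * period           # fast glaciation seen backwards from t = 0
  saw <- ifelse(x < rise, x / rise, (period - x) / (period - rise))
  s <- 0.85 * saw + 0.15 * (1 - cos(2 * pi * t / 41)) / 2
  data.frame(time_ky = t, d18o = 3.2 + amplitude * s)
}

#' Simulate a forcing-driven climate history with a known Gaussian niche
#'
#' Builds a synthetic montane world on a lon/lat grid. Terrain is a low
#' plain with a few Gaussian peaks, so terrain area grows as you descend
#' (hypsometry). Climate variables form two correlated families, like real
#' bioclim stacks: a temperature family following the elevation lapse rate
#' and cooling coherently with the d18O forcing, and a precipitation family
#' built from broad, mutually orthogonal sub-regional moisture gradients
#' with weak forcing slopes. Every variable at every time is *exactly
#' affine* in the forcing value, so downstream covariate interpolation must
#' reproduce anchor climates to machine precision.
#'
#' True suitability is the Gaussian-niche density of each cell's climate,
#' equal to 1 for a cell exactly at the niche optimum. By default the niche
#' is centered on the present-day climate of an upper-flank cell: the
#' species occupies highlands today, and glacial cooling moves the suitable
#' isotherm band downslope into larger terrain — the montane
#' expansion-contraction dynamic the generator emulates. Present-day
#' occurrences are sampled without replacement across cells with
#' probability proportional to present-day truth (at most one point per
#' cell, mirroring grid-level de-duplication).
#'
#' @param grid_rows,grid_cols grid size (>= 10 each; default 40 x 40).
#' @param n_vars number of climate variables (default 19, bioclim-like;
#'   roughly 11/19 of them temperature-family).
#' @param niche_center optional numeric vector (length `n_vars`) of niche
#'   optima in climate units; default: the present-day climate of the cell
#'   nearest to the 80th-percentile elevation.
#' @param niche_width positive vector of niche standard deviations; default
#'   5 degrees per temperature variable (a joint tolerance of ~1.5 degrees
#'   across the correlated family) and 4x the spatial sd for the
#'   precipitation family.
#' @param n_presences number of present-day occurrence points (default 78).
#' @param forcing_period,forcing_amplitude passed to [synthetic_forcing()].
#' @param anchor_times ky BP of the anchor climate layers; must include 0
#'   (default `c(0, 21, 130, 787)`: present, Last Glacial Maximum, Last
#'   Interglacial, Upper Pleistocene).
#' @param temp_sensitivity cooling of the temperature family per unit d18O
#'   (default 1.7 degC per per-mil, i.e. ~3 degC at a full glacial, the
#'   mainstream tropical last-glacial cooling estimate).
#' @param cellsize grid cell size in degrees (default 5 arc-minutes).
#' @param seed integer seed.
#' @return an object of class `climate_world` with elements `anchors` (list
#'   of [climate_stack()]), `forcing`, `truth` (per-anchor suitability
#'   matrices), `occurrences` (species/lon/lat data.frame), the underlying
#'   `base`/`slope` fields, the niche parameters, and the grid geometry.
#' @export
simulate_climate_history <- function(grid_rows = 40L, grid_cols = 40L,
                                     n_vars = 19L,
                                     niche_center = NULL, niche_width = NULL,
                                     n_presences = 78L,
                                     forcing_period = 100, forcing_amplitude = 1.8,
                                     anchor_times = c(0, 21, 130, 787),
                                     temp_sensitivity = 1.7,
                                     cellsize = 5 / 60, seed) {
  if (grid_rows < 10L || grid_cols < 10L) stopf("grid must be at least 10 x 10")
  if (n_presences < 10L) stopf("n_presences must be >= 10")
  if (anyDuplicated(anchor_times) || !0 %in% anchor_times) {
    stopf("anchor_times must be distinct and include 0")
  }
  forcing <- synthetic_forcing(forcing_period, forcing_amplitude)
  if (any(anchor_times < min(forcing$time_ky) | anchor_times > max(forcing$time_ky))) {
    stopf("anchor time outside the forcing domain [%g, %g]",
          min(forcing$time_ky), max(forcing$time_ky))
  }
  grid <- list(nrows = grid_rows, ncols = grid_cols,
               xll = -48, yll = -25, cellsize = cellsize, nodata = -9999)

  with_seed(seed, {
    rr <- matrix(seq_len(grid_rows), grid_rows, grid_cols)
    cc <- matrix(rep(seq_len(grid_cols), each = grid_rows), grid_rows, grid_cols)
    u <- (cc - 0.5) / grid_cols
    v <- (rr - 0.5) / grid_rows
    # sum of low-frequency sinusoids; cycles controls the spatial scale
    # (cycles < 1 gives a broad sub-regional gradient)
    smooth_field <- function(cycles = 1:3) {
      f <- matrix(0, grid_rows, grid_cols)
      for (h in 1:3) {
        fx <- stats::runif(1, min(cycles), max(cycles))
        fy <- stats::runif(1, min(cycles), max(cycles))
        f <- f + stats::rnorm(1, 0, 1) *
          sin(2 * pi * (fx * u + fy * v) + stats::runif(1, 0, 2 * pi))
      }
      f
    }
    # hypsometric elevation (km): one dominant conical massif -- on a cone
    # the area between two elevation contours grows quadratically as the
    # contours descend, so a cooling-driven descent of the suitable band
    # reliably gains terrain -- plus low satellite hills that are too warm
    # for the species today but become habitable under glacial cooling
    elev <- matrix(0.2, grid_rows, grid_cols)
    cone <- function(cu, cv, radius, height) {
      d <- sqrt((u - cu)^2 + (v - cv)^2)
      height * pmax(0, 1 - d / radius)
    }
    elev <- pmax(elev, 0.2 + cone(stats::runif(1, 0.45, 0.55),
                                  stats::runif(1, 0.45, 0.55),
                                  0.42, stats::runif(1, 2.4, 3.0)))
    for (k in 1:4) {
      elev <- pmax(elev, 0.2 + cone(stats::runif(1, 0.15, 0.85),
                                    stats::runif(1, 0.15, 0.85),
                                    0.15, stats::runif(1, 1.5, 2.1)))
    }

    d18o_0 <- forcing$d18o[forcing$time_ky == 0]
    base <- vector("list", n_vars)
    slope <- vector("list", n_vars)
    names(base) <- names(slope) <- sprintf("var%02d", seq_len(n_vars))
    # Variables form two correlated families, as real bioclim layers do:
    # a temperature family tied to the hypsometric elevation field and
    # cooling with the forcing, and a precipitation family sharing one
    # moisture field with small mixed-sign forcing slopes. Correlated
    # families are what lets a handful of PCA axes carry the climate
    # signal, mirroring real bioclim stacks.
    lapse <- -6.0 # degC per km
    n_temp <- max(1L, ceiling(n_vars * 11 / 19))
    relief <- (elev - min(elev)) / diff(range(elev))
    # Anomaly and moisture fields are residualized against elevation: over
    # a continental PCA domain, sub-regional moisture gradients and
    # lapse-rate residuals are uncorrelated with any one mountain system,
    # and this keeps the forcing-driven temperature shift confined to the
    # temperature principal axis on the small simulated grid too.
    ev <- as.vector(elev)
    basis <- list(ev - mean(ev))
    # Gram-Schmidt against elevation and every previously drawn factor, so
    # the factor fields are mutually uncorrelated over cells (as broad
    # climate gradients are over a continental PCA domain) and the
    # forcing-driven temperature shift stays confined to the temperature
    # principal axes
    orth <- function(f) {
      fv <- as.vector(f); fv <- fv - mean(fv)
      for (b in basis) fv <- fv - (sum(fv * b) / sum(b * b)) * b
      basis[[length(basis) + 1L]] <<- fv
      sdf <- stats::sd(fv)
      matrix(fv / ifelse(sdf > 0, sdf, 1), grid_rows, grid_cols)
    }
    # The climate space is spanned by a handful of broad shared factors,
    # as in real bioclim stacks (temperature/lapse, moisture, seasonality,
    # diurnal range): every variable is a mixture of its family's shared
    # factors, so all principal axes are smooth sub-regional gradients
    # rather than per-variable noise contrasts.
    wet <- orth(smooth_field(cycles = c(0.05, 0.25)))
    tfac1 <- orth(smooth_field(c(0.05, 0.25)))
    tfac2 <- orth(smooth_field(c(0.05, 0.25)))
    pfac1 <- orth(smooth_field(c(0.05, 0.25)))
    pfac2 <- orth(smooth_field(c(0.05, 0.25)))
    for (j in seq_len(n_vars)) {
      if (j <= n_temp) {
        a_j <- stats::runif(1, 0.8, 1.2)
        base[[j]] <- a_j * (24 + lapse * elev) +
          0.5 * (stats::rnorm(1) * tfac1 + stats::rnorm(1) * tfac2)
        # cooling is spatially near-coherent, with a mild relief modulation
        slope[[j]] <- -temp_sensitivity * a_j * (0.95 + 0.1 * relief)
      } else {
        b_j <- stats::runif(1, 0.8, 1.2)
        base[[j]] <- 50 + 10 * b_j * wet +
          3 * (stats::rnorm(1) * pfac1 + stats::rnorm(1) * pfac2)
        # precipitation responds weakly to the forcing, as a broad pattern
        slope[[j]] <- 0.1 * orth(smooth_field(c(0.05, 0.25)))
      }
      base[[j]] <- base[[j]] - slope[[j]] * d18o_0 # value(t) = base + slope*d18o(t)
    }

    field_at <- function(t) {
      fval <- stats::approx(forcing$time_ky, forcing$d18o, xout = t)$y
      stats::setNames(lapply(seq_len(n_vars), function(j) base[[j]] + slope[[j]] * fval),
                      names(base))
    }

    # niche: default center = present-day climate of an upper-flank cell
    # (the species occupies highlands today; glacial cooling then moves
    # the suitable band downslope into larger terrain, the montane
    # expansion-contraction dynamic the generator emulates)
    if (is.null(niche_center)) {
      ref_elev <- min(elev) + 0.7 * diff(range(elev))
      ref <- which.min(abs(elev - ref_elev))
      pres <- field_at(0)
      niche_center <- vapply(pres, function(m) m[ref], numeric(1))
    }
    if (is.null(niche_width)) {
      # temperature widths of 5 deg per variable give a joint (product)
      # niche of ~1.5 deg across the correlated family, broad enough that
      # present-day suitable habitat spans on the order of a hundred grid
      # cells; precipitation variables are weakly limiting
      niche_width <- vapply(seq_len(n_vars), function(j) {
        if (j <= n_temp) 5.0 else 4 * stats::sd(base[[j]])
      }, numeric(1))
    }
    stopifnot(length(niche_center) == n_vars, length(niche_width) == n_vars,
              all(niche_width > 0))

    # Gaussian-niche density, normalized so a cell exactly at the niche
    # center scores 1 (the density maximum); the scale is absolute across
    # times so range dynamics are comparable between slices
    truth_at <- function(t) {
      flds <- field_at(t)
      ll <- matrix(0, grid_rows, grid_cols)
      for (j in seq_len(n_vars)) {
        ll <- ll - 0.5 * ((flds[[j]] - niche_center[j]) / niche_width[j])^2
      }
      exp(ll)
    }

    anchors <- lapply(anchor_times, function(t) {
      climate_stack(field_at(t), grid = grid, time = t)
    })
    truth <- lapply(anchor_times, truth_at)
    names(anchors) <- names(truth) <- sprintf("t%g", anchor_times)

    tr0 <- truth_at(0)
    w <- as.vector(tr0)
    n_cells <- length(w)
    if (n_presences > n_cells) stopf("n_presences exceeds the number of grid cells")
    cells <- sample.int(n_cells, n_presences, replace = FALSE, prob = w)
    row_i <- ((cells - 1L) %% grid_rows) + 1L
    col_j <- ((cells - 1L) %/% grid_rows) + 1L
    occ <- data.frame(
      species = "synthetic",
      lon = grid$xll + (col_j - 0.5) * grid$cellsize,
      lat = grid$yll + (grid_rows - row_i + 0.5) * grid$cellsize
    )

    structure(
      list(grid = grid, elevation = elev, base = base, slope = slope,
           forcing = forcing, anchor_times = anchor_times, anchors = anchors,
           truth = truth, occurrences = occ,
           niche_center = niche_center, niche_width = niche_width,
           seed = seed),
      class = "climate_world"
    )
  })
}

#' True suitability of a synthetic world at an arbitrary time
#'
#' @param world a `climate_world` from [simulate_climate_history()].
#' @param time ky BP inside the forcing domain.
#' @return suitability matrix in `[0, 1]` (best cell = 1).
#' @export
truth_suitability <- function(world, time) {
  stopifnot(inherits(world, "climate_world"))
  fr <- world$forcing
  if (time < min(fr$time_ky) || time > max(fr$time_ky)) {
    stopf("time %g outside the forcing domain", time)
  }
  fval <- stats::approx(fr$time_ky, fr$d18o, xout = time)$y
  ll <- 0
  for (j in seq_along(world$base)) {
    fld <- world$base[[j]] + world$slope[[j]] * fval
    ll <- ll - 0.5 * ((fld - world$niche_center[j]) / world$niche_width[j])^2
  }
  exp(ll)
}

#' @export
print.climate_world <- function(x, ...) {
  cat(sprintf("climate_world: %d x %d grid, %d variables, %d anchors (%s ky BP)\n",
              x$grid$nrows, x$grid$ncols, length(x$base),
              length(x$anchor_times), paste(x$anchor_times, collapse = ", ")))
  cat(sprintf("  %d present-day occurrences; forcing 0-%g ky\n",
              nrow(x$occurrences), max(x$forcing$time_ky)))
  invisible(x)
}
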