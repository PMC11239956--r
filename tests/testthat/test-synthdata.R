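test_that("genotype generator is deterministic and respects its targets", {
  g1 <- simulate_hierarchical_genotypes(2, 2, 5, 50, 0.3, 0.02, 0.1, seed = 42)
  g2 <- simulate_hierarchical_genotypes(2, 2, 5, 50, 0.3, 0.02, 0.1, seed = 42)
  expect_identical(g1$genotypes, g2$genotypes)
  g3 <- simulate_hierarchical_genotypes(2, 2, 5, 50, 0.3, 0.02, 0.1, seed = 43)
  expect_false(identical(g1$genotypes, g3$genotypes))

  # no differentiation simulated -> Weir-Cockerham F_ST near 0
  fst0 <- vapply(1:5, function(s) {
    weir_fst(simulate_hierarchical_genotypes(1, 4, 15, 500, 0, 0, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(fst0)), 0.01)

  # fct = 0.35, two demes: recovery within +/- 0.05
  fst <- vapply(1:3, function(s) {
    weir_fst(simulate_hierarchical_genotypes(2, 1, 30, 2000, 0.35, 0, seed = s))
  }, numeric(1))
  expect_true(all(abs(fst - 0.35) < 0.05))
})

test_that("genotype generator validates its specification", {
  expect_error(simulate_hierarchical_genotypes(2, 1, 10, 100, 0.6, 0.5, seed = 1),
               "fct")
  expect_error(simulate_hierarchical_genotypes(2, 1, 10, 100, 0.3, 0.02,
                                               missing_rate = 1, seed = 1),
               "missing_rate")
})

test_that("barcode generator shares haplotypes across species when asked", {
  aln <- simulate_barcode_alignment(10, 20, 658, shared = TRUE, seed = 7)
  hap <- collapse_haplotypes(aln)
  both <- vapply(hap$species, function(s) all(c("A", "B") %in% s), logical(1))
  expect_true(any(both))
  # the shared haplotype is the plurality haplotype of each species
  shared_i <- which(both)[1]
  for (sp in c("A", "B")) {
    counts <- vapply(hap$species, function(s) sum(s == sp), integer(1))
    expect_equal(which.max(counts), shared_i)
  }

  # single individual per species, shared ancestor -> exactly one haplotype
  aln1 <- simulate_barcode_alignment(1, 1, 200, shared = TRUE, seed = 3)
  expect_equal(length(collapse_haplotypes(aln1)$frequency), 1L)

  # fixed seed -> identical sequences
  a <- simulate_barcode_alignment(5, 5, 300, seed = 11)
  b <- simulate_barcode_alignment(5, 5, 300, seed = 11)
  expect_identical(alignment_strings(a), alignment_strings(b))
})

test_that("diverged barcode simulation separates the species", {
  aln <- simulate_barcode_alignment(10, 10, 658, shared = FALSE, seed = 5)
  d <- k2p_matrix(aln)
  intra <- c(d[1:10, 1:10][upper.tri(diag(10))], d[11:20, 11:20][upper.tri(diag(10))])
  inter <- as.vector(d[1:10, 11:20])
  expect_gt(min(inter), max(intra))
})

test_that("climate world anchors are exactly affine in the forcing", {
  w <- simulate_climate_history(grid_rows = 12, grid_cols = 12, n_vars = 4,
                                n_presences = 15, seed = 9)
  for (k in seq_along(w$anchor_times)) {
    fval <- approx(w$forcing$time_ky, w$forcing$d18o, xout = w$anchor_times[k])$y
    for (j in seq_along(w$base)) {
      expect_equal(w$anchors[[k]]$variables[[j]],
                   w$base[[j]] + w$slope[[j]] * fval, tolerance = 1e-12)
    }
  }
  # truth normalization: the niche-center (reference) cell scores exactly 1
  expect_equal(max(truth_suitability(w, 0)), 1, tolerance = 1e-9)
  expect_true(all(truth_suitability(w, 100) <= 1 + 1e-12))
})

test_that("zero forcing amplitude freezes the climate", {
  w <- simulate_climate_history(grid_rows = 10, grid_cols = 10, n_vars = 3,
                                n_presences = 12, forcing_amplitude = 0, seed = 2)
  for (k in seq_along(w$anchors)[-1]) {
    expect_equal(w$anchors[[k]]$variables, w$anchors[[1]]$variables,
                 tolerance = 1e-12)
  }
})

test_that("occurrences oversample suitable habitat", {
  w <- simulate_climate_history(grid_rows = 20, grid_cols = 20, n_vars = 6,
                                n_presences = 40, seed = 4)
  tr <- truth_suitability(w, 0)
  idx <- skyisland:::cell_index(w$grid, w$occurrences$lon, w$occurrences$lat)
  expect_gt(mean(tr[idx]), mean(tr))
  # grid-deduplicated: one point per cell
  expect_false(any(duplicated(paste(idx[, 1], idx[, 2]))))
})

test_that("anchor times outside the forcing domain are rejected", {
  expect_error(simulate_climate_history(anchor_times = c(0, 900), seed = 1),
               "forcing domain")
})
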