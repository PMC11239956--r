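test_that("per-locus statistics match hand-evaluated formulas", {
  g <- make_genotypes(cbind(c(0L, 0L, 2L, 2L)), rep("p1", 4))
  st <- locus_statistics(g)
  expect_equal(st$p_hat, 0.5)
  expect_equal(st$ho, 0)
  expect_equal(st$he, 2 * 0.25 * 8 / 7)   # unbiased: 0.5714...
  expect_equal(st$pi, st$he)
  expect_equal(st$fis, 1)

  g2 <- make_genotypes(cbind(rep(1L, 6)), rep("p1", 6))
  st2 <- locus_statistics(g2)
  expect_equal(st2$ho, 1)
  expect_lt(st2$fis, 0)

  g3 <- make_genotypes(cbind(c(0L, 1L), c(NA_integer_, NA_integer_)),
                       rep("p1", 2))
  expect_warning(st3 <- locus_statistics(g3), "skipped")
  expect_equal(nrow(st3), 1L)
})

test_that("HWE exact test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(7, 0, 0), 1)
  expect_equal(hwe_exact_test(3, 4, 3), oracle_hwe(3, 4, 3))
  # every genotype table with n <= 8 individuals
  for (n in 2:8) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hwe_exact_test(nAA, nAa, naa), oracle_hwe(nAA, nAa, naa),
                   tolerance = 1e-12)
    }
  }
})

test_that("pairwise difference distances follow the stated rescaling", {
  m <- rbind(a = c(0L, 2L, 1L), b = c(2L, 2L, 0L))
  g <- make_genotypes(m, c("p1", "p2"))
  d <- pairwise_difference_matrix(g)
  expect_equal(d["a", "b"], 3)
  expect_equal(diag(d), c(a = 0, b = 0))

  m2 <- rbind(a = c(0L, 2L, 1L), b = c(2L, 2L, NA))
  d2 <- pairwise_difference_matrix(make_genotypes(m2, c("p1", "p2")))
  expect_equal(d2["a", "b"], 2 * 3 / 2)   # L / L_shared rescaling
  d3 <- pairwise_difference_matrix(make_genotypes(m2, c("p1", "p2")),
                                   rescale = FALSE)
  expect_equal(d3["a", "b"], 2)

  m4 <- rbind(a = c(0L, NA), b = c(NA, 2L))
  expect_error(pairwise_difference_matrix(make_genotypes(m4, c("p1", "p2"))),
               "share no genotyped loci")
})

test_that("AMOVA handles the degenerate textbook cases", {
  # two homozygous-distinct clones per population: all variation among pops
  m <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(2L, 2L, 2L), c(2L, 2L, 2L))
  g <- make_genotypes(m, c("p1", "p1", "p2", "p2"))
  res <- amova(g, "pops", n_permutations = 0)
  expect_equal(res$phi[["phi_st"]], 1)
  expect_equal(sum(res$percent_variation), 100, tolerance = 1e-9)

  # identical multisets across populations: no structure
  m2 <- rbind(c(0L, 2L), c(2L, 0L), c(0L, 2L), c(2L, 0L))
  g2 <- make_genotypes(m2, c("p1", "p1", "p2", "p2"))
  res2 <- amova(g2, "pops", n_permutations = 199, seed = 1)
  expect_lte(res2$variance_components[[1]], 0)
  expect_gt(res2$p_values[["phi_st"]], 0.05)

  # zero total variance -> explicit error
  m3 <- rbind(c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 1L))
  m3[] <- 0L
  g3 <- make_genotypes(m3, c("p1", "p1", "p2", "p2"))
  expect_error(amova(g3, "pops", n_permutations = 0), "variance")
})

test_that("AMOVA matches the definitional brute-force oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n_pop <- sample(2:4, 1)
    sizes <- sample(2:4, n_pop, replace = TRUE)
    n <- sum(sizes)
    L <- sample(5:20, 1)
    geno <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
    if (rep %% 3 == 0) geno[sample(length(geno), floor(0.1 * length(geno)))] <- NA
    pop <- rep(sprintf("p%d", seq_len(n_pop)), sizes)
    g <- make_genotypes(geno, pop)
    res <- try(amova(g, "pops", n_permutations = 0), silent = TRUE)
    orc <- try(oracle_amova(geno, pop), silent = TRUE)
    if (inherits(res, "try-error") || inherits(orc, "try-error")) next
    expect_equal(unname(res$variance_components), unname(orc$sigma2),
                 tolerance = 1e-10)
    expect_equal(unname(res$phi), unname(orc$phi), tolerance = 1e-10)

    if (n_pop >= 4) {
      grp <- ifelse(pop %in% c("p1", "p2"), "g1", "g2")
      g2 <- make_genotypes(geno, pop, grp)
      res2 <- amova(g2, "groups/pops", n_permutations = 0)
      orc2 <- oracle_amova(geno, pop, grp)
      expect_equal(unname(res2$variance_components), unname(orc2$sigma2),
                   tolerance = 1e-10)
      expect_equal(unname(res2$phi), unname(orc2$phi), tolerance = 1e-10)
      expect_equal(sum(res2$percent_variation), 100, tolerance = 1e-9)
    }
  }
})

test_that("pairwise Phi_ST agrees with the two-population AMOVA and algebra", {
  g <- simulate_hierarchical_genotypes(1, 3, 8, 120, 0, 0.1, seed = 5)
  fst <- pairwise_phi_st(g, n_permutations = 0)
  pops <- fst$populations
  sub <- subset_genotypes(g, which(g$population %in% pops[1:2]))
  sub$group <- NULL
  direct <- amova(sub, "pops", n_permutations = 0)$phi[["phi_st"]]
  expect_equal(fst$fst[pops[1], pops[2]], direct, tolerance = 1e-12)
  expect_equal(fst$linearized, ifelse(fst$fst < 1, fst$fst / (1 - fst$fst), Inf))
  expect_true(isSymmetric(fst$fst))
  expect_true(all(fst$fst_floored >= 0, na.rm = TRUE))

  # a duplicated population gives raw Phi <= 0, floored to 0
  m <- matrix(sample(0:2, 6 * 40, replace = TRUE), 6, 40)
  dup <- make_genotypes(rbind(m, m), rep(c("p1", "p2"), each = 6))
  fd <- pairwise_phi_st(dup, n_permutations = 0)
  expect_lte(fd$fst["p1", "p2"], 0)
  expect_equal(fd$fst_floored["p1", "p2"], 0)

  # Phi = 0.5 linearizes to 1
  expect_equal(0.5 / (1 - 0.5), 1)
})

test_that("permutation p-values are approximately uniform under the null", {
  pvals <- vapply(1:60, function(s) {
    g <- simulate_hierarchical_genotypes(1, 2, 6, 40, 0, 0, seed = 1000 + s)
    amova(g, "pops", n_permutations = 99, seed = s)$p_values[["phi_st"]]
  }, numeric(1))
  # permutation p-values are discrete, so silence the KS ties warning
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("the completeness filter keeps well-genotyped loci", {
  set.seed(3)
  geno <- matrix(sample(0:2, 12 * 10, replace = TRUE), 12, 10)
  geno[1:10, 1] <- NA            # locus 1 nearly absent
  g <- make_genotypes(geno, rep(c("p1", "p2", "p3"), each = 4))
  suppressMessages(f <- filter_loci(g, min_presence = 0.5, min_populations = 3))
  expect_false("locus00001" %in% colnames(f$genotypes))
  expect_equal(ncol(f$genotypes), 9L)
})
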