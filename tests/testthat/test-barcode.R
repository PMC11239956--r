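test_that("K2P distance matches its closed form and pairwise deletion", {
  # 10 bp with 2 transitions (A<->G) and 1 transversion (A<->T):
  a <- strsplit("AAAAACCCCC", "")[[1]]
  b <- strsplit("GGTAACCCCC", "")[[1]]
  expect_equal(k2p_distance(a, b),
               -0.5 * log(1 - 2 * 0.2 - 0.1) - 0.25 * log(1 - 2 * 0.1),
               tolerance = 1e-12)
  expect_lt(abs(k2p_distance(a, b) - 0.402360), 1e-6)

  expect_equal(k2p_distance("ACGT", "ACGT"), 0)

  # differences hidden behind N are deleted pairwise
  expect_equal(k2p_distance("ACGTACGTAC", "NNGTACGTAC"), 0)
  expect_error(k2p_distance("ANNN", "GNNN"), "saturation|comparable")
  expect_error(k2p_distance("NNNN", "ACGT"), "comparable")
  # saturated pair
  expect_error(k2p_distance("AAAAAAAAAA", "GGGGGGGGGG"), "saturation")
})

test_that("K2P matrix agrees with an independent implementation", {
  aln <- simulate_barcode_alignment(6, 6, 400, shared = FALSE, divergence = 25,
                                    seed = 31)
  d <- k2p_matrix(aln)
  bin <- ape::as.DNAbin(tolower(aln$seq))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(d), unname(ref[aln$ids, aln$ids]), tolerance = 1e-10)

  # K2P is never below the Jukes-Cantor correction of the same data
  p <- vapply(seq_len(nrow(d)), function(i) {
    mean(aln$seq[1, ] != aln$seq[i, ])
  }, numeric(1))
  jc <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(d[1, ] >= jc - 1e-12))
})

test_that("distance summaries reduce to brute-force pair means", {
  aln <- simulate_barcode_alignment(4, 5, 300, shared = TRUE, seed = 13)
  ds <- distance_summaries(aln)
  d <- ds$matrix
  ii <- which(aln$species == "A")
  intra_a <- mean(d[ii, ii][upper.tri(diag(length(ii)))])
  expect_equal(unname(ds$intra_mean["A"]), intra_a)
  inter <- mean(d[aln$species == "A", aln$species == "B"])
  expect_equal(ds$inter_mean, inter)
  expect_equal(ds$summary$percent, round(100 * ds$summary$distance, 2))

  ident <- dna_alignment(rep("ACGTACGTAC", 4), species = rep(c("x", "y"), 2))
  ds0 <- distance_summaries(ident)
  expect_equal(unname(ds0$intra_mean), c(0, 0))
  expect_equal(ds0$inter_mean, 0)

  one <- dna_alignment(c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGAAC"),
                       species = c("x", "x", "y"))
  expect_warning(dso <- distance_summaries(one), "single sequence")
  expect_true(is.na(dso$intra_mean[["y"]]))
})

test_that("barcode-gap partitioning splits gapped clouds and not continua", {
  # two clouds: intra <= 0.003, inter >= 0.05
  d <- matrix(0.055, 8, 8)
  d[1:4, 1:4] <- 0.002; d[5:8, 5:8] <- 0.003
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("s%d", 1:8)
  part <- barcode_gap_partition(d)
  expect_equal(length(unique(part$consensus)), 2L)
  expect_equal(length(unique(part$consensus[1:4])), 1L)

  # all distances small relative to the prior -> a single group
  d2 <- matrix(runif(25, 0, 0.003), 5, 5); d2 <- (d2 + t(d2)) / 2; diag(d2) <- 0
  p2 <- barcode_gap_partition(d2, priors = c(0.005, 0.01, 0.05))
  expect_true(all(p2$groups_by_prior == 1))

  # overlapping intra/inter ranges (shared haplotype world) -> one group
  aln <- simulate_barcode_alignment(10, 20, 658, shared = TRUE, seed = 17)
  po <- barcode_gap_partition(k2p_matrix(aln))
  expect_equal(length(unique(po$consensus)), 1L)
})

test_that("haplotype collapse conserves counts and species membership", {
  aln <- dna_alignment(c(rep("ACGTACGTAC", 5), "ACGTACGTAT"),
                       species = c("A", "A", "B", "B", "B", "A"))
  hap <- collapse_haplotypes(aln)
  expect_equal(length(hap$frequency), 2L)
  expect_equal(sum(hap$frequency), 6L)
  expect_setequal(hap$species[[1]], c("A", "B"))

  # property: frequencies always conserve the number of sequences
  for (s in 1:5) {
    a <- simulate_barcode_alignment(6, 7, 200, shared = (s %% 2 == 0), seed = s)
    expect_equal(sum(collapse_haplotypes(a)$frequency), 13L)
  }
})

test_that("the parsimony connection limit behaves like its estimator", {
  lim <- parsimony_connection_limit(658, 0.95)
  expect_gt(lim$limit, 0)
  # independent second coding of the same estimator
  for (j in c(1, 3, lim$limit, lim$limit + 1, 20)) {
    expect_equal(lim$table$prob[j], oracle_parsimony_prob(j, 658),
                 tolerance = 1e-9)
  }
  # monotonic: non-increasing in confidence
  lims <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(cf) {
    parsimony_connection_limit(658, cf)$limit
  }, integer(1))
  expect_true(all(diff(lims) <= 0))
  # degenerate bound: confidence -> 0+ admits the whole sequence length
  expect_equal(parsimony_connection_limit(120, 1e-300)$limit, 120L)
})

test_that("the parsimony network equals the tie-inclusive MST oracle", {
  # 3 haplotypes on a line, one step apart
  line <- rbind(strsplit("AAAA", "")[[1]],
                strsplit("AAAT", "")[[1]],
                strsplit("AATT", "")[[1]])
  net <- build_parsimony_network(line, limit = 5)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(sort(net$edges$steps), c(1L, 1L))
  expect_equal(length(unique(net$components)), 1L)

  # a pair beyond the limit stays disconnected
  far <- rbind(strsplit("AAAAAA", "")[[1]], strsplit("TTTTAA", "")[[1]])
  net2 <- build_parsimony_network(far, limit = 3)
  expect_equal(nrow(net2$edges), 0L)
  expect_equal(length(unique(net2$components)), 2L)

  # random instances against the definitional oracle
  set.seed(77)
  for (rep in 1:15) {
    H <- sample(4:7, 1)
    seqs <- matrix(sample(c("A", "C", "G", "T"), H * 12, replace = TRUE), H, 12)
    lim <- sample(3:8, 1)
    net <- build_parsimony_network(seqs, limit = lim)
    orc <- oracle_msn_edges(net$step_matrix, lim)
    got <- net$edges[order(net$edges$from, net$edges$to), ]
    want <- orc[order(orc$from, orc$to), ]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})
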