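#' Per-locus diversity statistics
#'
#' Computes, for every locus, the alternate-allele frequency, observed
#' heterozygosity, unbiased expected heterozygosity
#' `He = 2 p (1 - p) n / (n - 1)` (n = number of non-missing allele copies),
#' per-site nucleotide diversity (equal to unbiased He at a biallelic
#' variant site), the inbreeding coefficient `Fis = 1 - Ho / He`, and the
#' exact Hardy-Weinberg p-value. Monomorphic loci get `He = 0` and
#' `Fis = NA` (flagged, not an error); loci with no non-missing genotypes
#' are skipped with a warning.
#'
#' @param g a [genotype_matrix()].
#' @param by_population if `TRUE`, statistics are computed separately within
#'   each population and the result gains a `population` column.
#' @return data.frame with columns `locus_id` (+ `population`), `n_ind`,
#'   `p_hat`, `ho`, `he`, `pi`, `fis`, `hwe_p`.
#' @export
locus_statistics <- function(g, by_population = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  one_block <- function(mat, label = NULL) {
    n_ind <- colSums(!is.na(mat))
    skip <- n_ind == 0L
    if (any(skip)) {
      warnf("%d loci with no non-missing genotypes skipped%s", sum(skip),
            if (is.null(label)) "" else sprintf(" in population %s", label))
    }
    keep <- which(!skip)
    mat <- mat[, keep, drop = FALSE]
    n_ind <- n_ind[keep]
    n_all <- 2 * n_ind
    p <- colSums(mat, na.rm = TRUE) / n_all
    ho <- colSums(mat == 1L, na.rm = TRUE) / n_ind
    he <- ifelse(n_all > 1, 2 * p * (1 - p) * n_all / (n_all - 1), 0)
    fis <- ifelse(he > 0, 1 - ho / he, NA_real_)
    hwe <- vapply(seq_along(keep), function(j) {
      x <- mat[, j]
      hwe_exact_test(sum(x == 2L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                     sum(x == 0L, na.rm = TRUE))
    }, numeric(1))
    out <- data.frame(locus_id = colnames(mat), n_ind = n_ind, p_hat = p,
                      ho = ho, he = he, pi = he, fis = fis, hwe_p = hwe,
                      row.names = NULL)
    if (!is.null(label)) out <- cbind(population = label, out)
    out
  }
  if (!by_population) return(one_block(g$genotypes))
  do.call(rbind, lapply(unique(g$population), function(p) {
    one_block(g$genotypes[g$population == p, , drop = FALSE], label = p)
  }))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the observed allele counts: the p-value is the
#' sum, over all heterozygote counts compatible with the allele counts, of
#' the conditional probabilities that do not exceed the probability of the
#' observed configuration (the standard two-sided "sum of no-more-likely
#' tables" convention, without mid-p correction).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (here `A` is the alternate allele,
#'   so `n_AA` = dosage-2 homozygotes).
#' @return p-value in `(0, 1]`; monomorphic samples return 1.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  n_AA <- as.integer(n_AA); n_Aa <- as.integer(n_Aa); n_aa <- as.integer(n_aa)
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 2) stopf("need at least 2 genotyped individuals")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)
  hets <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  # log P(n_Aa = h | nA, n) up to a shared constant
  logp <- function(h) {
    nAAh <- (nA - h) / 2; naah <- (na - h) / 2
    h * log(2) - lgamma(nAAh + 1) - lgamma(h + 1) - lgamma(naah + 1)
  }
  lp <- vapply(hets, logp, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[hets == n_Aa]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Pairwise difference distance matrix between individuals
#'
#' `d(i, j)` is the summed absolute dosage difference over loci non-missing
#' in both individuals, rescaled by `L / L_shared` (L = total loci) so
#' distances remain comparable under missing data. The rescaling is
#' switchable off.
#'
#' @param g a [genotype_matrix()].
#' @param rescale rescale by `L / L_shared` (default TRUE)?
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_difference_matrix <- function(g, rescale = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  mat <- g$genotypes
  if (nrow(mat) < 2L) stopf("need at least 2 individuals")
  M <- (!is.na(mat)) * 1
  A <- mat; A[is.na(A)] <- 0L
  shared <- M %*% t(M)
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(upper.tri(shared) & shared == 0, arr.ind = TRUE)[1, ]
    stopf("individuals %s and %s share no genotyped loci",
          g$individual_ids[idx[1]], g$individual_ids[idx[2]])
  }
  I0 <- (mat == 0L & !is.na(mat)) * 1
  I2 <- (mat == 2L & !is.na(mat)) * 1
  eq <- I0 %*% t(I0) + ((mat == 1L & !is.na(mat)) * 1) %*% t((mat == 1L & !is.na(mat)) * 1) +
    I2 %*% t(I2)
  absdiff <- (shared - eq) + I0 %*% t(I2) + I2 %*% t(I0)
  d <- if (rescale) absdiff * ncol(mat) / shared else absdiff
  diag(d) <- 0
  dimnames(d) <- list(g$individual_ids, g$individual_ids)
  d
}

#' Multi-locus Weir-Cockerham F_ST
#'
#' Standard ratio-of-averages theta estimator over populations; used mainly
#' as an independent check that simulated differentiation hits its target.
#'
#' @param g a [genotype_matrix()].
#' @param by use `population` (default) or `group` labels as demes.
#' @return a single F_ST estimate.
#' @export
weir_fst <- function(g, by = c("population", "group")) {
  stopifnot(inherits(g, "genotype_matrix"))
  by <- match.arg(by)
  demes <- if (by == "population") g$population else {
    if (is.null(g$group)) stopf("no group labels present") else g$group
  }
  ids <- unique(demes)
  r <- length(ids)
  if (r < 2) stopf("need at least 2 demes")
  mat <- g$genotypes
  num <- 0; den <- 0
  ni <- vapply(ids, function(d) colSums(!is.na(mat[demes == d, , drop = FALSE])),
               numeric(ncol(mat)))          # loci x demes sample sizes
  pi_ <- vapply(ids, function(d) {
    m <- mat[demes == d, , drop = FALSE]
    colSums(m, na.rm = TRUE) / (2 * pmax(colSums(!is.na(m)), 1))
  }, numeric(ncol(mat)))
  hi <- vapply(ids, function(d) {
    m <- mat[demes == d, , drop = FALSE]
    colSums(m == 1L, na.rm = TRUE) / pmax(colSums(!is.na(m)), 1)
  }, numeric(ncol(mat)))
  ok <- rowSums(ni >= 1) == r
  ni <- ni[ok, , drop = FALSE]; pi_ <- pi_[ok, , drop = FALSE]; hi <- hi[ok, , drop = FALSE]
  nbar <- rowMeans(ni)
  nc <- (rowSums(ni) - rowSums(ni^2) / rowSums(ni)) / (r - 1)
  pbar <- rowSums(ni * pi_) / rowSums(ni)
  s2 <- rowSums(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(ni * hi) / rowSums(ni)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}
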