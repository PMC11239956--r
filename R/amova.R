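# Allele-level AMOVA.
#
# The decomposition treats the two allele copies of every diploid individual
# as the units, which puts the Phi statistics on the F-statistic scale
# (Phi_CT estimates the among-group fixation index directly). All stratum
# sums of squares are phase-free: the summed pairwise allele differences
# inside any set of individuals depend only on per-locus allele counts, so
# unphased dosage data are sufficient. For two individuals with dosages a, b
# at a locus the four inter-individual allele pairs contribute
# a(2-b) + b(2-a) differences, and the within-individual pair contributes
# a(2-a) (1 for a heterozygote, else 0).

# per-pair cross difference counts and within-individual counts,
# optionally rescaled by L / L_shared for missing data
allele_difference_counts <- function(g, rescale = TRUE) {
  mat <- g$genotypes
  L <- ncol(mat)
  M <- (!is.na(mat)) * 1
  A <- mat; A[is.na(A)] <- 0L
  storage.mode(A) <- "double"
  shared <- M %*% t(M)
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(upper.tri(shared) & shared == 0, arr.ind = TRUE)[1, ]
    stopf("individuals %s and %s share no genotyped loci",
          g$individual_ids[idx[1]], g$individual_ids[idx[2]])
  }
  sa <- A %*% t(M)             # sum of i's dosages over loci shared with j
  cross <- 2 * sa + 2 * t(sa) - 2 * A %*% t(A)
  if (rescale) cross <- cross * L / shared
  diag(cross) <- 0
  li <- rowSums(M)
  within <- rowSums(2 * A - A^2)
  if (rescale) within <- within * L / li
  list(cross = cross, within = within)
}

# SSD of strata defined by a factor, from precomputed difference counts;
# units are alleles (2 per individual)
strata_ssd <- function(counts, f) {
  f <- as.factor(f)
  bs <- rowsum(t(rowsum(counts$cross, f)), f)        # block sums (pairs double-counted)
  pair_sums <- diag(as.matrix(bs)) / 2
  wsum <- rowsum(counts$within, f)[, 1]
  nu <- 2 * as.vector(table(f))
  sum((pair_sums + wsum[levels(f)]) / nu)
}

amova_components_one <- function(counts, pop) {
  pop <- as.factor(pop)
  N2 <- 2 * length(pop)
  P <- nlevels(pop)
  ssd_total <- strata_ssd(counts, rep(1, length(pop)))
  ssd_wp <- strata_ssd(counts, pop)
  ssd_ap <- ssd_total - ssd_wp
  df_ap <- P - 1
  df_wp <- N2 - P
  cp <- 2 * as.vector(table(pop))
  n1 <- (N2 - sum(cp^2) / N2) / (P - 1)
  ms_wp <- ssd_wp / df_wp
  ms_ap <- ssd_ap / df_ap
  s2c <- ms_wp
  s2b <- (ms_ap - s2c) / n1
  list(ssd = c(among_populations = ssd_ap, within_populations = ssd_wp,
               total = ssd_total),
       df = c(among_populations = df_ap, within_populations = df_wp,
              total = N2 - 1),
       sigma2 = c(among_populations = s2b, within_populations = s2c))
}

amova_components_two <- function(counts, pop, grp) {
  pop <- as.factor(pop); grp_i <- as.factor(grp)
  N2 <- 2 * length(pop)
  P <- nlevels(pop); G <- nlevels(grp_i)
  ssd_total <- strata_ssd(counts, rep(1, length(pop)))
  ssd_wp <- strata_ssd(counts, pop)
  ssd_wg <- strata_ssd(counts, grp_i)
  ssd_ag <- ssd_total - ssd_wg
  ssd_ap <- ssd_wg - ssd_wp
  df_ag <- G - 1; df_ap <- P - G; df_wp <- N2 - P
  cp <- 2 * as.vector(table(pop))                    # allele copies per pop
  cg <- 2 * as.vector(table(grp_i))                  # allele copies per group
  grp_of_pop <- tapply(as.character(grp_i), pop, function(x) x[1])
  sum_cp2_over_cg <- sum(vapply(levels(grp_i), function(gg) {
    sum(cp[grp_of_pop == gg]^2) / (2 * sum(pop %in% levels(pop)[grp_of_pop == gg]))
  }, numeric(1)))
  n1 <- (N2 - sum_cp2_over_cg) / (P - G)
  n2 <- (sum_cp2_over_cg - sum(cp^2) / N2) / (G - 1)
  n3 <- (N2 - sum(cg^2) / N2) / (G - 1)
  ms_wp <- ssd_wp / df_wp
  ms_ap <- ssd_ap / df_ap
  ms_ag <- ssd_ag / df_ag
  s2c <- ms_wp
  s2b <- (ms_ap - s2c) / n1
  s2a <- (ms_ag - s2c - n2 * s2b) / n3
  list(ssd = c(among_groups = ssd_ag, among_populations_within_groups = ssd_ap,
               within_populations = ssd_wp, total = ssd_total),
       df = c(among_groups = df_ag, among_populations_within_groups = df_ap,
              within_populations = df_wp, total = N2 - 1),
       sigma2 = c(among_groups = s2a, among_populations_within_groups = s2b,
                  within_populations = s2c))
}

phi_from_components <- function(sigma2, truncate = FALSE) {
  s <- sigma2
  if (truncate) s <- pmax(s, 0)
  tot <- sum(s)
  if (tot == 0) stopf("total variance is 0; Phi statistics undefined")
  if (length(s) == 2) {
    c(phi_st = s[[1]] / tot)
  } else {
    c(phi_ct = s[[1]] / tot,
      phi_sc = s[[2]] / (s[[2]] + s[[3]]),
      phi_st = (s[[1]] + s[[2]]) / tot)
  }
}

#' Analysis of molecular variance (AMOVA) with Phi statistics
#'
#' Excoffier-style decomposition of allele-level squared pairwise
#' differences into hierarchical variance components, with unequal
#' sample-size coefficients, Phi statistics, and permutation p-values.
#' `hierarchy = "pops"` decomposes among/within populations;
#' `"groups/pops"` adds an among-group level (groups taken from the
#' genotype matrix). Negative variance components are retained as computed
#' (set `truncate_negative = TRUE` to floor them at zero before forming
#' Phi). Missing data are handled by rescaling each pair's difference count
#' by `L / L_shared` (switchable via `rescale`).
#'
#' Permutation schemes follow the hierarchical level of each statistic:
#' Phi_ST permutes individuals among populations; Phi_CT permutes whole
#' populations among groups; Phi_SC permutes individuals among populations
#' within groups. `p = (#{perm >= observed} + 1) / (n_permutations + 1)`.
#'
#' @param g a [genotype_matrix()]; two-level analyses require group labels.
#' @param hierarchy `"pops"` or `"groups/pops"`.
#' @param n_permutations permutation count (default 10000; 0 skips testing).
#' @param seed integer seed (required when permuting).
#' @param rescale rescale pair differences for missing data?
#' @param truncate_negative floor negative variance components at zero?
#' @return an `amova_result`: `table` (stratum, df, SSD, MS),
#'   `variance_components`, `percent_variation` (sums to 100), `phi`,
#'   `p_values`, `n_permutations`, `seed`.
#' @export
amova <- function(g, hierarchy = c("pops", "groups/pops"),
                  n_permutations = 10000L, seed = NULL,
                  rescale = TRUE, truncate_negative = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  hierarchy <- match.arg(hierarchy)
  pop <- g$population
  if (length(unique(pop)) < 2) stopf("need at least 2 populations")
  two_level <- hierarchy == "groups/pops"
  if (two_level) {
    if (is.null(g$group)) stopf("two-level AMOVA requires group labels")
    if (length(unique(g$group)) < 2) stopf("need at least 2 groups")
  }
  counts <- allele_difference_counts(g, rescale = rescale)

  comp <- if (two_level) amova_components_two(counts, pop, g$group)
          else amova_components_one(counts, pop)
  phi <- phi_from_components(comp$sigma2, truncate_negative)
  pct <- 100 * comp$sigma2 / sum(comp$sigma2)

  p_values <- NULL
  n_permutations <- as.integer(n_permutations)
  if (n_permutations > 0L) {
    if (is.null(seed)) stopf("permutation testing requires a seed")
    p_values <- with_seed(seed, {
      if (!two_level) {
        obs <- phi[["phi_st"]]
        cnt <- 0L
        for (b in seq_len(n_permutations)) {
          pp <- sample(pop)
          st <- phi_from_components(amova_components_one(counts, pp)$sigma2,
                                    truncate_negative)[["phi_st"]]
          if (st >= obs) cnt <- cnt + 1L
        }
        c(phi_st = (cnt + 1) / (n_permutations + 1))
      } else {
        pops <- unique(pop)
        grp_of_pop <- vapply(pops, function(p) g$group[match(p, pop)], character(1))
        cnt <- c(phi_ct = 0L, phi_sc = 0L, phi_st = 0L)
        for (b in seq_len(n_permutations)) {
          # Phi_CT: whole populations shuffled among groups
          gp <- sample(grp_of_pop)
          names(gp) <- pops
          ph <- phi_from_components(
            amova_components_two(counts, pop, gp[pop])$sigma2, truncate_negative)
          if (ph[["phi_ct"]] >= phi[["phi_ct"]]) cnt["phi_ct"] <- cnt["phi_ct"] + 1L
          # Phi_SC: individuals shuffled among populations within their group
          pp <- pop
          for (gg in unique(g$group)) {
            idx <- which(g$group == gg)
            pp[idx] <- sample(pop[idx])
          }
          ph <- phi_from_components(
            amova_components_two(counts, pp, g$group)$sigma2, truncate_negative)
          if (ph[["phi_sc"]] >= phi[["phi_sc"]]) cnt["phi_sc"] <- cnt["phi_sc"] + 1L
          # Phi_ST: individuals shuffled among populations across groups
          ord <- sample(length(pop))
          ph <- phi_from_components(
            amova_components_two(counts, pop[ord], g$group[ord])$sigma2,
            truncate_negative)
          if (ph[["phi_st"]] >= phi[["phi_st"]]) cnt["phi_st"] <- cnt["phi_st"] + 1L
        }
        (cnt + 1) / (n_permutations + 1)
      }
    })
  }

  strata <- names(comp$df)
  tab <- data.frame(stratum = strata, df = as.vector(comp$df),
                    SSD = as.vector(comp$ssd),
                    MS = as.vector(comp$ssd) / as.vector(comp$df),
                    row.names = NULL)
  structure(
    list(levels = if (two_level) 2L else 1L, table = tab,
         variance_components = comp$sigma2, percent_variation = pct,
         phi = phi, p_values = p_values,
         n_permutations = n_permutations, seed = seed),
    class = "amova_result"
  )
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA (%d-level, allele units)\n", x$levels))
  print(cbind(x$table,
              sigma2 = c(x$variance_components, NA),
              pct = c(round(x$percent_variation, 2), NA)), row.names = FALSE)
  for (nm in names(x$phi)) {
    p <- if (is.null(x$p_values)) NA else x$p_values[[nm]]
    cat(sprintf("  %s = %.4f  (perm p = %s)\n", nm, x$phi[[nm]],
                ifelse(is.na(p), "not tested", format(p, digits = 4))))
  }
  invisible(x)
}

#' Pairwise population Phi_ST (Slatkin F_ST) matrix
#'
#' For each pair of populations a one-level AMOVA restricted to the pair
#' gives the pairwise Phi_ST. Negative estimates are reported raw and also
#' floored at zero (matching the common display convention of printing 0
#' for negative pairwise F_ST), together with Slatkin's linearization
#' `F / (1 - F)` and permutation p-values.
#'
#' @inheritParams amova
#' @param alpha significance level for the `significant` flags.
#' @return an `fst_matrix`: `populations`, symmetric matrices `fst` (raw),
#'   `fst_floored`, `linearized`, `p_values`, `significant`, plus `alpha`.
#'   Populations with < 2 individuals are skipped with a warning (NA rows).
#' @export
pairwise_phi_st <- function(g, n_permutations = 10000L, seed = NULL,
                            alpha = 0.05, rescale = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- unique(g$population)
  if (length(pops) < 2) stopf("need at least 2 populations")
  sizes <- table(g$population)[pops]
  usable <- sizes >= 2
  if (any(!usable)) {
    warnf("populations with < 2 individuals skipped: %s",
          paste(pops[!usable], collapse = ", "))
  }
  P <- length(pops)
  fst <- pv <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  diag(fst) <- 0
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      if (!usable[i] || !usable[j]) next
      keep <- g$population %in% pops[c(i, j)]
      sub <- subset_genotypes(g, individuals = which(keep))
      sub$group <- NULL
      res <- amova(sub, hierarchy = "pops", n_permutations = n_permutations,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, i * P + j),
                   rescale = rescale)
      fst[i, j] <- fst[j, i] <- res$phi[["phi_st"]]
      if (!is.null(res$p_values)) pv[i, j] <- pv[j, i] <- res$p_values[["phi_st"]]
    }
  }
  floored <- pmax(fst, 0)
  lin <- ifelse(fst < 1, fst / (1 - fst), Inf)
  structure(
    list(populations = pops, fst = fst, fst_floored = floored,
         linearized = lin, p_values = pv,
         significant = !is.na(pv) & pv < alpha, alpha = alpha,
         n_permutations = as.integer(n_permutations), seed = seed),
    class = "fst_matrix"
  )
}

#' @export
print.fst_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise Phi_ST over %d populations (floored display; * = p < %.2g)\n",
              length(x$populations), x$alpha))
  disp <- matrix(sprintf("%.*f%s", digits, x$fst_floored,
                         ifelse(!is.na(x$significant) & x$significant, "*", "")),
                 nrow = nrow(x$fst), dimnames = dimnames(x$fst))
  diag(disp) <- "."
  print(disp, quote = FALSE)
  invisible(x)
}
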