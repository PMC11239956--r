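# Independent oracles, coded from definitions only. These deliberately use
# slow double loops and direct enumeration so they share no code path with
# the package implementations they check.

# --- allele-level AMOVA oracle -------------------------------------------
# Expands every diploid into two allele rows (phase chosen arbitrarily:
# alternate alleles first -- stratum-level sums of pairwise differences are
# phase-free) and computes SSDs from the definitional double sums.

oracle_allele_rows <- function(geno) {
  n <- nrow(geno); L <- ncol(geno)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) for (l in seq_len(L)) {
    g <- geno[i, l]
    if (!is.na(g)) {
      a1[i, l] <- as.integer(g >= 1)
      a2[i, l] <- as.integer(g >= 2)
    }
  }
  list(a1 = a1, a2 = a2)
}

# squared distance between two allele rows of individuals i and j, with the
# pair's L / L_shared rescaling driven by the individuals' missingness
oracle_pair_dist <- function(rows, i, j, ci, cj, L) {
  shared <- which(!is.na(rows$a1[i, ]) & !is.na(rows$a1[j, ]))
  x <- if (ci == 1) rows$a1[i, shared] else rows$a2[i, shared]
  y <- if (cj == 1) rows$a1[j, shared] else rows$a2[j, shared]
  sum(x != y) * L / length(shared)
}

oracle_ssd <- function(rows, idx, L) {
  # units are the 2*length(idx) allele copies of the individuals in idx
  units <- do.call(rbind, lapply(idx, function(i) rbind(c(i, 1L), c(i, 2L))))
  n_u <- nrow(units)
  total <- 0
  for (u in seq_len(n_u - 1)) for (v in (u + 1):n_u) {
    total <- total + oracle_pair_dist(rows, units[u, 1], units[v, 1],
                                      units[u, 2], units[v, 2], L)
  }
  total / n_u
}

oracle_amova <- function(geno, pop, grp = NULL) {
  rows <- oracle_allele_rows(geno)
  L <- ncol(geno)
  N2 <- 2 * nrow(geno)
  pops <- unique(pop)
  P <- length(pops)
  ssd_tot <- oracle_ssd(rows, seq_len(nrow(geno)), L)
  ssd_wp <- sum(vapply(pops, function(p) oracle_ssd(rows, which(pop == p), L),
                       numeric(1)))
  cp <- vapply(pops, function(p) 2 * sum(pop == p), numeric(1))
  if (is.null(grp)) {
    df <- c(P - 1, N2 - P)
    ssd <- c(ssd_tot - ssd_wp, ssd_wp)
    ms <- ssd / df
    # E[MS_among] = s2c + n' s2b ; E[MS_within] = s2c
    n1 <- (N2 - sum(cp^2) / N2) / (P - 1)
    cmat <- rbind(c(n1, 1), c(0, 1))
    sol <- solve(cmat, ms)
    s <- c(b = sol[1], c = sol[2])
    list(sigma2 = s, phi = c(phi_st = s[["b"]] / sum(s)),
         percent = 100 * s / sum(s))
  } else {
    grps <- unique(grp)
    G <- length(grps)
    ssd_wg <- sum(vapply(grps, function(g) oracle_ssd(rows, which(grp == g), L),
                         numeric(1)))
    ssd <- c(ssd_tot - ssd_wg, ssd_wg - ssd_wp, ssd_wp)
    df <- c(G - 1, P - G, N2 - P)
    ms <- ssd / df
    cg <- vapply(grps, function(g) 2 * sum(grp == g), numeric(1))
    grp_of_pop <- vapply(pops, function(p) grp[which(pop == p)[1]], grp[1])
    s_cp2_cg <- sum(vapply(grps, function(g) {
      sum(cp[grp_of_pop == g]^2) / cg[grps == g]
    }, numeric(1)))
    n1 <- (N2 - s_cp2_cg) / (P - G)
    n2 <- (s_cp2_cg - sum(cp^2) / N2) / (G - 1)
    n3 <- (N2 - sum(cg^2) / N2) / (G - 1)
    cmat <- rbind(c(n3, n2, 1),
                  c(0, n1, 1),
                  c(0, 0, 1))
    sol <- solve(cmat, ms)
    s <- c(a = sol[1], b = sol[2], c = sol[3])
    list(sigma2 = s,
         phi = c(phi_ct = s[["a"]] / sum(s),
                 phi_sc = s[["b"]] / (s[["b"]] + s[["c"]]),
                 phi_st = (s[["a"]] + s[["b"]]) / sum(s)),
         percent = 100 * s / sum(s))
  }
}

# --- exact HWE oracle ----------------------------------------------------
# Direct enumeration with plain factorials over all heterozygote counts
# compatible with the observed allele counts.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  pr <- vapply(hets, function(h) {
    nAAh <- (nA - h) / 2; naah <- (na - h) / 2
    factorial(n) / (factorial(nAAh) * factorial(h) * factorial(naah)) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  p_obs <- pr[hets == n_Aa]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# --- minimum-spanning-network oracle -------------------------------------
# An edge (u, v, w) belongs to the MSN iff w <= limit and u, v are in
# different connected components of the graph restricted to edges of
# weight < w.
oracle_msn_edges <- function(steps, limit) {
  H <- nrow(steps)
  connected_below <- function(w) {
    adj <- steps < w & !diag(TRUE, H)
    reach <- diag(TRUE, H)
    for (k in seq_len(H)) reach <- reach | (reach %*% adj) > 0
    reach
  }
  edges <- data.frame(from = integer(0), to = integer(0), steps = integer(0))
  for (u in seq_len(H - 1)) for (v in (u + 1):H) {
    w <- steps[u, v]
    if (w <= limit && !connected_below(w)[u, v]) {
      edges <- rbind(edges, data.frame(from = u, to = v, steps = w))
    }
  }
  edges
}

# --- second, independent coding of the parsimony probability -------------
# Same model, different numerics: lambda by uniroot, probability assembled
# from Poisson masses.
oracle_parsimony_prob <- function(j, m) {
  p <- min(j / m, 0.7499)
  lam <- stats::uniroot(function(l) 0.75 * (1 - exp(-4 * l / 3)) - p,
                        c(1e-12, 60), tol = 1e-14)$root
  p_diff <- 0.75 * (1 - exp(-4 * lam / 3))
  lp1 <- stats::dpois(1, lam, log = TRUE) - log(p_diff)
  lp0 <- stats::dpois(0, lam, log = TRUE) - log(1 - p_diff)
  exp(j * lp1 + (m - j) * lp0)
}

# --- adjusted Rand index -------------------------------------------------
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  nij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- a * b / n2
  (nij - exp_) / ((a + b) / 2 - exp_)
}

# small genotype fixture builder
make_genotypes <- function(mat, pop, grp = NULL) {
  genotype_matrix(mat, population = pop, group = grp)
}
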