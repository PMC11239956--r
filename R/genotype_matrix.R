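#' Diploid biallelic genotype matrix with population labels
#'
#' Container for a SNP genotype matrix coded as alternate-allele dosage
#' (0, 1, 2, or `NA` for missing), one row per individual and one column per
#' locus, together with the population of each individual and an optional
#' higher-level group label (e.g. species or mountain range). Groups, when
#' present, must be constant within a population.
#'
#' @param genotypes integer matrix (individuals x loci) with entries in
#'   `{0, 1, 2, NA}`.
#' @param population character/factor of population labels, one per
#'   individual.
#' @param group optional character/factor of group labels, one per
#'   individual; must be constant within each population.
#' @param individual_ids optional individual labels (default taken from
#'   rownames or generated).
#' @param locus_ids optional locus labels (default taken from colnames or
#'   generated).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, population, group = NULL,
                            individual_ids = NULL, locus_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) stopf("genotypes must be 0, 1, 2 or NA; found %d other entries", sum(bad))
  n <- nrow(genotypes)
  population <- as.character(population)
  if (length(population) != n) stopf("population labels (%d) do not match individuals (%d)", length(population), n)
  if (anyNA(population)) stopf("every individual needs a population label")
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != n) stopf("group labels (%d) do not match individuals (%d)", length(group), n)
    per_pop <- tapply(group, population, function(x) length(unique(x)))
    if (any(per_pop > 1L)) {
      stopf("group must be constant within a population; violated in: %s",
            paste(names(per_pop)[per_pop > 1L], collapse = ", "))
    }
  }
  individual_ids <- individual_ids %||% rownames(genotypes) %||% sprintf("ind%03d", seq_len(n))
  locus_ids <- locus_ids %||% colnames(genotypes) %||% sprintf("locus%05d", seq_len(ncol(genotypes)))
  if (anyDuplicated(individual_ids)) stopf("individual_ids must be unique")
  dimnames(genotypes) <- list(individual_ids, locus_ids)
  structure(
    list(genotypes = genotypes,
         individual_ids = as.character(individual_ids),
         population = population,
         group = group),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  populations: %d (%s)\n", length(unique(x$population)),
              paste(utils::head(unique(x$population), 8), collapse = ", ")))
  if (!is.null(x$group)) {
    cat(sprintf("  groups: %s\n", paste(unique(x$group), collapse = ", ")))
  }
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param g a [genotype_matrix()].
#' @param individuals logical/integer/character index of rows to keep.
#' @param loci logical/integer/character index of columns to keep.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(g, individuals = NULL, loci = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  ii <- individuals %||% seq_len(nrow(g$genotypes))
  if (is.character(ii)) ii <- match(ii, g$individual_ids)
  jj <- loci %||% seq_len(ncol(g$genotypes))
  genotype_matrix(g$genotypes[ii, jj, drop = FALSE],
                  population = g$population[ii],
                  group = if (is.null(g$group)) NULL else g$group[ii],
                  individual_ids = g$individual_ids[ii])
}

#' Locus completeness filter
#'
#' Keeps a locus when it is genotyped in at least `min_presence` of the
#' individuals of a population, in at least `min_populations` populations.
#' This reproduces the per-population completeness semantics of standard
#' RAD/GBS locus filters (e.g. a 50% within-population presence requirement
#' across at least six populations); both knobs are exposed and nothing is
#' hard-coded.
#'
#' @param g a [genotype_matrix()].
#' @param min_presence fraction in (0, 1]; minimum within-population
#'   genotyping rate for a locus to count as present in that population.
#' @param min_populations minimum number of populations in which the locus
#'   must be present.
#' @return a filtered `genotype_matrix`; the number of dropped loci is
#'   reported via `message()`.
#' @export
filter_loci <- function(g, min_presence = 0.5, min_populations = 6L) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- unique(g$population)
  min_populations <- min(as.integer(min_populations), length(pops))
  present <- vapply(pops, function(p) {
    rows <- g$population == p
    colMeans(!is.na(g$genotypes[rows, , drop = FALSE])) >= min_presence
  }, logical(ncol(g$genotypes)))
  keep <- rowSums(present) >= min_populations
  if (!any(keep)) stopf("completeness filter removed every locus")
  if (any(!keep)) message(sprintf("filter_loci: dropped %d of %d loci", sum(!keep), length(keep)))
  subset_genotypes(g, loci = which(keep))
}
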