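#' Run a multi-stage analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order
#' (`simulate` -> `popgen` -> `cluster` -> `barcode`), writing CSV/VCF/
#' FASTA outputs and a manifest to the output directory. Every output row
#' in the manifest records the stage, the file, and the seed that produced
#' it; a `run_info.txt` provenance record captures the full configuration.
#' Missing input paths abort before any stage runs; a stage failure aborts
#' the stages downstream of it.
#'
#' @param config a named list, or the path of a YAML file, with elements:
#'   \describe{
#'     \item{out_dir}{output directory (created if needed).}
#'     \item{stages}{character vector of stages to run.}
#'     \item{seed}{integer master seed.}
#'     \item{simulate}{optional list of arguments for
#'       [simulate_hierarchical_genotypes()] (`genotypes`) and
#'       [simulate_barcode_alignment()] (`barcodes`).}
#'     \item{genotypes_vcf,labels_csv,fasta}{input paths, when not
#'       simulating.}
#'     \item{popgen}{optional list: `n_permutations`, `min_presence`,
#'       `min_populations`.}
#'     \item{cluster}{optional list: `n_axes`, `k_min`, `k_max`, `n_pcs`.}
#'   }
#' @return data.frame manifest of written outputs (invisibly also written
#'   as `manifest.csv`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stopf("config needs out_dir")
  stages <- config$stages %||% c("simulate", "popgen", "cluster", "barcode")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # pre-flight: every required external input must exist
  if (!"simulate" %in% stages) {
    for (key in c("genotypes_vcf", "labels_csv")) {
      if (any(c("popgen", "cluster") %in% stages)) {
        p <- config[[key]]
        if (is.null(p) || !file.exists(p)) stopf("missing input: %s", key)
      }
    }
    if ("barcode" %in% stages) {
      p <- config$fasta
      if (is.null(p) || !file.exists(p)) stopf("missing input: fasta")
    }
  }

  manifest <- list()
  note <- function(stage, file, seed_used = NA) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = file, seed = seed_used)
  }
  log_info <- function(stage, fmt, ...) {
    message(sprintf(paste0("stage=", stage, " ", fmt), ...))
  }

  g <- NULL; aln <- NULL
  if ("simulate" %in% stages) {
    sim <- config$simulate %||% list()
    ga <- sim$genotypes %||% list()
    ga$seed <- ga$seed %||% seed
    g <- do.call(simulate_hierarchical_genotypes, ga)
    vcf_path <- file.path(out_dir, "genotypes.vcf")
    write_vcf(g, vcf_path); note("simulate", vcf_path, ga$seed)
    lab_path <- file.path(out_dir, "labels.csv")
    write_labels(g, lab_path); note("simulate", lab_path, ga$seed)
    ba <- sim$barcodes %||% list(n_a = 10, n_b = 20)
    ba$seed <- ba$seed %||% derive_seed(seed, 3L)
    aln <- do.call(simulate_barcode_alignment, ba)
    fas_path <- file.path(out_dir, "barcodes.fasta")
    write_fasta(aln, fas_path); note("simulate", fas_path, ba$seed)
    log_info("simulate", "simulate wrote genotypes + barcodes seed=%d", seed)
  }

  if (any(c("popgen", "cluster") %in% stages) && is.null(g)) {
    g <- read_vcf(config$genotypes_vcf, labels = config$labels_csv)
  }

  if ("popgen" %in% stages) {
    pg <- config$popgen %||% list()
    stats_df <- locus_statistics(g)
    p1 <- file.path(out_dir, "locus_stats.csv")
    utils::write.csv(stats_df, p1, row.names = FALSE); note("popgen", p1)
    hier <- if (!is.null(g$group) && length(unique(g$group)) > 1) "groups/pops" else "pops"
    am <- amova(g, hierarchy = hier,
                n_permutations = pg$n_permutations %||% 100L,
                seed = derive_seed(seed, 11L))
    p2 <- file.path(out_dir, "amova.csv")
    utils::write.csv(
      data.frame(stratum = c(names(am$variance_components), "phi"),
                 sigma2 = c(am$variance_components, NA),
                 percent = c(am$percent_variation, NA),
                 phi = c(rep(NA, length(am$variance_components)),
                         paste(sprintf("%s=%.4f", names(am$phi), am$phi),
                               collapse = ";"))),
      p2, row.names = FALSE)
    note("popgen", p2, derive_seed(seed, 11L))
    fst <- pairwise_phi_st(g, n_permutations = pg$n_permutations %||% 100L,
                           seed = derive_seed(seed, 12L))
    p3 <- file.path(out_dir, "fst_matrix.csv")
    utils::write.csv(fst$fst_floored, p3); note("popgen", p3, derive_seed(seed, 12L))
  }

  if ("cluster" %in% stages) {
    cl <- config$cluster %||% list()
    pca <- genotype_pca(g, n_axes = cl$n_axes %||%
                          min(40L, nrow(g$genotypes) - 1L))
    scan <- kmeans_bic_scan(pca$scores, k_min = cl$k_min %||% 1L,
                            k_max = cl$k_max %||% min(8L, nrow(pca$scores) - 1L),
                            seed = derive_seed(seed, 21L))
    p1 <- file.path(out_dir, "bic_by_k.csv")
    utils::write.csv(data.frame(k = names(scan$bic_by_k), bic = scan$bic_by_k),
                     p1, row.names = FALSE)
    note("cluster", p1, derive_seed(seed, 21L))
    if (scan$best_k >= 2) {
      dap <- dapc_fit(pca$scores, scan$assignments,
                      n_pcs = cl$n_pcs %||% min(10L, ncol(pca$scores)),
                      seed = derive_seed(seed, 22L))
      p2 <- file.path(out_dir, "membership.csv")
      utils::write.csv(dap$membership_probabilities, p2); note("cluster", p2)
    }
    p3 <- file.path(out_dir, "assignments.csv")
    utils::write.csv(data.frame(individual = g$individual_ids,
                                cluster = scan$assignments),
                     p3, row.names = FALSE)
    note("cluster", p3)
  }

  if ("barcode" %in% stages) {
    if (is.null(aln)) aln <- read_fasta(config$fasta, labels = config$fasta_labels)
    d <- k2p_matrix(aln)
    p1 <- file.path(out_dir, "k2p_matrix.csv")
    utils::write.csv(d, p1); note("barcode", p1)
    part <- barcode_gap_partition(d)
    p2 <- file.path(out_dir, "partition.csv")
    utils::write.csv(data.frame(id = names(part$consensus), group = part$consensus),
                     p2, row.names = FALSE)
    note("barcode", p2)
    hap <- collapse_haplotypes(aln)
    net <- build_parsimony_network(hap)
    p3 <- file.path(out_dir, "network_edges.csv")
    utils::write.csv(net$edges, p3, row.names = FALSE); note("barcode", p3)
  }

  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  info <- c(sprintf("skyisland %s", as.character(utils::packageVersion("skyisland"))),
            sprintf("date: %s", format(Sys.time())),
            sprintf("seed: %d", seed),
            sprintf("stages: %s", paste(stages, collapse = ",")),
            utils::capture.output(utils::str(config)))
  writeLines(info, file.path(out_dir, "run_info.txt"))
  invisible(manifest)
}
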