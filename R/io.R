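#' Read a VCF into a genotype matrix
#'
#' Parses biallelic SNP records from a VCF 4.x file (via \pkg{vcfR}) into
#' alternate-allele dosages. Multiallelic records are skipped with their
#' count logged; `./.` (or `.|.`/`.`) becomes missing. Locus ids are
#' `CHROM:POS`.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param labels optional data.frame (or CSV path) with columns
#'   `individual`, `population`, and optionally `group`; when absent every
#'   sample is placed in population `"pop1"`.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, labels = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2 || !grepl("GT", vcf@gt[1, "FORMAT"])) {
    stopf("VCF has no GT field")
  }
  alt <- vcf@fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    message(sprintf("read_vcf: skipped %d multiallelic record(s)", sum(multi)))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  chrom <- vcf@fix[keep, "CHROM"]
  pos <- vcf@fix[keep, "POS"]
  dosage <- function(x) {
    x <- sub(":.*", "", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 2L
    out
  }
  geno <- t(matrix(dosage(as.vector(gt)), nrow = nrow(gt)))  # individuals x loci
  rownames(geno) <- colnames(gt)
  colnames(geno) <- paste0(chrom, ":", pos)
  ids <- rownames(geno)
  if (is.null(labels)) {
    pop <- rep("pop1", length(ids)); grp <- NULL
  } else {
    if (is.character(labels)) labels <- utils::read.csv(labels, stringsAsFactors = FALSE)
    m <- match(ids, labels$individual)
    if (anyNA(m)) stopf("labels missing for: %s", paste(ids[is.na(m)], collapse = ", "))
    pop <- labels$population[m]
    grp <- if ("group" %in% names(labels)) labels$group[m] else NULL
  }
  genotype_matrix(geno, population = pop, group = grp, individual_ids = ids)
}

#' Write a genotype matrix as a minimal VCF
#'
#' @param g a [genotype_matrix()].
#' @param path output path (plain-text VCF 4.2).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  loci <- colnames(g$genotypes)
  has_pos <- grepl(":", loci)
  chrom <- ifelse(has_pos, sub(":.*", "", loci), "chr1")
  pos <- ifelse(has_pos, sub(".*:", "", loci), as.character(seq_along(loci)))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_along(loci), function(j) {
    gts <- g$genotypes[, j]
    cells <- ifelse(is.na(gts), "./.", gt_code[as.character(gts)])
    paste(c(chrom[j], pos[j], loci[j], "A", "T", ".", "PASS", ".", "GT", cells),
          collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$individual_ids), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write sample labels as CSV
#'
#' @param g a [genotype_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(g, path) {
  df <- data.frame(individual = g$individual_ids, population = g$population)
  if (!is.null(g$group)) df$group <- g$group
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Records must be equal length; sequences are uppercased and validated
#' against the IUPAC alphabet. Species labels come from a labels CSV
#' (`id`, `species`), or from FASTA headers split at `delimiter` (last
#' field), or are left `NULL`.
#'
#' @param path FASTA path.
#' @param labels optional data.frame or CSV path with `id` and `species`.
#' @param delimiter optional header delimiter for embedded species labels
#'   (e.g. `"|"` for `">seq1|speciesA"`).
#' @return a [dna_alignment()].
#' @export
read_fasta <- function(path, labels = NULL, delimiter = NULL) {
  recs <- ape::read.FASTA(path)
  chars <- lapply(as.character(recs), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1) {
    off <- names(recs)[lens != stats::median(lens)]
    stopf("ragged alignment in %s: %s", path, paste(off, collapse = ", "))
  }
  ids <- names(recs)
  species <- NULL
  if (!is.null(labels)) {
    if (is.character(labels)) labels <- utils::read.csv(labels, stringsAsFactors = FALSE)
    m <- match(ids, labels$id)
    if (anyNA(m)) stopf("species labels missing for: %s", paste(ids[is.na(m)], collapse = ", "))
    species <- labels$species[m]
  } else if (!is.null(delimiter)) {
    parts <- strsplit(ids, delimiter, fixed = TRUE)
    species <- vapply(parts, function(p) p[length(p)], character(1))
    ids <- vapply(parts, function(p) paste(p[-length(p)], collapse = delimiter),
                  character(1))
  }
  dna_alignment(do.call(rbind, chars), ids = ids, species = species)
}

#' Write an alignment as FASTA
#'
#' @param aln a [dna_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  strs <- alignment_strings(aln)
  out <- character(2 * length(strs))
  out[c(TRUE, FALSE)] <- paste0(">", names(strs))
  out[c(FALSE, TRUE)] <- unname(strs)
  writeLines(out, path)
  invisible(path)
}
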