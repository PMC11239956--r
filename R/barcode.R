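IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")

#' Aligned DNA sequences with species labels
#'
#' @param sequences character matrix (sequences x sites), or a character
#'   vector of equal-length strings, over the IUPAC alphabet (plus gap and
#'   `?`). Lowercase input is uppercased.
#' @param ids unique sequence labels.
#' @param species optional species label per sequence.
#' @return an object of class `dna_alignment` with elements `ids`,
#'   `species`, and `seq` (uppercase character matrix).
#' @export
dna_alignment <- function(sequences, ids = NULL, species = NULL) {
  if (is.character(sequences) && is.null(dim(sequences))) {
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1) {
      stopf("ragged alignment: lengths %s", paste(unique(lens), collapse = ", "))
    }
    sequences <- do.call(rbind, strsplit(sequences, ""))
  }
  sequences <- toupper(as.matrix(sequences))
  bad <- !(sequences %in% IUPAC_CHARS)
  if (any(bad)) {
    stopf("illegal characters in alignment: %s",
          paste(unique(sequences[bad]), collapse = " "))
  }
  n <- nrow(sequences)
  ids <- ids %||% rownames(sequences) %||% sprintf("seq%03d", seq_len(n))
  if (anyDuplicated(ids)) stopf("sequence ids must be unique")
  if (!is.null(species) && length(species) != n) {
    stopf("species labels (%d) do not match sequences (%d)", length(species), n)
  }
  rownames(sequences) <- ids
  structure(list(ids = as.character(ids),
                 species = if (is.null(species)) NULL else as.character(species),
                 seq = sequences),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("dna_alignment: %d sequences x %d sites\n", nrow(x$seq), ncol(x$seq)))
  if (!is.null(x$species)) print(table(x$species))
  invisible(x)
}

#' Sequence strings of an alignment
#' @param aln a [dna_alignment()].
#' @return named character vector of sequences.
#' @export
alignment_strings <- function(aln) {
  stats::setNames(apply(aln$seq, 1, paste0, collapse = ""), aln$ids)
}

is_strict_base <- function(x) x %in% c("A", "C", "G", "T")

#' Kimura 2-parameter distance between two sequences
#'
#' Pairwise deletion: sites where either sequence carries a gap, `N`, `?`,
#' or any IUPAC ambiguity are excluded before computing the transition
#' proportion `P` and transversion proportion `Q`; then
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param a,b character vectors (one character per site) or single strings
#'   of equal length.
#' @return distance in substitutions/site; errors on saturation
#'   (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) and when no comparable sites
#'   remain.
#' @export
k2p_distance <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1]]
  a <- toupper(a); b <- toupper(b)
  if (length(a) != length(b)) stopf("sequences differ in length")
  ok <- is_strict_base(a) & is_strict_base(b)
  n <- sum(ok)
  if (n == 0) stopf("no comparable sites after pairwise deletion")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stopf("K2P distance undefined (saturation): P = %.3f, Q = %.3f", P, Q)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' All-pairs K2P distance matrix
#'
#' @param aln a [dna_alignment()].
#' @param on_saturation `"error"` (default, per the K2P contract) or
#'   `"na"` to record saturated pairs as `NA` with a warning.
#' @return symmetric matrix of distances (substitutions/site).
#' @export
k2p_matrix <- function(aln, on_saturation = c("error", "na")) {
  stopifnot(inherits(aln, "dna_alignment"))
  on_saturation <- match.arg(on_saturation)
  n <- nrow(aln$seq)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      val <- tryCatch(k2p_distance(aln$seq[i, ], aln$seq[j, ]),
                      error = function(e) {
                        if (on_saturation == "error") stop(e)
                        warnf("pair %s / %s: %s", aln$ids[i], aln$ids[j],
                              conditionMessage(e))
                        NA_real_
                      })
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' Intra/interspecific distance summaries
#'
#' Arithmetic means over unordered sequence pairs within each species and
#' between species, from the K2P distance matrix, reported both in
#' substitutions/site and as percentages (rounded to two decimals for
#' reporting). A species with a single sequence gets an `NA` intraspecific
#' mean (flagged by a warning).
#'
#' @param aln a [dna_alignment()] with species labels (>= 2 species for the
#'   interspecific mean).
#' @return list with `model = "K2P"`, `matrix`, `intra_mean` (per species),
#'   `inter_mean`, `min`, `max`, and a `summary` data.frame with percent
#'   columns.
#' @export
distance_summaries <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (is.null(aln$species)) stopf("species labels are required")
  if (nrow(aln$seq) < 2) stopf("need at least 2 sequences")
  d <- k2p_matrix(aln)
  sp <- aln$species
  species <- unique(sp)
  intra <- vapply(species, function(s) {
    idx <- which(sp == s)
    if (length(idx) < 2) {
      warnf("species %s has a single sequence; intraspecific mean undefined", s)
      return(NA_real_)
    }
    m <- d[idx, idx]
    mean(m[upper.tri(m)])
  }, numeric(1))
  inter <- NA_real_
  if (length(species) >= 2) {
    vals <- c()
    for (i in seq_along(species)[-length(species)]) {
      for (j in (i + 1):length(species)) {
        vals <- c(vals, as.vector(d[sp == species[i], sp == species[j]]))
      }
    }
    inter <- mean(vals)
  }
  off <- d[upper.tri(d)]
  summary <- data.frame(
    quantity = c(paste0("intra_", species), "inter", "min", "max"),
    distance = c(intra, inter, min(off), max(off)),
    percent = round(100 * c(intra, inter, min(off), max(off)), 2)
  )
  list(model = "K2P", matrix = d, intra_mean = intra, inter_mean = inter,
       min = min(off), max = max(off), summary = summary)
}

#' Barcode-gap partitioning of a distance matrix
#'
#' Initial-partition analogue of automatic barcode gap discovery: for each
#' prior maximum intraspecific distance `P` in a (log-spaced, by default)
#' grid, sorted pairwise distances are scanned for the first gap that is
#' wider than both `relative_gap_width` times the mean spacing of the
#' distances below it (the local slope) and the prior `P` itself, with the
#' gap's upper edge lying beyond `P`; sequences are
#' then split by single-linkage clustering at the gap midpoint, and the
#' procedure recurses once inside each resulting group. If no such gap
#' exists the result is a single group (a valid outcome, not an error).
#' The consensus partition is the modal partition across the prior grid.
#'
#' @param d symmetric pairwise distance matrix.
#' @param priors numeric grid of prior maximum intraspecific distances
#'   (default 10 log-spaced values from 0.001 to 0.1).
#' @param relative_gap_width gap width multiplier (default 1.5).
#' @return list with `groups_by_prior` (group count per prior),
#'   `partitions` (list of integer membership vectors), and `consensus`
#'   (the modal partition, as an integer vector named by sequence).
#' @export
barcode_gap_partition <- function(d, priors = NULL, relative_gap_width = 1.5) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d))
  priors <- priors %||% exp(seq(log(0.001), log(0.1), length.out = 10))
  n <- nrow(d)
  ids <- rownames(d) %||% sprintf("seq%03d", seq_len(n))

  find_gap <- function(dist_vals, prior) {
    ds <- sort(dist_vals)
    if (length(ds) < 2) return(NA_real_)
    gaps <- diff(ds)
    for (i in seq_along(gaps)) {
      upper <- ds[i + 1]
      if (upper <= prior) next
      below <- ds[seq_len(i)]
      spacing <- if (i >= 2) mean(diff(below)) else 0
      if (gaps[i] > max(relative_gap_width * spacing, prior)) {
        return((ds[i] + upper) / 2)
      }
    }
    NA_real_
  }

  single_linkage_cut <- function(sub_d, h) {
    if (nrow(sub_d) == 1) return(1L)
    hc <- stats::hclust(stats::as.dist(sub_d), method = "single")
    stats::cutree(hc, h = h)
  }

  partition_once <- function(idx, prior, depth) {
    if (length(idx) <= 1) return(rep(1L, length(idx)))
    sub <- d[idx, idx, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    thr <- find_gap(vals, prior)
    if (is.na(thr)) return(rep(1L, length(idx)))
    cl <- single_linkage_cut(sub, thr)
    if (depth >= 1 || length(unique(cl)) == 1) return(cl)
    # one recursion inside each group
    out <- integer(length(idx))
    nxt <- 0L
    for (k in unique(cl)) {
      inner <- partition_once(idx[cl == k], prior, depth + 1)
      out[cl == k] <- nxt + inner
      nxt <- nxt + max(inner)
    }
    out
  }

  partitions <- lapply(priors, function(p) {
    cl <- partition_once(seq_len(n), p, 0)
    stats::setNames(as.integer(factor(cl, levels = unique(cl))), ids)
  })
  counts <- vapply(partitions, function(p) length(unique(p)), integer(1))
  sig <- vapply(partitions, paste, character(1), collapse = ",")
  consensus <- partitions[[match(names(which.max(table(sig))), sig)]]
  list(groups_by_prior = stats::setNames(counts, signif(priors, 3)),
       partitions = partitions, consensus = consensus)
}

#' Collapse identical sequences into haplotypes
#'
#' By default haplotypes are exact full-string matches (ambiguity codes are
#' *not* treated as wildcards); `match_ambiguous = TRUE` instead collapses
#' sequences identical over their shared unambiguous positions, greedily in
#' input order.
#'
#' @param aln a [dna_alignment()].
#' @param match_ambiguous treat N/ambiguity/gap as wildcards when matching?
#' @return a `haplo_set`: `haplotypes` (character matrix of representative
#'   sequences), `frequency`, `members` (list of ids), `species` (list of
#'   species labels per haplotype, when present).
#' @export
collapse_haplotypes <- function(aln, match_ambiguous = FALSE) {
  stopifnot(inherits(aln, "dna_alignment"))
  n <- nrow(aln$seq)
  if (!match_ambiguous) {
    strs <- apply(aln$seq, 1, paste0, collapse = "")
    key <- match(strs, unique(strs))
  } else {
    key <- integer(n)
    reps <- list()
    for (i in seq_len(n)) {
      s <- aln$seq[i, ]
      hit <- 0L
      for (h in seq_along(reps)) {
        r <- reps[[h]]
        ok <- is_strict_base(s) & is_strict_base(r)
        if (all(s[ok] == r[ok])) { hit <- h; break }
      }
      if (hit == 0L) { reps[[length(reps) + 1L]] <- s; hit <- length(reps) }
      key[i] <- hit
    }
  }
  uh <- sort(unique(key))
  members <- lapply(uh, function(h) aln$ids[key == h])
  structure(
    list(haplotypes = aln$seq[match(uh, key), , drop = FALSE],
         frequency = lengths(members),
         members = members,
         species = if (is.null(aln$species)) NULL else
           lapply(uh, function(h) aln$species[key == h]),
         assignment = stats::setNames(match(key, uh), aln$ids)),
    class = "haplo_set"
  )
}

#' @export
print.haplo_set <- function(x, ...) {
  cat(sprintf("haplo_set: %d haplotypes from %d sequences\n",
              length(x$frequency), sum(x$frequency)))
  for (i in seq_along(x$frequency)) {
    sp <- if (is.null(x$species)) "" else
      sprintf(" [%s]", paste(sort(unique(x$species[[i]])), collapse = "+"))
    cat(sprintf("  H%d (n=%d)%s\n", i, x$frequency[i], sp))
  }
  invisible(x)
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps `j` for which the estimated
#' probability of a parsimonious connection (every observed difference
#' caused by exactly one substitution, no hidden or superimposed changes)
#' exceeds `confidence`. The probability is computed under a
#' Jukes-Cantor-style model with Poisson substitution counts per site: the
#' per-site substitution intensity is solved iteratively so the expected
#' proportion of visibly different sites matches `j / seq_len`, and
#' `log P_j = j log(lambda e^-lambda / p_diff) + (m - j) log(e^-lambda / p_same)`.
#' Computation is in log space, so the limit degenerates to `seq_len` as
#' `confidence` approaches zero.
#'
#' @param seq_len alignment length in sites (>= 1).
#' @param confidence parsimony confidence level in (0, 1); default 0.95,
#'   the conventional statistical-parsimony criterion.
#' @return list with `limit` (max steps) and `table` (data.frame of `steps`
#'   and `prob`).
#' @export
parsimony_connection_limit <- function(seq_len, confidence = 0.95) {
  stopifnot(seq_len >= 1, confidence > 0, confidence < 1)
  m <- as.integer(seq_len)
  logp <- vapply(seq_len(m), function(j) parsimony_log_prob(j, m), numeric(1))
  ok <- logp > log(confidence)
  limit <- if (any(ok)) max(which(ok)) else 0L
  list(limit = as.integer(limit),
       table = data.frame(steps = seq_len(m), prob = exp(logp)))
}

# log probability of a parsimonious connection at j observed differences
# over m sites (see parsimony_connection_limit)
parsimony_log_prob <- function(j, m) {
  # cap the visible-difference proportion below the JC saturation bound
  p_target <- min(j / m, 0.7499)
  lam <- solve_site_intensity(p_target)
  p_diff <- 0.75 * (1 - exp(-4 * lam / 3))
  p_same <- 1 - p_diff
  j * (log(lam) - lam - log(p_diff)) + (m - j) * (-lam - log(p_same))
}

# iterative solve of 0.75 (1 - e^{-4 lam / 3}) = p for the Poisson site
# intensity lambda (fixed-point, with a bisection fallback)
solve_site_intensity <- function(p) {
  stopifnot(p > 0, p < 0.75)
  lam <- p
  for (i in 1:200) {
    nxt <- -0.75 * log(1 - p / 0.75)
    if (abs(nxt - lam) < 1e-14) break
    lam <- nxt
  }
  lam
}

#' Minimum spanning haplotype network under a parsimony limit
#'
#' Builds the minimum spanning network over haplotypes: every minimum
#' spanning tree edge plus every tie-equal alternative (an edge of weight
#' `w` is included iff its endpoints are disconnected using only edges of
#' weight `< w`), restricted to edges whose mutational step count does not
#' exceed `limit`. Disconnected components are reported separately.
#'
#' @param haplotypes a `haplo_set` from [collapse_haplotypes()], or a
#'   character matrix of haplotype sequences.
#' @param limit maximum steps per edge (default from
#'   [parsimony_connection_limit()] at 95% on the alignment length).
#' @return a `haplo_network`: `nodes`, `edges` (data.frame `from`, `to`,
#'   `steps`), `connection_limit`, `components` (membership vector),
#'   `step_matrix`.
#' @export
build_parsimony_network <- function(haplotypes, limit = NULL) {
  seqs <- if (inherits(haplotypes, "haplo_set")) haplotypes$haplotypes
          else as.matrix(haplotypes)
  H <- nrow(seqs)
  limit <- limit %||% parsimony_connection_limit(ncol(seqs))$limit
  steps <- matrix(0L, H, H)
  for (i in seq_len(max(H - 1, 0))) {
    for (j in (i + 1):H) {
      ok <- is_strict_base(seqs[i, ]) & is_strict_base(seqs[j, ])
      steps[i, j] <- steps[j, i] <- sum(seqs[i, ok] != seqs[j, ok])
    }
  }
  edges <- data.frame(from = integer(0), to = integer(0), steps = integer(0))
  comp <- seq_len(H)
  if (H > 1) {
    for (w in sort(unique(steps[upper.tri(steps)]))) {
      if (w > limit) break
      cand <- which(upper.tri(steps) & steps == w, arr.ind = TRUE)
      add <- cand[comp[cand[, 1]] != comp[cand[, 2]], , drop = FALSE]
      if (nrow(add)) {
        edges <- rbind(edges, data.frame(from = add[, 1], to = add[, 2], steps = w))
        for (r in seq_len(nrow(add))) {  # merge after collecting the tie class
          c1 <- comp[add[r, 1]]; c2 <- comp[add[r, 2]]
          if (c1 != c2) comp[comp == c2] <- c1
        }
      }
    }
  }
  structure(
    list(nodes = haplotypes, edges = edges,
         connection_limit = limit,
         components = as.integer(factor(comp)),
         step_matrix = steps),
    class = "haplo_network"
  )
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplo_network: %d haplotypes, %d edges (limit %d steps), %d component(s)\n",
              nrow(x$step_matrix), nrow(x$edges), x$connection_limit,
              length(unique(x$components))))
  if (nrow(x$edges)) print(x$edges, row.names = FALSE)
  invisible(x)
}
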