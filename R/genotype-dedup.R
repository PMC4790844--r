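#' Does a locus mismatch between two diploid genotypes?
#'
#' The two alleles of each genotype are paired across samples by the
#' minimum-total-difference matching (there are only two possible pairings of
#' a diploid pair, so order of storage never matters). The locus counts as
#' mismatching if, under that best pairing, any matched pair of alleles
#' differs by more than `tol_bp` base pairs.
#'
#' @param g1,g2 length-2 integer vectors of allele lengths (bp).
#' @param tol_bp allele-length tolerance in base pairs (default 2: alleles
#'   within 2 bp are treated as the same allele, absorbing one-step
#'   scoring slippage).
#' @return `TRUE` if the locus mismatches, `FALSE` otherwise, `NA` if either
#'   genotype is missing.
#' @export
#' @examples
#' locus_mismatch(c(150, 154), c(152, 156))  # 2 bp apiece: no mismatch
#' locus_mismatch(c(150, 154), c(150, 160))  # best pairing leaves 6 bp
locus_mismatch <- function(g1, g2, tol_bp = 2) {
  if (anyNA(g1) || anyNA(g2)) return(NA)
  stopifnot(length(g1) == 2L, length(g2) == 2L, tol_bp >= 0)
  d_straight <- c(abs(g1[1] - g2[1]), abs(g1[2] - g2[2]))
  d_crossed <- c(abs(g1[1] - g2[2]), abs(g1[2] - g2[1]))
  best <- if (sum(d_straight) <= sum(d_crossed)) d_straight else d_crossed
  any(best > tol_bp)
}

# genotype_table (long) -> list of per-sample 2 x L matrices, loci as columns
genotype_wide <- function(genotypes) {
  samples <- unique(genotypes$sample_id)
  loci <- sort(unique(genotypes$locus_id))
  a <- matrix(NA_integer_, length(samples), length(loci),
              dimnames = list(samples, loci))
  b <- a
  ia <- cbind(match(genotypes$sample_id, samples),
              match(genotypes$locus_id, loci))
  a[ia] <- genotypes$allele_a
  b[ia] <- genotypes$allele_b
  list(a = a, b = b, samples = samples, loci = loci)
}

#' Detect duplicate individuals among genotyped feathers
#'
#' All pairs of samples (within each colony by default; set
#' `scope = "global"` to compare across colonies too) are compared locus by
#' locus with [locus_mismatch()]. Two samples are declared the same
#' individual when at most `max_mismatch_loci` loci mismatch — i.e.
#' individuals are unique only if alleles mismatch at more than one locus by
#' more than `tol_bp` base pairs. Loci missing in either sample are skipped
#' (not counted as compared). Duplicate groups are the connected components
#' of the same-individual relation.
#'
#' @param genotypes a `genotype_table` (long format).
#' @param colony_of named character vector mapping sample_id to colony_id, or
#'   a `feather_table`; required when `scope = "colony"`.
#' @param tol_bp see [locus_mismatch()].
#' @param max_mismatch_loci maximum mismatching loci still treated as the
#'   same individual (default 1).
#' @param scope `"colony"` (compare within sampling location, the default) or
#'   `"global"`.
#' @return A `dedup_result`: list with `matches` (data.frame `sample_a`,
#'   `sample_b`, `compared_loci`, `mismatching_loci`, `is_same_individual`),
#'   `groups` (list of sample-id vectors, one per individual, singletons
#'   included), `duplicate_groups` (the groups of size >= 2), `by_colony`
#'   (per-colony duplicate proportions; `NULL` for global scope), and
#'   `excluded` (samples with zero scored loci).
#' @export
match_individuals <- function(genotypes, colony_of = NULL, tol_bp = 2,
                              max_mismatch_loci = 1,
                              scope = c("colony", "global")) {
  scope <- match.arg(scope)
  gw <- genotype_wide(genotypes)
  scored <- rowSums(!is.na(gw$a) & !is.na(gw$b))
  excluded <- gw$samples[scored == 0]
  if (length(excluded)) {
    warning("excluding ", length(excluded),
            " sample(s) with no scored loci: ",
            paste(excluded, collapse = ", "))
    keep <- scored > 0
    gw$a <- gw$a[keep, , drop = FALSE]
    gw$b <- gw$b[keep, , drop = FALSE]
    gw$samples <- gw$samples[keep]
  }
  n <- length(gw$samples)
  if (n < 2L) stop("need at least 2 scored samples")
  if (scope == "colony") {
    if (is.null(colony_of)) stop("colony_of is required for scope = 'colony'")
    if (is.data.frame(colony_of))
      colony_of <- setNames(as.character(colony_of$colony_id),
                            colony_of$sample_id)
    colony <- unname(colony_of[gw$samples])
    if (anyNA(colony))
      stop("colony_of does not cover sample(s): ",
           paste(gw$samples[is.na(colony)], collapse = ", "))
  } else {
    colony <- rep("all", n)
  }

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[colony[pairs[, 1]] == colony[pairs[, 2]], , drop = FALSE]
  L <- length(gw$loci)
  res <- data.frame(sample_a = gw$samples[pairs[, 1]],
                    sample_b = gw$samples[pairs[, 2]],
                    compared_loci = 0L, mismatching_loci = 0L,
                    is_same_individual = FALSE, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    compared <- 0L; mism <- 0L
    for (l in seq_len(L)) {
      m <- locus_mismatch(c(gw$a[i, l], gw$b[i, l]),
                          c(gw$a[j, l], gw$b[j, l]), tol_bp = tol_bp)
      if (is.na(m)) next
      compared <- compared + 1L
      if (m) mism <- mism + 1L
    }
    res$compared_loci[r] <- compared
    res$mismatching_loci[r] <- mism
    res$is_same_individual[r] <- compared > 0L && mism <= max_mismatch_loci
  }

  # connected components of the same-individual relation (union-find)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in which(res$is_same_individual)) {
    ri <- find(match(res$sample_a[r], gw$samples))
    rj <- find(match(res$sample_b[r], gw$samples))
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(gw$samples, roots)
  names(groups) <- NULL
  dup_groups <- groups[lengths(groups) >= 2]

  by_colony <- NULL
  if (scope == "colony") {
    n_col <- table(colony)
    extra <- vapply(names(n_col), function(cc) {
      gs <- groups[vapply(groups, function(g)
        colony[match(g[1], gw$samples)] == cc, logical(1))]
      sum(lengths(gs) - 1L)
    }, integer(1))
    by_colony <- data.frame(colony_id = names(n_col),
                            n = as.integer(n_col),
                            n_duplicates = as.integer(extra),
                            proportion = as.integer(extra) / as.integer(n_col),
                            stringsAsFactors = FALSE)
  }
  structure(list(matches = res, groups = groups,
                 duplicate_groups = dup_groups, by_colony = by_colony,
                 excluded = excluded,
                 tol_bp = tol_bp, max_mismatch_loci = max_mismatch_loci,
                 scope = scope),
            class = "dedup_result")
}

#' @export
print.dedup_result <- function(x, ...) {
  extra <- sum(lengths(x$duplicate_groups) - 1L)
  total <- sum(lengths(x$groups))
  cat(sprintf(
    "Duplicate screen (%s scope, tol %d bp, <= %d mismatching locus/loci):\n",
    x$scope, x$tol_bp, x$max_mismatch_loci))
  cat(sprintf("%d of %d feathers are repeat samples of another individual\n",
              extra, total))
  invisible(x)
}

#' Estimate per-locus allele frequencies from a genotype table
#'
#' @param genotypes a `genotype_table`.
#' @param samples optional sample ids to restrict to (e.g. the deduplicated
#'   set, so planted duplicates do not inflate frequencies).
#' @return Named list of per-locus frequency vectors (names = allele bp).
#' @export
allele_frequencies <- function(genotypes, samples = NULL) {
  g <- genotypes
  if (!is.null(samples)) g <- g[g$sample_id %in% samples, , drop = FALSE]
  loci <- sort(unique(g$locus_id))
  setNames(lapply(loci, function(l) {
    al <- c(g$allele_a[g$locus_id == l], g$allele_b[g$locus_id == l])
    al <- al[!is.na(al)]
    if (length(al) == 0L) stop("no scored alleles at locus ", l)
    tab <- table(al)
    setNames(as.numeric(tab) / sum(tab), names(tab))
  }), loci)
}

#' Probability of identity from allele frequencies
#'
#' The probability that two unrelated individuals drawn at random share a
#' multilocus genotype: per locus
#' \eqn{\sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2}, multiplied across
#' independent loci.
#'
#' @param freqs per-locus list of allele frequency vectors (each summing
#'   to 1), e.g. from [allele_frequencies()] or a scenario's allele pool.
#' @return A `pid_report`: list with `per_locus` (named numeric) and
#'   `overall`.
#' @export
#' @examples
#' probability_of_identity(list(L1 = c("150" = 0.5, "152" = 0.5)))
probability_of_identity <- function(freqs) {
  stopifnot(is.list(freqs), length(freqs) >= 1L)
  per_locus <- vapply(seq_along(freqs), function(li) {
    p <- as.numeric(freqs[[li]])
    if (length(p) == 0L) stop("empty locus ", li)
    if (abs(sum(p) - 1) > 1e-9)
      stop("allele frequencies at locus ", li, " do not sum to 1")
    s2 <- sum(p^2); s4 <- sum(p^4)
    # sum_i p_i^4 + sum_{i<j} (2 p_i p_j)^2 = 2 (sum p^2)^2 - sum p^4
    2 * s2^2 - s4
  }, numeric(1))
  names(per_locus) <- names(freqs) %||% sprintf("L%02d", seq_along(freqs))
  structure(list(per_locus = per_locus, overall = prod(per_locus)),
            class = "pid_report")
}

#' @export
print.pid_report <- function(x, ...) {
  cat(sprintf("Probability of identity over %d locus/loci: %.3g\n",
              length(x$per_locus), x$overall))
  invisible(x)
}

#' Keep one representative per duplicate group
#'
#' Each duplicate group contributes a single member, chosen uniformly at
#' random (seeded); singleton groups are kept as-is.
#'
#' @param groups list of sample-id vectors (e.g. `groups` from
#'   [match_individuals()]).
#' @param seed integer seed.
#' @return Character vector of kept sample ids.
#' @export
select_representatives <- function(groups, seed = 1L) {
  stopifnot(is.list(groups))
  ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(ids)) stop("groups are not disjoint")
  set.seed(child_seed(seed, "representatives"))
  kept <- vapply(groups, function(g)
    if (length(g) == 1L) g else g[sample.int(length(g), 1L)], character(1))
  kept[order(match(kept, ids))]
}
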