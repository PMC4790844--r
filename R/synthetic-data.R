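#' Describe one breeding colony's isotope distribution
#'
#' A colony specification holds the trivariate-normal distribution of feather
#' isotope values (\eqn{\delta^2}H, \eqn{\delta^{13}}C, \eqn{\delta^{15}}N, in
#' per mil) at one breeding colony, together with its location and the number
#' of feathers to simulate there.
#'
#' @param colony_id character label.
#' @param latitude,longitude colony coordinates in decimal degrees.
#' @param n_samples number of feathers to draw (>= 1).
#' @param mean length-3 numeric, the colony mean isotope values (H, C, N), per mil.
#' @param covariance 3x3 symmetric positive semi-definite matrix (per mil
#'   squared), or a length-3 vector of variances taken as a diagonal matrix.
#' @return An object of class `colony_spec`.
#' @export
#' @examples
#' colony_spec("C01", 49.5, -119.1, 10, c(-120, -24, 12), c(400, 4, 2))
colony_spec <- function(colony_id, latitude, longitude, n_samples, mean,
                        covariance) {
  stopifnot(length(colony_id) == 1L, length(mean) == 3L, n_samples >= 1)
  if (latitude < -90 || latitude > 90)
    stop("latitude out of [-90, 90] for colony ", colony_id)
  if (longitude < -180 || longitude > 180)
    stop("longitude out of [-180, 180] for colony ", colony_id)
  if (is.vector(covariance) && length(covariance) == 3L)
    covariance <- diag(as.numeric(covariance), 3)
  if (!is_symmetric(covariance))
    stop("covariance must be a symmetric 3x3 matrix for colony ", colony_id)
  if (min_eigen(covariance) < -1e-8 * max(1, max(abs(covariance))))
    stop("covariance is not positive semi-definite for colony ", colony_id)
  dimnames(covariance) <- list(ISO_COLS, ISO_COLS)
  structure(
    list(colony_id = as.character(colony_id), latitude = latitude,
         longitude = longitude, n_samples = as.integer(n_samples),
         mean = setNames(as.numeric(mean), ISO_COLS),
         covariance = covariance),
    class = "colony_spec")
}

#' Scenario configuration for the synthetic-data generators
#'
#' Bundles the colony specifications with the analytical measurement SDs, the
#' genotype model (per-locus allele pools), and the planted duplicate
#' structure. The default lab SDs are 3 per mil for hydrogen, 0.2 for carbon
#' and 0.3 for nitrogen, the long-run SDs of laboratory standards typical of
#' feather isotope work.
#'
#' @param colonies list of [colony_spec()] objects.
#' @param lab_sd length-3 non-negative numeric, per-isotope measurement SD
#'   (per mil), order H, C, N.
#' @param duplicate_rate fraction in `[0, 1)` of samples that are genotype
#'   copies of another sample from the same colony (shed feathers from the
#'   same bird).
#' @param allele_pool per-locus list of named numeric vectors; names are
#'   allele lengths in base pairs, values are frequencies summing to 1.
#' @param near_dup_bp if positive, each planted duplicate has one allele at
#'   one locus shifted by this many base pairs, producing near-duplicates for
#'   exercising the matching rule's tolerance. Default 0 (exact copies).
#' @param seed integer root seed; all generator randomness derives from it via
#'   [child_seed()].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(colonies,
                            lab_sd = c(3, 0.2, 0.3),
                            duplicate_rate = 0,
                            allele_pool = default_allele_pool(),
                            near_dup_bp = 0,
                            seed = 1L) {
  stopifnot(is.list(colonies), length(colonies) >= 1L)
  for (cs in colonies)
    if (!inherits(cs, "colony_spec")) stop("colonies must be colony_spec objects")
  ids <- vapply(colonies, `[[`, "", "colony_id")
  if (anyDuplicated(ids)) stop("duplicate colony_id in scenario")
  stopifnot(length(lab_sd) == 3L, all(lab_sd >= 0))
  if (duplicate_rate < 0 || duplicate_rate >= 1)
    stop("duplicate_rate must be in [0, 1)")
  if (length(allele_pool) < 1L) stop("allele_pool must cover at least one locus")
  for (i in seq_along(allele_pool)) {
    p <- allele_pool[[i]]
    if (length(p) == 0L) stop("empty allele pool at locus ", i)
    if (abs(sum(p) - 1) > 1e-9)
      stop("allele frequencies at locus ", i, " do not sum to 1")
    if (any(p < 0)) stop("negative allele frequency at locus ", i)
  }
  if (is.null(names(allele_pool)))
    names(allele_pool) <- sprintf("L%02d", seq_along(allele_pool))
  structure(
    list(colonies = colonies,
         lab_sd = setNames(as.numeric(lab_sd), ISO_COLS),
         duplicate_rate = duplicate_rate,
         n_loci = length(allele_pool),
         allele_pool = allele_pool,
         near_dup_bp = near_dup_bp,
         seed = as.integer(seed)),
    class = "scenario_config")
}

#' Default per-locus allele pool
#'
#' Ten polymorphic microsatellite-like loci. Each locus has `n_alleles`
#' alleles on a 4-bp ladder (tetranucleotide-repeat spacing, so the default
#' 2-bp matching tolerance absorbs scoring slippage without merging distinct
#' alleles) with geometrically decreasing frequencies.
#'
#' @param n_loci number of loci.
#' @param n_alleles alleles per locus.
#' @param decay geometric decay of allele frequencies within a locus.
#' @return Named list of per-locus frequency vectors (names = lengths in bp).
#' @export
default_allele_pool <- function(n_loci = 10, n_alleles = 6, decay = 0.8) {
  stopifnot(n_loci >= 1, n_alleles >= 1, decay > 0)
  pool <- lapply(seq_len(n_loci), function(l) {
    lengths <- 100 + 40 * l + 4 * (seq_len(n_alleles) - 1)
    p <- decay^(seq_len(n_alleles) - 1)
    setNames(p / sum(p), lengths)
  })
  names(pool) <- sprintf("L%02d", seq_len(n_loci))
  pool
}

#' Default 17-colony scenario
#'
#' An illustrative continental scenario: 17 breeding colonies (5-20 feathers
#' each) spread across western/central North America plus one enriched
#' low-latitude coastal colony, with colony means and within-colony spreads
#' chosen so pooled values span roughly -165 to -12 per mil in
#' \eqn{\delta^2}H, -29.5 to -11 in \eqn{\delta^{13}}C and 6.7 to 19.9 in
#' \eqn{\delta^{15}}N. It emulates the *kind* of variability reported for
#' colonial waterbirds (very high within-colony spread, weak geography); it is
#' not a reconstruction of any real data set.
#'
#' @param seed root seed stored in the configuration.
#' @param duplicate_rate passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
#' @examples
#' ft <- generate_feathers(default_scenario(seed = 7))
#' table(ft$colony_id)
default_scenario <- function(seed = 1L, duplicate_rate = 0) {
  # id, lat, lon, n, mean H/C/N, sd H/C/N, corr(H, C)
  tab <- data.frame(
    id  = sprintf("C%02d", 1:17),
    lat = c(49.5, 53.0, 55.1, 52.2, 50.8, 47.2, 45.8, 43.9, 42.5, 41.9,
            40.1, 48.9, 50.4, 50.1, 53.2, 39.9, 27.5),
    lon = c(-119.1, -115.5, -108.2, -106.6, -101.9, -99.5, -96.8, -102.3,
            -112.4, -121.4, -99.0, -94.7, -89.5, -88.3, -81.7, -116.0, -97.3),
    n   = c(15, 9, 10, 10, 10, 6, 20, 18, 9, 15, 10, 14, 10, 10, 8, 5, 10),
    mH  = c(-142, -135, -128, -120, -112, -105, -98, -108, -118, -125,
            -92, -95, -102, -99, -110, -88, -48),
    mC  = c(-26.5, -25.8, -24.9, -25.5, -24.0, -23.6, -23.0, -24.4, -25.2,
            -24.6, -22.5, -22.0, -23.2, -22.8, -23.8, -21.5, -13.8),
    mN  = c(9.5, 10.2, 11.0, 12.3, 11.8, 12.9, 13.5, 12.1, 10.8, 11.5,
            13.8, 14.5, 13.1, 13.9, 12.6, 14.8, 15.5),
    sH  = c(12, 18, 25, 15, 28, 10, 22, 30, 14, 20, 26, 35, 24, 18, 16, 12, 13),
    sC  = c(1.8, 2.2, 2.0, 1.5, 2.5, 1.6, 2.8, 2.4, 1.9, 2.1, 3.0, 2.6,
            2.2, 2.0, 1.7, 2.3, 1.5),
    sN  = c(1.2, 1.6, 1.4, 1.8, 2.0, 1.5, 2.2, 1.9, 1.3, 1.7, 2.4, 2.1,
            1.8, 1.6, 1.4, 2.0, 1.5),
    rHC = c(0, 0, 0, 0, 0, 0, 0.4, 0, 0, 0, 0, 0.3, 0, 0, 0, 0, 0.5))
  colonies <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    s <- c(r$sH, r$sC, r$sN)
    corr <- diag(3)
    corr[1, 2] <- corr[2, 1] <- r$rHC
    sigma <- diag(s) %*% corr %*% diag(s)
    colony_spec(r$id, r$lat, r$lon, r$n, c(r$mH, r$mC, r$mN), sigma)
  })
  scenario_config(colonies, duplicate_rate = duplicate_rate, seed = seed)
}

#' Generate a synthetic feather isotope table
#'
#' Draws each colony's feathers from its trivariate-normal specification.
#' Deterministic given the config's seed; each colony uses its own child
#' random stream keyed by colony id, so adding or reordering colonies does not
#' perturb the draws of the others.
#'
#' @param config a [scenario_config()].
#' @return A `feather_table` data.frame with columns `sample_id`, `colony_id`,
#'   `latitude`, `longitude`, `d2H`, `d13C`, `d15N`.
#' @export
#' @examples
#' cs <- colony_spec("A", 50, -100, 4, c(-100, -24, 12), rep(0, 3))
#' generate_feathers(scenario_config(list(cs), seed = 1))
generate_feathers <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  rows <- lapply(config$colonies, function(cs) {
    set.seed(child_seed(config$seed, paste0("isotopes/", cs$colony_id)))
    x <- MASS::mvrnorm(cs$n_samples, mu = cs$mean, Sigma = cs$covariance)
    if (cs$n_samples == 1L) x <- matrix(x, nrow = 1)
    data.frame(
      sample_id = sprintf("%s_%03d", cs$colony_id, seq_len(cs$n_samples)),
      colony_id = cs$colony_id,
      latitude = cs$latitude, longitude = cs$longitude,
      d2H = x[, 1], d13C = x[, 2], d15N = x[, 3],
      stringsAsFactors = FALSE)
  })
  ft <- do.call(rbind, rows)
  rownames(ft) <- NULL
  class(ft) <- c("feather_table", "data.frame")
  ft
}

#' Reference cluster profiles for the clustering scenario
#'
#' Mean and SD triplets of four isotopic clusters of pelican feathers (the
#' grey/red/blue/green partition reported for this system), used as the
#' default geometry of [generate_cluster_scenario()].
#'
#' @return data.frame with columns `cluster`, `mH`, `mC`, `mN`, `sH`, `sC`, `sN`.
#' @export
default_cluster_profiles <- function() {
  data.frame(
    cluster = c("grey", "red", "blue", "green"),
    mH = c(-100.53, -74.74, -137.83, -42.89),
    mC = c(-22.73, -21.84, -22.89, -18.43),
    mN = c(13.46, 13.74, 12.52, 12.34),
    sH = c(7.1, 7.3, 14.3, 14.1),
    sC = c(2.5, 3.5, 2.7, 4.7),
    sN = c(2.6, 2.2, 2.9, 1.5),
    stringsAsFactors = FALSE)
}

#' Generate feathers from k planted isotopic clusters
#'
#' Samples are drawn from `k` independent trivariate normals with diagonal
#' covariance built from per-cluster SD triplets. The default geometry is the
#' four-cluster partition of [default_cluster_profiles()]. Cluster membership
#' is recorded in the returned table's `"cluster"` attribute (ground truth for
#' recovery tests); `colony_id` carries the cluster label.
#'
#' @param k number of clusters (>= 1).
#' @param means k x 3 matrix (or data.frame) of cluster means.
#' @param sds k x 3 matrix of per-axis SDs (>= 0).
#' @param n_per_cluster samples per cluster (recycled to length k).
#' @param seed integer seed.
#' @return A `feather_table` with attribute `cluster` (integer labels 1..k).
#' @export
#' @examples
#' ft <- generate_cluster_scenario(n_per_cluster = 10, seed = 3)
#' table(attr(ft, "cluster"))
generate_cluster_scenario <- function(k = 4, means = NULL, sds = NULL,
                                      n_per_cluster = 50, seed = 1L) {
  stopifnot(k >= 1)
  if (is.null(means) || is.null(sds)) {
    prof <- default_cluster_profiles()
    if (k > nrow(prof) && (is.null(means) || is.null(sds)))
      stop("provide means and sds when k > ", nrow(prof))
    means <- means %||% as.matrix(prof[seq_len(k), c("mH", "mC", "mN")])
    sds <- sds %||% as.matrix(prof[seq_len(k), c("sH", "sC", "sN")])
  }
  means <- as.matrix(means); sds <- as.matrix(sds)
  stopifnot(nrow(means) == k, ncol(means) == 3, nrow(sds) == k, ncol(sds) == 3)
  if (any(sds < 0)) stop("negative SD in cluster scenario")
  n_per_cluster <- rep_len(n_per_cluster, k)
  colonies <- lapply(seq_len(k), function(i)
    colony_spec(sprintf("cluster_%02d", i),
                latitude = 40 + i, longitude = -100 - i,
                n_samples = n_per_cluster[i],
                mean = means[i, ], covariance = diag(sds[i, ]^2, 3)))
  ft <- generate_feathers(scenario_config(colonies, seed = seed))
  attr(ft, "cluster") <- rep(seq_len(k), times = n_per_cluster)
  ft
}

#' Generate synthetic microsatellite genotypes with planted duplicates
#'
#' Each base individual receives an independent diploid genotype (two alleles
#' per locus drawn from the locus pool). A `duplicate_rate` fraction of
#' samples are then turned into copies of another sample from the same colony
#' (exact copies by default; see `near_dup_bp` in [scenario_config()]),
#' emulating shed feathers collected twice from one bird. Ground-truth
#' duplicate pairs are returned alongside.
#'
#' @param config a [scenario_config()].
#' @param feathers a `feather_table` giving sample and colony ids.
#' @return list with elements `genotypes` (long `genotype_table` data.frame:
#'   `sample_id`, `locus_id`, `allele_a`, `allele_b`), `duplicates`
#'   (data.frame `copy_id`, `source_id`; zero rows when none planted), and
#'   `allele_pool`.
#' @export
generate_genotypes <- function(config, feathers) {
  stopifnot(inherits(config, "scenario_config"))
  samples <- feathers$sample_id
  colony <- feathers$colony_id
  n <- length(samples)
  if (n < 1L) stop("no samples to genotype")
  pool <- config$allele_pool
  loci <- names(pool)

  # independent base genotypes, one stream for all loci
  set.seed(child_seed(config$seed, "genotypes"))
  geno <- lapply(pool, function(p) {
    lengths <- as.integer(names(p))
    idx <- sample.int(length(p), 2L * n, replace = TRUE, prob = p)
    matrix(lengths[idx], nrow = n, ncol = 2)
  })

  # plant duplicates: copies of a random other sample in the same colony
  dup <- data.frame(copy_id = character(0), source_id = character(0),
                    stringsAsFactors = FALSE)
  n_dup <- round(config$duplicate_rate * n)
  if (n_dup > 0) {
    set.seed(child_seed(config$seed, "duplicates"))
    eligible <- which(ave(seq_len(n), colony, FUN = length) >= 2)
    if (length(eligible) < n_dup)
      stop("not enough samples in multi-sample colonies to plant ", n_dup,
           " duplicates")
    copies <- sort(sample(eligible, n_dup))
    sources <- integer(n_dup)
    for (j in seq_along(copies)) {
      i <- copies[j]
      cands <- setdiff(which(colony == colony[i]), copies)
      if (length(cands) == 0L) cands <- setdiff(which(colony == colony[i]), i)
      sources[j] <- if (length(cands) == 1L) cands else sample(cands, 1L)
    }
    for (l in loci)
      geno[[l]][copies, ] <- geno[[l]][sources, , drop = FALSE]
    if (config$near_dup_bp > 0) {
      # shift one allele at one locus per copy to create near-duplicates
      shift_locus <- sample(seq_along(loci), n_dup, replace = TRUE)
      for (j in seq_along(copies)) {
        l <- loci[shift_locus[j]]
        geno[[l]][copies[j], 1] <- geno[[l]][copies[j], 1] + config$near_dup_bp
      }
    }
    dup <- data.frame(copy_id = samples[copies], source_id = samples[sources],
                      stringsAsFactors = FALSE)
  }

  gt <- do.call(rbind, lapply(seq_along(loci), function(li) {
    g <- geno[[li]]
    data.frame(sample_id = samples, locus_id = loci[li],
               allele_a = g[, 1], allele_b = g[, 2],
               stringsAsFactors = FALSE)
  }))
  gt <- gt[order(match(gt$sample_id, samples), gt$locus_id), ]
  rownames(gt) <- NULL
  class(gt) <- c("genotype_table", "data.frame")
  list(genotypes = gt, duplicates = dup, allele_pool = pool)
}
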