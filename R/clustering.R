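#' k-means clustering of feather isotope triplets
#'
#' Partitions the (d2H, d13C, d15N) triplets into `k` clusters by k-means,
#' taking the best of `n_restarts` random starts by total within-cluster sum
#' of squares. Isotopes are clustered on their native per-mil scales by
#' default (d2H spans an order of magnitude more than the other two axes and
#' dominates the partition); set `standardize = TRUE` to z-score each axis
#' first.
#'
#' @param feathers a `feather_table` (or any data.frame with the three
#'   isotope columns).
#' @param k number of clusters; must not exceed the number of distinct points.
#' @param n_restarts random restarts (default 50, enough to stabilize the
#'   WSS curve).
#' @param standardize z-score each isotope axis before clustering.
#' @param seed integer seed; results are deterministic given the seed.
#' @param iter_max maximum k-means iterations.
#' @return A `cluster_result`: list with `k`, `labels` (integer per sample),
#'   `centroids` (k x 3, on the clustering scale), `wss` (total
#'   within-cluster sum of squares), `standardize`.
#' @export
#' @examples
#' ft <- generate_cluster_scenario(k = 2, n_per_cluster = 8, seed = 1)
#' cluster_feathers(ft, k = 2)$k
cluster_feathers <- function(feathers, k, n_restarts = 50,
                             standardize = FALSE, seed = 1L, iter_max = 100) {
  x <- iso_matrix(feathers)
  if (standardize) x <- scale(x)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct)
    stop("k = ", k, " exceeds the number of distinct points (", n_distinct, ")")
  set.seed(child_seed(seed, paste0("kmeans/k", k)))
  km <- if (k == 1L) {
    ctr <- matrix(colMeans(x), 1, 3)
    list(cluster = rep(1L, nrow(x)), centers = ctr,
         tot.withinss = sum(sweep(x, 2, ctr[1, ])^2))
  } else if (k == n_distinct) {
    # every distinct point is its own cluster; WSS is exactly zero
    u <- unique(x)
    list(cluster = match(apply(x, 1, paste, collapse = "\r"),
                         apply(u, 1, paste, collapse = "\r")),
         centers = u, tot.withinss = 0)
  } else {
    stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = iter_max)
  }
  structure(list(k = k, labels = as.integer(km$cluster),
                 centroids = km$centers, wss = km$tot.withinss,
                 standardize = standardize),
            class = "cluster_result")
}

#' Within-cluster sum-of-squares curve over k
#'
#' @inheritParams cluster_feathers
#' @param k_range integer vector of cluster counts (values above the number
#'   of distinct points are dropped).
#' @return Named numeric vector, WSS per k.
#' @export
wss_curve <- function(feathers, k_range = 1:20, n_restarts = 50,
                      standardize = FALSE, seed = 1L) {
  x <- iso_matrix(feathers)
  n_distinct <- nrow(unique(if (standardize) scale(x) else x))
  k_range <- sort(unique(k_range[k_range >= 1 & k_range <= n_distinct]))
  wss <- vapply(k_range, function(k)
    cluster_feathers(feathers, k, n_restarts = n_restarts,
                     standardize = standardize, seed = seed)$wss,
    numeric(1))
  setNames(wss, k_range)
}

# Elbow of a WSS curve. `wss` is named by k and must include k = min(k)..max.
# "last_drop": largest k whose relative WSS drop from k-1 reaches
# `drop_threshold` (a formalization of reading the elbow plot: keep adding
# clusters while each one still explains a sizeable share of the remaining
# variance). "curvature": maximum second difference.
elbow_from_curve <- function(wss, rule = c("last_drop", "curvature"),
                             drop_threshold = 0.3) {
  rule <- match.arg(rule)
  k <- as.integer(names(wss))
  stopifnot(length(wss) >= 3, all(diff(k) == 1L))
  if (any(diff(wss) > 1e-8 * max(abs(wss))))
    warning("WSS curve is not monotone non-increasing; ",
            "consider more restarts")
  drops <- -diff(wss) / pmax(wss[-length(wss)], .Machine$double.eps)
  names(drops) <- k[-1]
  big <- which(drops >= drop_threshold)
  low_confidence <- FALSE
  if (rule == "curvature") {
    curv <- wss[-c(length(wss) - 1, length(wss))] - 2 * wss[-c(1, length(wss))] +
      wss[-c(1, 2)]
    k_hat <- k[-c(1, length(k))][which.max(curv)]
    low_confidence <- length(big) == 0L
  } else if (length(big)) {
    k_hat <- as.integer(names(drops)[max(big)])
  } else {
    # no drop clears the threshold: no strong elbow; report the smallest k
    # whose drop is already below threshold and flag low confidence
    k_hat <- as.integer(names(drops)[1])
    low_confidence <- TRUE
  }
  list(k = k_hat, low_confidence = low_confidence, drops = drops)
}

#' Choose the number of isotopic clusters from the WSS curve
#'
#' Computes the within-cluster sum-of-squares curve for k = 1..`k_max` and
#' locates its elbow. The default rule (`"last_drop"`) returns the largest k
#' whose relative WSS drop from k-1 is at least `drop_threshold`; when no
#' drop reaches the threshold there is no strong elbow, the smallest k below
#' threshold is returned and the result is flagged low-confidence.
#' `"curvature"` instead maximizes the discrete second difference. The full
#' curve is returned so the choice can be inspected (and overridden) by eye,
#' which is how this selection is traditionally made.
#'
#' @inheritParams cluster_feathers
#' @param k_max largest k examined (default 20).
#' @param rule `"last_drop"` or `"curvature"`.
#' @param drop_threshold relative WSS drop counted as a real cluster gain.
#' @return list with `k`, `low_confidence`, `wss` (the curve, k = 1..k_max),
#'   `drops` (relative drops), `rule`.
#' @export
#' @examples
#' ft <- generate_cluster_scenario(n_per_cluster = 20, seed = 2)
#' choose_k(ft, k_max = 8, n_restarts = 10)$k
choose_k <- function(feathers, k_max = 20, rule = c("last_drop", "curvature"),
                     drop_threshold = 0.3, n_restarts = 50,
                     standardize = FALSE, seed = 1L) {
  rule <- match.arg(rule)
  wss <- wss_curve(feathers, k_range = 1:k_max, n_restarts = n_restarts,
                   standardize = standardize, seed = seed)
  e <- elbow_from_curve(wss, rule = rule, drop_threshold = drop_threshold)
  list(k = e$k, low_confidence = e$low_confidence, wss = wss,
       drops = e$drops, rule = rule)
}

#' Per-cluster isotope summary (mean and SD)
#'
#' Arithmetic mean and sample SD (n-1 divisor) of each isotope within each
#' cluster, the standard "mean (SD) by cluster" summary table. Singleton
#' clusters report `NA` SDs.
#'
#' @param feathers a `feather_table`.
#' @param labels integer cluster label per sample.
#' @return data.frame with one row per cluster: `cluster`, `n`, then
#'   `mean_*` and `sd_*` for the three isotopes.
#' @export
cluster_summary <- function(feathers, labels) {
  stopifnot(length(labels) == nrow(feathers))
  f <- factor(labels)
  out <- data.frame(cluster = levels(f), n = as.integer(table(f)),
                    stringsAsFactors = FALSE)
  for (col in ISO_COLS) {
    out[[paste0("mean_", col)]] <- as.numeric(tapply(feathers[[col]], f, mean))
    out[[paste0("sd_", col)]] <- as.numeric(tapply(feathers[[col]], f,
      function(z) if (length(z) < 2) NA_real_ else sd(z)))
  }
  out
}

#' Cluster composition of each colony
#'
#' For each colony, the fraction of its feathers falling into each cluster
#' (rows sum to 1), plus the count of colonies containing at least m distinct
#' clusters for m = 1..k — the summary used to show whether clusters track
#' geography.
#'
#' @param feathers a `feather_table`.
#' @param labels integer cluster label per sample.
#' @return list with `proportions` (colonies x clusters matrix),
#'   `clusters_per_colony` (named integer), and `colonies_with_at_least`
#'   (element m = number of colonies containing >= m clusters).
#' @export
cluster_composition_by_colony <- function(feathers, labels) {
  stopifnot(length(labels) == nrow(feathers))
  tab <- table(feathers$colony_id, factor(labels))
  prop <- sweep(unclass(tab), 1, rowSums(tab), "/")
  present <- rowSums(tab > 0)
  k <- ncol(tab)
  at_least <- vapply(seq_len(k), function(m) sum(present >= m), integer(1))
  list(proportions = prop,
       clusters_per_colony = setNames(as.integer(present), rownames(tab)),
       colonies_with_at_least = setNames(at_least, seq_len(k)))
}

#' MANOVA across isotopic clusters
#'
#' One-way multivariate analysis of variance of the three isotope axes across
#' cluster (or any group) labels, computed from the between- and within-group
#' SSCP matrices. The default statistic is Wilks' lambda with Rao's F
#' approximation; Pillai's trace is also available. Degrees of freedom are
#' reported both under the multivariate convention and under the
#' univariate-style convention (df1 = g - 1, df2 = n - g) that some software
#' prints for this test, so either style of report can be compared.
#'
#' @param feathers a `feather_table`.
#' @param labels group label per sample (>= 2 groups, each with >= 2 samples;
#'   total n must exceed variables + groups).
#' @param statistic `"wilks"` or `"pillai"`.
#' @return A `manova_result`: list with `statistic_name`, `statistic`,
#'   `F_approx`, `df1`, `df2`, `p`, `df1_univariate`, `df2_univariate`,
#'   `SSCP_between`, `SSCP_within`, `n`, `groups`.
#' @export
manova_clusters <- function(feathers, labels,
                            statistic = c("wilks", "pillai")) {
  statistic <- match.arg(statistic)
  x <- iso_matrix(feathers)
  f <- factor(labels)
  g <- nlevels(f)
  n <- nrow(x)
  p <- ncol(x)
  if (g < 2) stop("need at least 2 groups")
  if (any(table(f) < 2)) stop("every group needs at least 2 samples")
  if (n <= p + g) stop("need n > variables + groups")
  grand <- colMeans(x)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (lev in levels(f)) {
    xi <- x[f == lev, , drop = FALSE]
    mi <- colMeans(xi)
    W <- W + crossprod(sweep(xi, 2, mi))
    B <- B + nrow(xi) * tcrossprod(mi - grand)
  }
  evW <- eigen((W + t(W)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(evW) < 1e-10 * max(evW))
    stop("within-group SSCP matrix is singular")
  dfh <- g - 1
  dfe <- n - g
  if (statistic == "wilks") {
    lambda <- det(W) / det(W + B)
    tt <- if (p^2 + dfh^2 - 5 > 0)
      sqrt((p^2 * dfh^2 - 4) / (p^2 + dfh^2 - 5)) else 1
    df1 <- p * dfh
    df2 <- (dfe + dfh - (p + dfh + 1) / 2) * tt - (p * dfh - 2) / 2
    Fapprox <- ((1 - lambda^(1 / tt)) / lambda^(1 / tt)) * df2 / df1
    stat <- lambda
  } else {
    ev <- Re(eigen(solve(W + B, B), only.values = TRUE)$values[seq_len(min(p, dfh))])
    V <- sum(ev)
    s <- min(p, dfh)
    m <- (abs(p - dfh) - 1) / 2
    nn <- (dfe - p - 1) / 2
    df1 <- s * (2 * m + s + 1)
    df2 <- s * (2 * nn + s + 1)
    Fapprox <- (df2 / df1) * V / (s - V)
    stat <- V
  }
  pval <- stats::pf(Fapprox, df1, df2, lower.tail = FALSE)
  structure(list(statistic_name = statistic, statistic = stat,
                 F_approx = Fapprox, df1 = df1, df2 = df2, p = pval,
                 df1_univariate = dfh, df2_univariate = dfe,
                 SSCP_between = B, SSCP_within = W, n = n, groups = g),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("MANOVA (%s = %.4f): approx F(%.1f, %.1f) = %.2f, p = %.3g\n",
              x$statistic_name, x$statistic, x$df1, x$df2, x$F_approx, x$p))
  cat(sprintf("univariate-style df: F(%d, %d)\n",
              x$df1_univariate, x$df2_univariate))
  invisible(x)
}
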