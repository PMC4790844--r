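test_that("k-means basics: zero WSS at k = n, planted two-cloud recovery", {
  set.seed(1)
  x <- matrix(rnorm(18), 6, 3)
  ft <- feathers_from_matrix(x, "A")
  cl <- cluster_feathers(ft, k = 6, n_restarts = 5)
  expect_equal(cl$wss, 0, tolerance = 1e-10)
  expect_error(cluster_feathers(ft, k = 7), "distinct points")

  # two well-separated clouds: exhaustive search over all 2-partitions
  set.seed(2)
  y <- rbind(matrix(rnorm(15), 5, 3), matrix(rnorm(15, mean = 30), 5, 3))
  ft2 <- feathers_from_matrix(y, "A")
  cl2 <- cluster_feathers(ft2, k = 2, n_restarts = 10)
  wss_of <- function(lbl) {
    sum(sapply(unique(lbl), function(g) {
      xi <- y[lbl == g, , drop = FALSE]
      sum(sweep(xi, 2, colMeans(xi))^2)
    }))
  }
  best <- Inf; best_lbl <- NULL
  for (code in 1:(2^9 - 1)) {  # all bipartitions with point 1 in group 0
    lbl <- c(0, as.integer(intToBits(code))[1:9])
    if (length(unique(lbl)) < 2) next
    w <- wss_of(lbl)
    if (w < best) { best <- w; best_lbl <- lbl }
  }
  expect_equal(rand_index(cl2$labels, best_lbl), 1)
  expect_equal(cl2$wss, best, tolerance = 1e-8)
})

test_that("k-means is invariant to replication and row permutation", {
  set.seed(3)
  y <- rbind(matrix(rnorm(24, sd = 1), 8, 3),
             matrix(rnorm(24, mean = 25), 8, 3))
  ft <- feathers_from_matrix(y, "A")
  cl <- cluster_feathers(ft, k = 2, n_restarts = 10, seed = 5)

  ft_dup <- feathers_from_matrix(rbind(y, y), "A")
  cl_dup <- cluster_feathers(ft_dup, k = 2, n_restarts = 10, seed = 5)
  expect_equal(cl$centroids[order(cl$centroids[, 1]), ],
               cl_dup$centroids[order(cl_dup$centroids[, 1]), ],
               tolerance = 1e-8, ignore_attr = TRUE)

  perm <- sample(nrow(y))
  cl_perm <- cluster_feathers(feathers_from_matrix(y[perm, ], "A"),
                              k = 2, n_restarts = 10, seed = 6)
  expect_equal(rand_index(cl$labels[perm], cl_perm$labels), 1)
})

test_that("WSS curve is non-increasing with enough restarts", {
  ft <- generate_cluster_scenario(n_per_cluster = 25, seed = 4)
  wss <- wss_curve(ft, k_range = 1:8, n_restarts = 20, seed = 4)
  expect_true(all(diff(wss) <= 1e-8 * wss[1]))
})

test_that("elbow rules locate the breakpoint of a piecewise-linear curve", {
  # steep linear descent to k* = 3, then nearly flat
  wss <- setNames(c(100, 60, 20, 19.5, 19, 18.8, 18.7), 1:7)
  e_drop <- isocolony:::elbow_from_curve(wss, rule = "last_drop")
  expect_equal(e_drop$k, 3L)
  expect_false(e_drop$low_confidence)
  e_curv <- isocolony:::elbow_from_curve(wss, rule = "curvature")
  expect_equal(e_curv$k, 3L)
  # non-monotone curve warns but still answers
  wss_bad <- setNames(c(100, 60, 20, 21, 19, 18.8, 18.7), 1:7)
  expect_warning(isocolony:::elbow_from_curve(wss_bad), "not monotone")
})

test_that("choose_k recovers four planted clusters and flags the null case", {
  ft <- generate_cluster_scenario(n_per_cluster = 50, seed = 5)
  ck <- choose_k(ft, k_max = 10, n_restarts = 20, seed = 5)
  expect_equal(ck$k, 4L)
  expect_false(ck$low_confidence)
  expect_length(ck$wss, 10)

  # a single spherical cluster has no strong elbow
  set.seed(6)
  null_ft <- feathers_from_matrix(matrix(rnorm(300), 100, 3), "A")
  ck0 <- choose_k(null_ft, k_max = 8, n_restarts = 20, seed = 6)
  expect_true(ck0$low_confidence)
})

test_that("planted well-separated clusters are recovered almost perfectly", {
  means <- matrix(c(-150, -24, 12, -100, -24, 12, -50, -24, 12), 3,
                  byrow = TRUE)
  sds <- matrix(1, 3, 3)  # >= 10 SDs apart in d2H
  ft <- generate_cluster_scenario(k = 3, means = means, sds = sds,
                                  n_per_cluster = 20, seed = 7)
  cl <- cluster_feathers(ft, k = 3, n_restarts = 20, seed = 7)
  expect_gte(rand_index(cl$labels, attr(ft, "cluster")), 0.99)
})

test_that("cluster summary reports mean and n-1 SD, with NA for singletons", {
  ft <- feathers_from_matrix(rbind(c(-100, -22, 13), c(-102, -24, 15),
                                   c(-50, -18, 11)), "A")
  s <- cluster_summary(ft, c(1, 1, 2))
  expect_equal(s$mean_d2H, c(-101, -50))
  expect_equal(s$mean_d15N, c(14, 11))
  expect_true(is.na(s$sd_d2H[2]))
  # SD against the explicit sum formula
  v <- c(-100, -102)
  sd_oracle <- sqrt((sum(v^2) - 2 * mean(v)^2) / (2 - 1))
  expect_equal(s$sd_d2H[1], sd_oracle, tolerance = 1e-12)
})

test_that("colony composition proportions are normalized and counted", {
  # colony X entirely in cluster 2 -> unit basis vector
  ft <- feathers_from_matrix(matrix(rnorm(36), 12, 3),
                             rep(c("X", "Y", "Z"), each = 4))
  labels <- c(rep(2, 4), rep(c(1, 2, 3, 4), 2))
  comp <- cluster_composition_by_colony(ft, labels)
  expect_equal(unname(rowSums(comp$proportions)), rep(1, 3))
  expect_equal(unname(comp$proportions["X", ]), c(0, 1, 0, 0))
  # Y and Z are even 4-way mixes -> all three colonies have >= 1 cluster,
  # two colonies have >= 4
  expect_equal(unname(comp$colonies_with_at_least), c(3L, 2L, 2L, 2L))
  expect_equal(unname(comp$clusters_per_colony), c(1L, 4L, 4L))
})

test_that("MANOVA SSCP matrices match a brute-force double loop", {
  set.seed(8)
  x <- matrix(rnorm(60), 20, 3)
  labels <- rep(1:4, each = 5)
  ft <- feathers_from_matrix(x, "A")
  mv <- manova_clusters(ft, labels)
  grand <- colMeans(x)
  W <- matrix(0, 3, 3); B <- matrix(0, 3, 3)
  for (i in 1:20) {
    gi <- labels[i]
    mi <- colMeans(x[labels == gi, , drop = FALSE])
    W <- W + tcrossprod(x[i, ] - mi)
  }
  for (g in 1:4) {
    mg <- colMeans(x[labels == g, , drop = FALSE])
    B <- B + 5 * tcrossprod(mg - grand)
  }
  expect_equal(mv$SSCP_within, W, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mv$SSCP_between, B, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mv$df1_univariate, 3)
  expect_equal(mv$df2_univariate, 16)
})

test_that("MANOVA agrees with the reference implementation and Hotelling", {
  set.seed(9)
  x <- matrix(rnorm(90), 30, 3)
  x[16:30, 1] <- x[16:30, 1] + 1.5
  labels <- rep(1:2, each = 15)
  ft <- feathers_from_matrix(x, "A")
  mv <- manova_clusters(ft, labels)
  ref <- summary(stats::manova(x ~ factor(labels)), test = "Wilks")
  expect_equal(mv$statistic, ref$stats[1, "Wilks"], tolerance = 1e-8)
  expect_equal(mv$F_approx, ref$stats[1, "approx F"], tolerance = 1e-8)
  expect_equal(mv$p, ref$stats[1, "Pr(>F)"], tolerance = 1e-8)

  # two groups: Wilks' F equals the Hotelling T^2 transformation
  n <- 30; p <- 3
  d <- colMeans(x[1:15, ]) - colMeans(x[16:30, ])
  Sp <- (14 * cov(x[1:15, ]) + 14 * cov(x[16:30, ])) / (n - 2)
  T2 <- (15 * 15 / 30) * drop(t(d) %*% solve(Sp) %*% d)
  F_hot <- (n - p - 1) / (p * (n - 2)) * T2
  expect_equal(mv$F_approx, F_hot, tolerance = 1e-10)

  # Pillai route agrees with the reference as well
  mvp <- manova_clusters(ft, labels, statistic = "pillai")
  refp <- summary(stats::manova(x ~ factor(labels)), test = "Pillai")
  expect_equal(mvp$statistic, refp$stats[1, "Pillai"], tolerance = 1e-8)
  expect_equal(mvp$p, refp$stats[1, "Pr(>F)"], tolerance = 1e-8)
})

test_that("MANOVA p is invariant to joint affine transformation", {
  set.seed(10)
  x <- matrix(rnorm(75), 25, 3)
  labels <- rep(1:5, each = 5)
  ft <- feathers_from_matrix(x, "A")
  A <- random_pd3()  # nonsingular linear map
  b <- rnorm(3)
  x2 <- sweep(x %*% A, 2, b, "+")
  ft2 <- feathers_from_matrix(x2, "A")
  expect_equal(manova_clusters(ft, labels)$p,
               manova_clusters(ft2, labels)$p, tolerance = 1e-8)
})

test_that("MANOVA input contracts are enforced", {
  ft <- feathers_from_matrix(matrix(rnorm(30), 10, 3), "A")
  expect_error(manova_clusters(ft, rep(1, 10)), "at least 2 groups")
  expect_error(manova_clusters(ft, c(1, rep(2, 9))), "at least 2 samples")
  # collinear responses make the within-SSCP singular
  x <- matrix(rnorm(40), 20, 2)
  xs <- cbind(x, x[, 1] + x[, 2])
  ft2 <- feathers_from_matrix(xs, "A")
  expect_error(manova_clusters(ft2, rep(1:2, each = 10)), "singular")
})
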