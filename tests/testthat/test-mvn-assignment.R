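test_that("colony fit matches the explicit outer-product covariance", {
  x <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  fit <- fit_colony_mvn(x)
  expect_equal(unname(fit$mu), c(0.5, 0.5, 0.5))
  # oracle: S = sum (x - mu)(x - mu)' / n, accumulated term by term
  S <- matrix(0, 3, 3)
  for (i in 1:4) S <- S + tcrossprod(x[i, ] - fit$mu)
  expect_equal(unname(fit$sigma), S / 4, tolerance = 1e-12)
  # unbiased divisor toggle
  expect_equal(unname(fit_colony_mvn(x, unbiased = TRUE)$sigma),
               S / 3, tolerance = 1e-12)
})

test_that("colony fit edge cases: identical points, order invariance, errors", {
  x <- matrix(rep(c(-100, -24, 12), each = 5), 5, 3)
  fit <- fit_colony_mvn(x, ridge = 1e-3)
  expect_equal(unname(fit$mu), c(-100, -24, 12))
  expect_equal(unname(fit$sigma), diag(1e-3, 3))

  set.seed(1)
  y <- matrix(rnorm(30), 10, 3)
  f1 <- fit_colony_mvn(y)
  f2 <- fit_colony_mvn(y[sample(10), ])
  expect_equal(f1$mu, f2$mu)
  expect_equal(f1$sigma, f2$sigma)

  expect_error(fit_colony_mvn(y[1, , drop = FALSE]), "at least 2")
  expect_error(fit_colony_mvn(y[1:2, ]), "singular")  # rank-1 covariance
})

test_that("log density is exact at the mean and against the naive oracle", {
  m <- structure(list(colony_id = "A", mu = c(0, 0, 0), sigma = diag(3),
                      n = 10L), class = "colony_mvn")
  expect_equal(mvn_log_density(c(0, 0, 0), m), -1.5 * log(2 * pi),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:10) {
    sigma <- random_pd3()
    mu <- rnorm(3)
    mm <- structure(list(colony_id = "A", mu = mu, sigma = sigma, n = 10L),
                    class = "colony_mvn")
    v <- rnorm(3)
    expect_equal(mvn_log_density(mu + v, mm), mvn_log_density(mu - v, mm),
                 tolerance = 1e-10)
    x <- rnorm(3)
    expect_equal(mvn_log_density(x, mm), naive_mvn_logdens(x, mu, sigma),
                 tolerance = 1e-10)
  }
  bad <- structure(list(colony_id = "A", mu = c(0, 0, 0),
                        sigma = matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3),
                        n = 3L), class = "colony_mvn")
  expect_error(mvn_log_density(c(0, 0, 0), bad), "positive definite")
})

test_that("measurement perturbation is centred and vanishes at zero SD", {
  ft <- generate_feathers(default_scenario(seed = 2))
  expect_equal(perturb_dataset(ft, lab_sd = c(0, 0, 0), seed = 1), ft)
  one <- ft[1, ]
  reps <- replicate(10000, perturb_dataset(one, seed = NULL)$d2H)
  expect_lt(abs(mean(reps) - one$d2H), 3 * 3 / sqrt(10000))
  expect_error(perturb_dataset(ft, lab_sd = c(-1, 0, 0)), "lab_sd")
})

test_that("degenerate resampling settings reduce to the argmax classifier", {
  ft <- separated_scenario(seed = 6, K = 3, n = 10, sep = 2)
  a <- resampling_assign(ft, lab_sd = 0, n_param_reps = 1, n_noise = 1,
                         loocv = FALSE, seed = 1)
  expect_equal(a$winner, argmax_classifier(ft))
  expect_true(all(a$confidence == 1))
})

test_that("single-colony input assigns everything to it with confidence 1", {
  ft <- feathers_from_matrix(matrix(rnorm(24), 8, 3), "only")
  a <- resampling_assign(ft, n_param_reps = 3, n_noise = 5, seed = 1)
  expect_true(all(a$winner == "only"))
  expect_true(all(a$confidence == 1))
})

test_that("two colonies with identical distributions split the outcomes", {
  set.seed(7)
  x <- matrix(rnorm(45, sd = 5), 15, 3)
  ft <- rbind(feathers_from_matrix(x, "A"), feathers_from_matrix(x, "B"))
  ft$sample_id <- sprintf("S%03d", seq_len(nrow(ft)))
  a <- resampling_assign(ft, lab_sd = c(3, 3, 3), n_param_reps = 20,
                         n_noise = 20, seed = 3)
  # each sample's share of outcomes for colony A hovers around 1/2
  shareA <- attr(a, "counts")[, "A"] / attr(a, "n_sims")
  expect_lt(abs(mean(shareA) - 0.5), 0.1)
  expect_true(all(shareA > 0.05 & shareA < 0.95))
})

test_that("assignment counts are conserved and the winner attains the max", {
  for (cfgi in 1:2) {
    ft <- if (cfgi == 1) common_mvn_scenario(seed = 3, K = 3, n = 6)
          else separated_scenario(seed = 4, K = 3, n = 5, sep = 4)
    a <- resampling_assign(ft, n_param_reps = 4, n_noise = 7,
                           loocv = cfgi == 2, seed = cfgi)
    counts <- attr(a, "counts")
    expect_true(all(rowSums(counts) == attr(a, "n_sims")))
    expect_equal(attr(a, "n_sims"), 28)
    for (i in seq_len(nrow(a))) {
      expect_equal(counts[i, a$winner[i]], max(counts[i, ]))
      expect_equal(a$confidence[i], counts[i, a$winner[i]] / 28)
    }
  }
})

test_that("zero lab SD makes every outcome identical per individual", {
  ft <- common_mvn_scenario(seed = 5, K = 4, n = 6)
  a <- resampling_assign(ft, lab_sd = 0, n_param_reps = 5, n_noise = 4,
                         seed = 2)
  expect_true(all(a$confidence == 1))
})

test_that("the focal sample never contributes to any fit in its own assignment", {
  ft <- common_mvn_scenario(seed = 8, K = 3, n = 5)
  violations <- 0L
  obs <- function(rep, colony, rows, focal) {
    if (!is.na(focal) && focal %in% rows) violations <<- violations + 1L
  }
  invisible(resampling_assign(ft, n_param_reps = 2, n_noise = 2, loocv = TRUE,
                              seed = 1, fit_observer = obs))
  expect_identical(violations, 0L)
  # too-small colonies are refused under leave-one-out
  tiny <- common_mvn_scenario(seed = 8, K = 3, n = 2)
  expect_error(resampling_assign(tiny, loocv = TRUE, n_param_reps = 1,
                                 n_noise = 1), "leave-one-out")
})

test_that("resampling is deterministic given the seed, in both parameter modes", {
  ft <- common_mvn_scenario(seed = 9, K = 3, n = 6)
  for (mode in c("fresh", "pregenerated")) {
    a1 <- resampling_assign(ft, n_param_reps = 3, n_noise = 4, seed = 11,
                            param_mode = mode)
    a2 <- resampling_assign(ft, n_param_reps = 3, n_noise = 4, seed = 11,
                            param_mode = mode)
    expect_identical(attr(a1, "counts"), attr(a2, "counts"))
    expect_true(all(rowSums(attr(a1, "counts")) == 12))
  }
})

test_that("cross-validation tabulates per-colony success like the standard table", {
  ft <- separated_scenario(seed = 10, K = 4, n = 8, sep = 10)
  cv <- cross_validate(ft, n_param_reps = 5, n_noise = 5, seed = 2)
  expect_named(cv$by_colony, c("colony_id", "n", "n_correct",
                               "proportion_correct"))
  expect_equal(cv$by_colony$n, rep(8L, 4))
  expect_equal(cv$by_colony$proportion_correct,
               cv$by_colony$n_correct / cv$by_colony$n)
  expect_equal(cv$overall, cv$n_correct_total / cv$n_total)
  # 10-SD separated colonies should be nearly perfectly recoverable
  expect_gte(cv$overall, 0.95)
})

test_that("range-success correlation matches the closed-form Pearson oracle", {
  # perfectly anti-monotone linear relation -> r = -1
  K <- 6
  x <- lapply(1:K, function(i)
    cbind(d2H = c(-100 - i, -100 + i), d13C = c(-24, -23), d15N = c(12, 13)))
  ft <- do.call(rbind, Map(function(m, i)
    feathers_from_matrix(m, sprintf("C%d", i)), x, 1:K))
  ft$sample_id <- sprintf("S%03d", seq_len(nrow(ft)))
  by_col <- data.frame(colony_id = sprintf("C%d", 1:K), n = 2L,
                       n_correct = seq(K, 1), # success falls as range grows
                       proportion_correct = seq(K, 1) / K)
  rs <- range_vs_success(ft, by_col, "d2H")
  expect_equal(rs$r, -1, tolerance = 1e-12)

  # random pairs against the explicit sum-formula correlation
  set.seed(13)
  by_col$proportion_correct <- runif(K)
  rs2 <- range_vs_success(ft, by_col, "d2H")
  a <- rs2$data$range; b <- rs2$data$proportion_correct
  r_oracle <- (sum(a * b) - K * mean(a) * mean(b)) /
    sqrt((sum(a^2) - K * mean(a)^2) * (sum(b^2) - K * mean(b)^2))
  expect_equal(rs2$r, r_oracle, tolerance = 1e-12)

  by_col$proportion_correct <- rep(0.5, K)
  expect_error(range_vs_success(ft, by_col, "d2H"), "zero variance")
})
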