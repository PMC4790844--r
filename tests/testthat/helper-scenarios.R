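# Scenario builders and small oracles shared across the test files.

# Feather table straight from matrices (bypasses the generator).
feathers_from_matrix <- function(x, colony_id, latitude = 45, longitude = -100) {
  data.frame(sample_id = sprintf("S%04d", seq_len(nrow(x))),
             colony_id = colony_id,
             latitude = latitude, longitude = longitude,
             d2H = x[, 1], d13C = x[, 2], d15N = x[, 3],
             stringsAsFactors = FALSE)
}

# K colonies all drawn from one common trivariate normal (chance-level
# assignment scenario).
common_mvn_scenario <- function(seed, K = 5, n = 30,
                                mean = c(-100, -24, 12),
                                sds = c(20, 2, 1.5)) {
  cs <- lapply(seq_len(K), function(i)
    colony_spec(sprintf("C%d", i), 40 + i, -100 - i, n, mean, diag(sds^2)))
  generate_feathers(scenario_config(cs, seed = seed))
}

# K colonies whose means are `sep` within-colony SDs apart along d2H.
separated_scenario <- function(seed, K = 4, n = 15, sep = 10, sd_within = 5) {
  cs <- lapply(seq_len(K), function(i)
    colony_spec(sprintf("C%d", i), 40 + i, -100 - i, n,
                c(-150 + (i - 1) * sep * sd_within, -24 + i, 10 + i),
                diag(c(sd_within^2, 1, 1))))
  generate_feathers(scenario_config(cs, seed = seed))
}

# 8 colonies along a d2H gradient; every second colony has 4x the covariance
# (correlation-direction scenario: noisy colonies should assign worse).
heterogeneous_variance_scenario <- function(seed) {
  mH <- seq(-160, -20, length.out = 8)
  cs <- lapply(1:8, function(i) {
    scale <- if (i %% 2 == 0) 4 else 1
    colony_spec(sprintf("C%d", i), 40 + i, -100 - i, 12,
                c(mH[i], -24 + 0.5 * i, 11 + 0.3 * i),
                diag(c(100, 4, 1)) * scale)
  })
  generate_feathers(scenario_config(cs, seed = seed))
}

# Naive dense multivariate-normal log density (explicit inverse/determinant),
# the oracle for the Cholesky-based implementation.
naive_mvn_logdens <- function(x, mu, sigma) {
  d <- as.numeric(x - mu)
  -0.5 * (length(d) * log(2 * pi) + log(det(sigma)) +
            t(d) %*% solve(sigma) %*% d)[1, 1]
}

# Random symmetric positive-definite 3x3 matrix.
random_pd3 <- function() {
  a <- matrix(rnorm(9), 3)
  crossprod(a) + diag(0.5, 3)
}

# Rand index between two labelings.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Deterministic maximum-likelihood classifier: each sample to the colony
# maximizing the naive MVN log density fitted (ML, divisor n) on the
# unperturbed data. Oracle for the degenerate resampling settings.
argmax_classifier <- function(feathers) {
  x <- as.matrix(feathers[, c("d2H", "d13C", "d15N")])
  colonies <- sort(unique(feathers$colony_id))
  fits <- lapply(colonies, function(cc) {
    xi <- x[feathers$colony_id == cc, , drop = FALSE]
    mu <- colMeans(xi)
    xc <- sweep(xi, 2, mu)
    list(mu = mu, sigma = crossprod(xc) / nrow(xi))
  })
  vapply(seq_len(nrow(x)), function(i) {
    ld <- vapply(fits, function(f) naive_mvn_logdens(x[i, ], f$mu, f$sigma),
                 numeric(1))
    colonies[which.max(ld)]
  }, character(1))
}
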