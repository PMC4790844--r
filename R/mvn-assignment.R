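#' Fit a colony's trivariate-normal isotope distribution
#'
#' The colony model is the maximum-likelihood multivariate normal: `mu` is the
#' arithmetic mean and `sigma` the ML covariance (divisor n; set
#' `unbiased = TRUE` for the n-1 divisor), plus `ridge` times the identity.
#' With `auto_ridge = TRUE` a ridge of `1e-6 *` mean diagonal is added
#' whenever the smallest eigenvalue falls below `1e-10 *` the largest, which
#' keeps small colonies (n as low as 6 in three dimensions, smaller still
#' under leave-one-out) numerically positive definite.
#'
#' @param x n x 3 numeric matrix of isotope triplets (rows = feathers), or a
#'   `feather_table`.
#' @param ridge non-negative variance (per mil squared) added to the diagonal.
#' @param colony_id optional label stored in the fit.
#' @param unbiased use the n-1 covariance divisor instead of n.
#' @param auto_ridge regularize automatically when near-singular.
#' @return An object of class `colony_mvn`: list with `colony_id`, `mu`,
#'   `sigma`, `n`.
#' @export
#' @examples
#' x <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
#' fit_colony_mvn(x)$mu
fit_colony_mvn <- function(x, ridge = 0, colony_id = NA_character_,
                           unbiased = FALSE, auto_ridge = FALSE) {
  if (inherits(x, "feather_table") || is.data.frame(x)) x <- iso_matrix(x)
  stopifnot(is.matrix(x), ncol(x) == 3, ridge >= 0)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples to fit a colony distribution")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sigma <- crossprod(xc) / (if (unbiased) n - 1 else n)
  sigma <- sigma + diag(ridge, 3)
  if (auto_ridge) {
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(max(ev), .Machine$double.eps))
      sigma <- sigma + diag(1e-6 * mean(diag(sigma)) + 1e-12, 3)
  }
  if (min_eigen(sigma) <= 0)
    stop("covariance is singular after ridge",
         if (!is.na(colony_id)) paste0(" for colony ", colony_id))
  dimnames(sigma) <- list(ISO_COLS, ISO_COLS)
  structure(list(colony_id = colony_id, mu = setNames(mu, ISO_COLS),
                 sigma = sigma, n = n),
            class = "colony_mvn")
}

# Fast internal fit: returns mean, upper Cholesky factor and half log-det.
# Regularizes via a Cholesky attempt plus a pivot-conditioning check.
fit_mvn_fast <- function(x, ridge = 0, unbiased = FALSE) {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sigma <- crossprod(xc) / (if (unbiased) n - 1 else n) + diag(ridge, 3)
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) < 1e-8 * max(diag(R))) {
    sigma <- sigma + diag(1e-6 * mean(diag(sigma)) + 1e-12, 3)
    R <- chol(sigma)
  }
  list(mu = mu, R = R, hld = sum(log(diag(R))))
}

# Log density rows of x (m x 3) under a fast fit.
dmvn_log_fast <- function(x, fit) {
  z <- backsolve(fit$R, t(x) - fit$mu, transpose = TRUE)
  -0.5 * colSums(z^2) - fit$hld - 1.5 * log(2 * pi)
}

#' Trivariate-normal log density
#'
#' Exact log density of one or more points under a fitted colony model,
#' computed through the Cholesky factor of the covariance for numerical
#' stability.
#'
#' @param x length-3 numeric vector or m x 3 matrix.
#' @param model a `colony_mvn`.
#' @return Numeric vector of log densities (one per row of `x`).
#' @export
#' @examples
#' x <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
#' m <- fit_colony_mvn(x)
#' mvn_log_density(m$mu, m)
mvn_log_density <- function(x, model) {
  stopifnot(inherits(model, "colony_mvn"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == 3)
  R <- tryCatch(chol(model$sigma),
                error = function(e) stop("sigma is not positive definite"))
  fit <- list(mu = model$mu, R = R, hld = sum(log(diag(R))))
  dmvn_log_fast(x, fit)
}

#' Perturb a feather table with analytical measurement noise
#'
#' Error-incorporated resampling replaces every measured isotope value with a
#' normal draw centred on the measurement, with SD equal to the per-isotope
#' lab-standard SD. This is the building block of [resampling_assign()]; one
#' call produces one complete perturbed data set.
#'
#' @param feathers a `feather_table`.
#' @param lab_sd length-3 non-negative numeric (H, C, N), per mil; a single
#'   number is recycled as a pooled scalar SD.
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used (as inside the resampling loop).
#' @return A `feather_table` of the same shape with perturbed isotope values.
#' @export
perturb_dataset <- function(feathers, lab_sd = c(3, 0.2, 0.3), seed = NULL) {
  lab_sd <- rep_len(as.numeric(lab_sd), 3)
  stopifnot(all(lab_sd >= 0))
  if (!is.null(seed)) set.seed(seed)
  out <- feathers
  n <- nrow(out)
  for (j in seq_along(ISO_COLS))
    out[[ISO_COLS[j]]] <- out[[ISO_COLS[j]]] + rnorm(n, 0, lab_sd[j])
  out
}

# Internal engine shared by resampling_assign() and cross_validate().
assign_engine <- function(feathers, lab_sd, n_param_reps, n_noise, loocv,
                          seed, param_mode, ridge, unbiased, fit_observer) {
  iso <- iso_matrix(feathers)
  colony <- factor(feathers$colony_id)
  K <- nlevels(colony)
  n <- nrow(iso)
  lab_sd <- rep_len(as.numeric(lab_sd), 3)
  stopifnot(all(lab_sd >= 0), n_param_reps >= 1, n_noise >= 1)
  idx <- split(seq_len(n), colony)
  sizes <- lengths(idx)
  if (any(sizes < 2L))
    stop("every colony needs >= 2 samples to fit a covariance; apply ",
         "filter_min_colony_size() first")
  if (loocv && any(sizes < 3L))
    stop("leave-one-out requires every colony to retain >= 2 samples after ",
         "removing the focal individual")
  counts <- matrix(0L, n, K, dimnames = list(feathers$sample_id, levels(colony)))
  ldsum <- matrix(0, n, K, dimnames = dimnames(counts))

  set.seed(seed)
  pregen <- NULL
  if (param_mode == "pregenerated") {
    # the original procedure's variant: 100 perturbed data sets are built up
    # front and each outer repetition picks one to define the parameters
    pregen <- lapply(seq_len(n_param_reps), function(r) {
      iso + matrix(rnorm(n * 3), n, 3) %*% diag(lab_sd, 3)
    })
  }
  noise_sd <- rep(lab_sd, each = n_noise)
  for (r in seq_len(n_param_reps)) {
    pert <- if (is.null(pregen)) {
      iso + matrix(rnorm(n * 3), n, 3) %*% diag(lab_sd, 3)
    } else {
      pregen[[sample.int(n_param_reps, 1L)]]
    }
    fits <- vector("list", K)
    for (k in seq_len(K)) {
      fits[[k]] <- fit_mvn_fast(pert[idx[[k]], , drop = FALSE],
                                ridge = ridge, unbiased = unbiased)
      if (!is.null(fit_observer) && !loocv)
        fit_observer(rep = r, colony = levels(colony)[k], rows = idx[[k]],
                     focal = NA_integer_)
    }
    for (i in seq_len(n)) {
      f <- fits
      if (loocv) {
        ci <- as.integer(colony[i])
        keep <- setdiff(idx[[ci]], i)
        f[[ci]] <- fit_mvn_fast(pert[keep, , drop = FALSE],
                                ridge = ridge, unbiased = unbiased)
        if (!is.null(fit_observer))
          for (k in seq_len(K))
            fit_observer(rep = r, colony = levels(colony)[k],
                         rows = if (k == ci) keep else idx[[k]], focal = i)
      }
      pts <- matrix(rep(iso[i, ], each = n_noise) + rnorm(3L * n_noise) * noise_sd,
                    n_noise, 3)
      ld <- vapply(f, function(m) dmvn_log_fast(pts, m), numeric(n_noise))
      ld <- matrix(ld, nrow = n_noise, ncol = K)
      w <- max.col(ld, ties.method = "first")
      counts[i, ] <- counts[i, ] + tabulate(w, K)
      ldsum[i, ] <- ldsum[i, ] + colSums(ld)
    }
  }
  n_sims <- n_param_reps * n_noise
  # winner: maximal count; count ties broken by higher mean log density
  win <- integer(n); tie <- logical(n)
  for (i in seq_len(n)) {
    mx <- max(counts[i, ])
    cand <- which(counts[i, ] == mx)
    tie[i] <- length(cand) > 1L
    win[i] <- if (tie[i]) cand[which.max(ldsum[i, cand])] else cand
  }
  res <- data.frame(
    sample_id = feathers$sample_id,
    colony_id = as.character(feathers$colony_id),
    winner = levels(colony)[win],
    confidence = counts[cbind(seq_len(n), win)] / n_sims,
    tie = tie,
    stringsAsFactors = FALSE)
  structure(res, class = c("assignment_result", "data.frame"),
            counts = counts, n_sims = n_sims,
            mean_log_density = ldsum / n_sims)
}

#' Error-incorporated resampling assignment
#'
#' The maximum-likelihood assignment test with measurement error propagated
#' by resampling. For each of `n_param_reps` outer repetitions, one freshly
#' perturbed data set (see [perturb_dataset()]) defines every colony's
#' trivariate-normal parameters; within the repetition, each of the focal
#' individual's `n_noise` perturbed isotope triplets is assigned to the
#' colony maximizing the log density, so each individual accumulates
#' `n_param_reps * n_noise` assignment outcomes (100 x 100 = 10,000 at the
#' defaults). The winner is the colony with the greatest number of
#' assignments and the confidence is its share of the outcomes (8,000 of
#' 10,000 = 80% confidence). With `loocv = TRUE` the focal individual is
#' excluded from all parameter fits during its own assignment.
#'
#' Count ties for the winner are broken deterministically by the higher mean
#' log density across simulations and flagged in the `tie` column.
#'
#' @param feathers a `feather_table` (already filtered to analyzable colonies).
#' @param lab_sd per-isotope measurement SDs, per mil (default 3, 0.2, 0.3
#'   for H, C, N); a single number acts as a pooled scalar SD.
#' @param n_param_reps outer repetitions (fresh parameter data sets).
#' @param n_noise perturbed triplets assigned per repetition.
#' @param loocv exclude the focal individual from all parameter fits.
#' @param seed integer seed; results are reproducible given the seed.
#' @param param_mode `"fresh"` draws a new parameter data set each repetition;
#'   `"pregenerated"` builds `n_param_reps` data sets up front and each
#'   repetition samples one of them (the literal reading of the original
#'   procedure).
#' @param ridge covariance ridge passed to the fits (per mil squared);
#'   automatic regularization also guards near-singular fits.
#' @param unbiased use n-1 covariance divisor.
#' @param fit_observer optional function(rep, colony, rows, focal) called for
#'   every parameter fit; instrumentation hook used to verify leave-one-out
#'   strictness.
#' @return An `assignment_result` data.frame (`sample_id`, `colony_id`,
#'   `winner`, `confidence`, `tie`) with the full per-colony count matrix in
#'   `attr(, "counts")` and `attr(, "n_sims")`.
#' @export
resampling_assign <- function(feathers, lab_sd = c(3, 0.2, 0.3),
                              n_param_reps = 100, n_noise = 100,
                              loocv = FALSE, seed = 1L,
                              param_mode = c("fresh", "pregenerated"),
                              ridge = 0, unbiased = FALSE,
                              fit_observer = NULL) {
  param_mode <- match.arg(param_mode)
  assign_engine(feathers, lab_sd, n_param_reps, n_noise, loocv, seed,
                param_mode, ridge, unbiased, fit_observer)
}

#' Leave-one-out cross-validation of colony assignment
#'
#' Runs [resampling_assign()] with the leave-one-out exclusion criterion and
#' tabulates, per colony, how many known-origin feathers were assigned back
#' to their true colony, mirroring the standard cross-validation success
#' table (colony, n, n correct, proportion correct) plus the overall
#' proportion and each sample's assignment confidence.
#'
#' @inheritParams resampling_assign
#' @param ... further arguments passed to [resampling_assign()].
#' @return A `crossval_result`: list with `by_colony` (data.frame
#'   `colony_id`, `n`, `n_correct`, `proportion_correct`), `overall`,
#'   `n_total`, `n_correct_total`, and `assignments` (the full
#'   `assignment_result`).
#' @export
cross_validate <- function(feathers, lab_sd = c(3, 0.2, 0.3),
                           n_param_reps = 100, n_noise = 100, seed = 1L, ...) {
  a <- resampling_assign(feathers, lab_sd = lab_sd,
                         n_param_reps = n_param_reps, n_noise = n_noise,
                         loocv = TRUE, seed = seed, ...)
  correct <- a$winner == a$colony_id
  by_col <- aggregate_counts(a$colony_id, correct)
  structure(
    list(by_colony = by_col,
         overall = sum(by_col$n_correct) / sum(by_col$n),
         n_total = sum(by_col$n),
         n_correct_total = sum(by_col$n_correct),
         assignments = a),
    class = "crossval_result")
}

aggregate_counts <- function(colony_id, correct) {
  colony <- factor(colony_id)
  n <- as.integer(table(colony))
  n_correct <- as.integer(tapply(correct, colony, sum))
  data.frame(colony_id = levels(colony), n = n, n_correct = n_correct,
             proportion_correct = n_correct / n,
             stringsAsFactors = FALSE)
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("Leave-one-out cross-validation of colony assignment\n")
  print(x$by_colony, row.names = FALSE)
  cat(sprintf("Overall: %d / %d correct (%.1f%%)\n",
              x$n_correct_total, x$n_total, 100 * x$overall))
  invisible(x)
}

#' Correlate per-colony assignment success with isotopic range
#'
#' Pearson correlation between each colony's proportion of correctly assigned
#' feathers and the within-colony range (max - min) of one isotope, the
#' diagnostic used to show that isotopically noisy colonies assign poorly.
#'
#' @param feathers the `feather_table` the cross-validation was run on.
#' @param cv a `crossval_result` (or its `by_colony` data.frame).
#' @param isotope one of `"d2H"`, `"d13C"`, `"d15N"`.
#' @return list with `r`, `p` (two-sided, t distribution with n-2 df), `n`
#'   (number of colonies), `isotope`, and the per-colony data.frame.
#' @export
range_vs_success <- function(feathers, cv, isotope = c("d2H", "d13C", "d15N")) {
  isotope <- match.arg(isotope)
  by_col <- if (inherits(cv, "crossval_result")) cv$by_colony else cv
  stopifnot(nrow(by_col) >= 3)
  v <- feathers[[isotope]]
  rng <- tapply(v, factor(feathers$colony_id, levels = by_col$colony_id),
                function(z) max(z) - min(z))
  df <- data.frame(colony_id = by_col$colony_id,
                   range = as.numeric(rng),
                   proportion_correct = by_col$proportion_correct,
                   stringsAsFactors = FALSE)
  if (sd(df$range) == 0 || sd(df$proportion_correct) == 0)
    stop("zero variance in range or success; correlation undefined")
  ct <- stats::cor.test(df$range, df$proportion_correct, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(df),
       isotope = isotope, data = df)
}
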