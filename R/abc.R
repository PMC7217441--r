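#' Construct an observed census series
#'
#' A census series records, at a set of (typically sparse and irregular)
#' census years, the fraction of the population mainly speaking each
#' language. Rows are normalised to the simplex on construction; a warning is
#' issued when a row deviates from sum 1 by more than 1e-6, which is common
#' for published census tables rounded to a few digits.
#'
#' @param years strictly increasing integer-valued census years.
#' @param fractions matrix of speaker fractions, one row per census year and
#'   one column per language; entries in \eqn{[0, 1]}.
#' @param names language identifiers; defaults to the column names of
#'   `fractions`.
#' @return an object of class `observed_series`.
#' @export
observed_series <- function(years, fractions, names = NULL) {
  years <- as.numeric(years)
  fractions <- as.matrix(fractions)
  if (is.null(names)) names <- colnames(fractions)
  if (is.null(names)) names <- paste0("lang", seq_len(ncol(fractions)))
  if (length(years) != nrow(fractions))
    stop("`years` must have one entry per row of `fractions`")
  if (length(names) != ncol(fractions))
    stop("`names` must have one entry per column of `fractions`")
  if (any(diff(years) <= 0)) stop("`years` must be strictly increasing")
  if (any(fractions < 0) || any(fractions > 1))
    stop("fractions must lie in [0, 1]")
  sums <- rowSums(fractions)
  if (any(sums <= 0)) stop("every row must have positive total")
  if (any(abs(sums - 1) > 1e-6))
    warning("normalising ", sum(abs(sums - 1) > 1e-6),
            " row(s) whose fractions do not sum to 1")
  fractions <- fractions / sums
  colnames(fractions) <- names
  rownames(fractions) <- NULL
  structure(list(years = years, names = as.character(names),
                 fractions = fractions),
            class = "observed_series")
}

#' @export
print.observed_series <- function(x, ...) {
  cat("Census series:", length(x$years), "census years (",
      x$years[1], "-", x$years[length(x$years)], "),",
      length(x$names), "languages:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.observed_series <- function(x, ...) {
  data.frame(year = x$years, x$fractions, check.names = FALSE)
}

#' Squared-error distance between a census series and a model simulation
#'
#' Simulates the model with yearly Euler steps from the first census year,
#' samples the simulation at each census year, and returns the sum over
#' languages and census time points of the squared differences (no square
#' root). This is the discrepancy the ABC sampler drives down.
#'
#' @param observed an `observed_series`.
#' @param model a `competition_model` whose languages match the series.
#' @param x0 initial fractions at the first census year; defaults to the
#'   first (normalised) observed row, in which case the first time point
#'   contributes zero.
#' @return nonnegative scalar distance.
#' @export
trajectory_distance <- function(observed, model, x0 = NULL) {
  stopifnot(inherits(observed, "observed_series"),
            inherits(model, "competition_model"))
  if (!identical(observed$names, model$names))
    stop("language sets differ between the series (",
         paste(observed$names, collapse = ", "), ") and the model (",
         paste(model$names, collapse = ", "), ")")
  if (is.null(x0)) x0 <- observed$fractions[1, ]
  x0 <- population_state(x0)
  offsets <- observed$years - observed$years[1]
  if (any(abs(offsets - round(offsets)) > 1e-9))
    stop("census years must be whole years apart for yearly sampling")
  cpp_distance(model$utilities, model$alpha, model$beta, x0,
               as.integer(round(offsets)), observed$fractions)
}

#' Prior specification for model calibration
#'
#' The default prior over \eqn{\theta = (\alpha, \beta, s_1..s_n)}: \eqn{\alpha}
#' uniform on `alpha_range`, \eqn{\beta \mid \alpha} uniform on
#' \eqn{[0, \alpha]} (which enforces both bias constraints), and the
#' utilities flat (Dirichlet(1)) on the simplex. The default
#' \eqn{\alpha} range (0, 3) comfortably covers all fitted community values.
#'
#' @param n_languages number of competing languages (>= 2).
#' @param alpha_range length-2 numeric, lower and upper bound for
#'   \eqn{\alpha}; lower bound >= 0.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(n_languages, alpha_range = c(0, 3)) {
  n_languages <- as.integer(n_languages)
  if (n_languages < 2) stop("`n_languages` must be >= 2")
  if (length(alpha_range) != 2 || alpha_range[1] < 0 ||
      diff(alpha_range) <= 0)
    stop("`alpha_range` must be an increasing pair with lower bound >= 0")
  structure(list(n_languages = n_languages,
                 alpha_range = as.numeric(alpha_range)),
            class = "prior_spec")
}

#' Draw parameter particles from the prior
#'
#' @param prior a `prior_spec`.
#' @param n number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return data.frame with columns `alpha`, `beta`, `s1..sn`; each row
#'   satisfies all model invariants.
#' @export
sample_prior <- function(prior, n = 1, seed = NULL) {
  stopifnot(inherits(prior, "prior_spec"))
  if (!is.null(seed)) set.seed(seed)
  k <- prior$n_languages
  alpha <- runif(n, prior$alpha_range[1], prior$alpha_range[2])
  beta <- runif(n, 0, alpha)
  s <- matrix(rexp(n * k), nrow = n)   # Dirichlet(1): normalised exponentials
  s <- s / rowSums(s)
  out <- data.frame(alpha = alpha, beta = beta, s)
  names(out) <- c("alpha", "beta", paste0("s", seq_len(k)))
  out
}

#' Prior density at a parameter vector
#'
#' @param prior a `prior_spec`.
#' @param theta numeric vector `c(alpha, beta, s1..sn)`.
#' @return density value; 0 outside the support.
#' @export
prior_density <- function(prior, theta) {
  stopifnot(inherits(prior, "prior_spec"))
  k <- prior$n_languages
  if (length(theta) != 2 + k) stop("`theta` must have length ", 2 + k)
  if (!theta_in_support(theta, prior)) return(0)
  # uniform alpha x uniform beta|alpha x Dirichlet(1) simplex density
  (1 / diff(prior$alpha_range)) * (1 / theta[1]) * factorial(k - 1)
}

# support check: prior bounds plus all competition_model invariants
theta_in_support <- function(theta, prior) {
  alpha <- theta[1]; beta <- theta[2]; s <- theta[-(1:2)]
  alpha >= prior$alpha_range[1] && alpha <= prior$alpha_range[2] &&
    alpha > 0 && beta >= 0 && beta <= alpha &&
    all(s > 0) && abs(sum(s) - 1) <= 1e-9
}

# free coordinates used by the Gaussian kernel: alpha, beta, s1..s(n-1)
theta_to_coords <- function(theta) theta[-length(theta)]

coords_to_theta <- function(coords) {
  s_free <- coords[-(1:2)]
  c(coords[1:2], s_free, 1 - sum(s_free))
}

theta_is_valid <- function(theta, prior) theta_in_support(theta, prior)

# multivariate normal log-density with a tiny ridge for near-singular kernels
dmvnorm_log <- function(x, mean_mat, sigma) {
  p <- ncol(mean_mat)
  sigma <- sigma + diag(1e-12, p)
  ch <- chol(sigma)
  diffs <- sweep(mean_mat, 2, x)          # mean_j - x per row
  z <- backsolve(ch, t(diffs), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

#' Perturb a particle with a Gaussian kernel
#'
#' Adds multivariate Gaussian noise to the free coordinates
#' \eqn{(\alpha, \beta, s_1..s_{n-1})} and sets \eqn{s_n = 1 - \sum s_i};
#' proposals violating any model invariant (or, when `prior` is supplied,
#' falling outside its support) are rejected and redrawn.
#'
#' @param theta numeric parameter vector `c(alpha, beta, s1..sn)`.
#' @param kernel_covariance symmetric positive semi-definite covariance for
#'   the free coordinates. A zero matrix returns `theta` unchanged.
#' @param prior optional `prior_spec`; when given, proposals must also lie in
#'   its support.
#' @param max_attempts redraw budget before failing with an error.
#' @return a valid perturbed parameter vector.
#' @export
perturb_particle <- function(theta, kernel_covariance, prior = NULL,
                             max_attempts = 1000) {
  k <- length(theta) - 2
  coords <- theta_to_coords(theta)
  if (all(abs(kernel_covariance) < 1e-300)) return(theta)
  ch <- chol(kernel_covariance + diag(1e-12, length(coords)))
  if (is.null(prior)) prior <- prior_spec(k, c(0, Inf))
  for (attempt in seq_len(max_attempts)) {
    prop <- coords + as.numeric(rnorm(length(coords)) %*% ch)
    cand <- coords_to_theta(prop)
    if (theta_is_valid(cand, prior)) return(cand)
  }
  stop("perturbation failed to produce a valid particle after ",
       max_attempts, " attempts; the kernel covariance may be too wide")
}

#' Importance weight of a particle against the previous ensemble
#'
#' Computes the ABC-SMC weight: the prior density at \eqn{\theta} divided by
#' the kernel-mixture density \eqn{\sum_j w_j K(\theta \mid \theta_j, \Sigma)}
#' over the previous weighted ensemble. Weights are unnormalised; callers
#' renormalise the full ensemble to sum 1.
#'
#' @param theta parameter vector of the new particle.
#' @param previous_thetas matrix of previous-iteration particles, one row per
#'   particle, columns `alpha, beta, s1..sn`.
#' @param previous_weights normalised weights of the previous ensemble.
#' @param kernel_covariance the kernel covariance used for perturbation.
#' @param prior a `prior_spec`.
#' @return unnormalised weight (>= 0).
#' @export
compute_weight <- function(theta, previous_thetas, previous_weights,
                           kernel_covariance, prior) {
  pd <- prior_density(prior, theta)
  if (pd == 0) return(0)
  prev_coords <- previous_thetas[, -ncol(previous_thetas), drop = FALSE]
  logk <- dmvnorm_log(theta_to_coords(theta), prev_coords,
                      kernel_covariance)
  denom <- sum(previous_weights * exp(logk))
  if (denom <= 0)
    stop("zero kernel-mixture density in weight computation")
  pd / denom
}

# twice the weighted (ML) empirical covariance of the free coordinates
kernel_covariance_of <- function(thetas, weights) {
  coords <- thetas[, -ncol(thetas), drop = FALSE]
  2 * cov.wt(coords, wt = weights, method = "ML")$cov
}

#' Calibrate a competition model to a census series with ABC-SMC
#'
#' Sequential Monte Carlo approximate Bayesian computation. Iteration 0
#' rejection-samples particles from the prior until their simulation distance
#' ([trajectory_distance()]) falls below an initial tolerance; later
#' iterations resample from the previous weighted ensemble, perturb with a
#' Gaussian kernel whose covariance is twice the weighted empirical
#' covariance of the ensemble, re-simulate, and accept under a decreasing
#' tolerance. Tolerances are set adaptively to the `accept_quantile` of the
#' previous iteration's accepted distances, which makes the tolerance
#' schedule non-increasing by construction. The default quantile of 0.5
#' halves the retained distance mass each iteration; flatter schedules
#' (e.g. 0.75) shrink the tolerance too slowly to concentrate the ensemble
#' within a few tens of iterations on census-like series.
#'
#' The initial state for every candidate simulation is the first observed
#' census row; it is not a fitted parameter.
#'
#' @param observed an `observed_series`.
#' @param prior a `prior_spec`; defaults to [prior_spec()] for the series'
#'   language count.
#' @param n_particles ensemble size (>= 2); default 100.
#' @param max_iterations iteration cap; default 50.
#' @param seed integer seed; all randomness flows through it, so identical
#'   seeds and settings give bit-identical ensembles.
#' @param accept_quantile quantile of the previous accepted distances used as
#'   the next tolerance; default 0.5.
#' @param min_improvement early-stop threshold: stop when the tolerance would
#'   improve by less than this relative fraction; default 0.01.
#' @param max_attempts per-particle simulator-call budget within one
#'   iteration; exceeding it aborts with a diagnostic. Default 1e5.
#' @param pilot number of prior draws used to set the initial tolerance;
#'   default `4 * n_particles`.
#' @param verbose print one line per iteration.
#' @return an object of class `abc_posterior`: list with `particles`
#'   (data.frame `alpha, beta, s<language>.., weight, distance`), `iteration`
#'   (last completed), `tolerance`, `kernel_covariance`, and `trace`
#'   (per-iteration tolerance plus mean and sd of the normalised distance
#'   `distance / (n_census_years * n_languages)` across particles).
#' @export
run_abc_smc <- function(observed, prior = NULL, n_particles = 100,
                        max_iterations = 50, seed = NULL,
                        accept_quantile = 0.5, min_improvement = 0.01,
                        max_attempts = 1e5, pilot = 4 * n_particles,
                        verbose = FALSE) {
  stopifnot(inherits(observed, "observed_series"))
  if (n_particles < 2) stop("`n_particles` must be >= 2")
  k <- length(observed$names)
  if (is.null(prior)) prior <- prior_spec(k)
  if (prior$n_languages != k)
    stop("prior dimension does not match the series")
  if (!is.null(seed)) set.seed(seed)

  x0 <- observed$fractions[1, ]
  offsets <- as.integer(round(observed$years - observed$years[1]))
  dist_of <- function(theta) {
    cpp_distance(theta[-(1:2)], theta[1], theta[2], x0, offsets,
                 observed$fractions)
  }
  norm_const <- length(observed$years) * k

  # pilot prior sample sets the initial tolerance
  pilot_draws <- sample_prior(prior, n = pilot)
  pilot_d <- apply(as.matrix(pilot_draws), 1, dist_of)
  eps <- unname(quantile(pilot_d, accept_quantile))

  thetas <- matrix(NA_real_, n_particles, 2 + k)
  dists <- numeric(n_particles)
  for (i in seq_len(n_particles)) {
    attempts <- 0
    repeat {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("iteration 0: particle ", i, " exceeded ", max_attempts,
             " attempts at tolerance ", signif(eps, 4))
      th <- as.numeric(sample_prior(prior, n = 1))
      d <- dist_of(th)
      if (d <= eps) break
    }
    thetas[i, ] <- th
    dists[i] <- d
  }
  weights <- rep(1 / n_particles, n_particles)
  kcov <- kernel_covariance_of(thetas, weights)
  trace <- data.frame(iteration = 0, tolerance = eps,
                      mean_norm_distance = mean(dists) / norm_const,
                      sd_norm_distance = stats::sd(dists) / norm_const)
  iteration <- 0

  for (t in seq_len(max_iterations)) {
    eps_new <- unname(quantile(dists, accept_quantile))
    if (eps_new <= 0 || (eps - eps_new) / eps < min_improvement) break
    eps <- eps_new
    new_thetas <- matrix(NA_real_, n_particles, 2 + k)
    new_dists <- numeric(n_particles)
    for (i in seq_len(n_particles)) {
      attempts <- 0
      repeat {
        attempts <- attempts + 1
        if (attempts > max_attempts)
          stop("iteration ", t, ": particle ", i, " exceeded ",
               max_attempts, " attempts at tolerance ", signif(eps, 4))
        j <- sample.int(n_particles, 1, prob = weights)
        th <- tryCatch(
          perturb_particle(thetas[j, ], kcov, prior),
          error = function(e) NULL)
        if (is.null(th)) next
        d <- dist_of(th)
        if (d <= eps) break
      }
      new_thetas[i, ] <- th
      new_dists[i] <- d
    }
    new_weights <- vapply(seq_len(n_particles), function(i)
      compute_weight(new_thetas[i, ], thetas, weights, kcov, prior),
      numeric(1))
    new_weights <- new_weights / sum(new_weights)
    thetas <- new_thetas
    dists <- new_dists
    weights <- new_weights
    kcov <- kernel_covariance_of(thetas, weights)
    iteration <- t
    trace <- rbind(trace, data.frame(
      iteration = t, tolerance = eps,
      mean_norm_distance = mean(dists) / norm_const,
      sd_norm_distance = stats::sd(dists) / norm_const))
    if (verbose)
      message(sprintf("iteration %d: eps = %.5g, mean norm distance = %.5g",
                      t, eps, mean(dists) / norm_const))
  }

  particles <- data.frame(thetas, weight = weights, distance = dists)
  names(particles) <- c("alpha", "beta", paste0("s_", observed$names),
                        "weight", "distance")
  structure(list(particles = particles, iteration = iteration,
                 tolerance = eps, kernel_covariance = kcov, trace = trace,
                 languages = observed$names, prior = prior),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("ABC-SMC posterior:", nrow(x$particles), "particles after",
      x$iteration, "iterations (final tolerance",
      signif(x$tolerance, 4), ")\n")
  print(summarize_posterior(x), row.names = FALSE)
  invisible(x)
}

#' Point estimates and spreads from a posterior ensemble
#'
#' Weighted means and weighted standard deviations per parameter; the
#' utility means are renormalised onto the simplex.
#'
#' @param ensemble an `abc_posterior`.
#' @return data.frame with columns `parameter`, `mean`, `sd`.
#' @export
summarize_posterior <- function(ensemble) {
  stopifnot(inherits(ensemble, "abc_posterior"))
  p <- ensemble$particles
  w <- p$weight / sum(p$weight)
  pars <- setdiff(names(p), c("weight", "distance"))
  mu <- vapply(pars, function(nm) sum(w * p[[nm]]), numeric(1))
  sd_ <- vapply(pars, function(nm)
    sqrt(max(0, sum(w * (p[[nm]] - mu[nm])^2))), numeric(1))
  s_idx <- grep("^s_", pars)
  mu[s_idx] <- mu[s_idx] / sum(mu[s_idx])
  data.frame(parameter = pars, mean = unname(mu), sd = unname(sd_))
}
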