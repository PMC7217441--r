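test_that("series constructor validates and normalises census rows", {
  s <- observed_series(c(1957, 1970), rbind(c(0.5, 0.5), c(0.6, 0.4)),
                       c("a", "b"))
  expect_s3_class(s, "observed_series")
  expect_error(observed_series(c(1970, 1957), rbind(c(0.5, 0.5), c(0.6, 0.4))),
               "increasing")
  expect_warning(
    s2 <- observed_series(1957, matrix(c(0.018, 0.975, 0.001), 1)),
    "normalising")
  expect_equal(sum(s2$fractions), 1)
})

test_that("trajectory distance is zero in-loop and additive in squared error", {
  m <- singapore_model()
  x0 <- singapore_x0()
  ser <- generate_observed_series(m, x0, noise_sd = 0)
  expect_equal(trajectory_distance(ser, m), 0, tolerance = 1e-20)
  # perturbing one census row by (+0.1, -0.1) adds exactly 0.1^2 + 0.1^2
  m2 <- competition_model(c(0.6, 0.4), alpha = 1, beta = 0.5,
                          names = c("a", "b"))
  x02 <- c(0.4, 0.6)
  row1 <- step_population(x02, m2, dt = 1)
  obs <- observed_series(c(2000, 2001), rbind(c(0.5, 0.5), row1), c("a", "b"))
  expect_equal(trajectory_distance(obs, m2, x0 = x02), 0.02)
  # language sets must match
  m3 <- competition_model(c(0.6, 0.4), 1, 0.5, names = c("x", "y"))
  expect_error(trajectory_distance(obs, m3), "language sets differ")
})

test_that("prior draws are reproducible and respect every constraint", {
  pr <- prior_spec(3)
  expect_identical(sample_prior(pr, 5, seed = 11), sample_prior(pr, 5, seed = 11))
  dr <- sample_prior(pr, 10000, seed = 2)
  s <- as.matrix(dr[, 3:5])
  expect_true(all(dr$beta >= 0))
  expect_true(all(dr$alpha - dr$beta >= 0))
  expect_true(all(s > 0))
  expect_equal(rowSums(s), rep(1, nrow(s)), tolerance = 1e-12)
  # flat simplex prior: each component mean is 1/3 within 3 standard errors
  se <- sqrt(1 / 18 / nrow(s))
  for (j in 1:3) expect_lt(abs(mean(s[, j]) - 1 / 3), 3 * se)
})

test_that("prior density matches its uniform-by-parts construction", {
  pr <- prior_spec(3, alpha_range = c(0, 3))
  th <- c(1.5, 0.5, 0.3, 0.3, 0.4)
  expect_equal(prior_density(pr, th), (1 / 3) * (1 / 1.5) * factorial(2))
  expect_equal(prior_density(pr, c(3.5, 0.5, 0.3, 0.3, 0.4)), 0)
  expect_equal(prior_density(pr, c(1.5, 1.6, 0.3, 0.3, 0.4)), 0)
  expect_equal(prior_density(pr, c(1.5, 0.5, 0.8, 0.1, 0.1)),
               prior_density(pr, th))  # flat over the simplex
})

test_that("particle perturbation preserves the constraints", {
  pr <- prior_spec(3)
  th <- c(1.0, 0.76, 0.35, 0.29, 0.36)
  # zero covariance leaves the particle unchanged
  expect_identical(perturb_particle(th, matrix(0, 4, 4), pr), th)
  set.seed(3)
  kc <- diag(c(0.05, 0.05, 0.01, 0.01))
  for (i in 1:200) {
    out <- perturb_particle(th, kc, pr)
    expect_true(out[2] >= 0 && out[1] >= out[2] && all(out[3:5] > 0))
    expect_equal(sum(out[3:5]), 1, tolerance = 1e-12)
  }
})

test_that("perturbation kernel has the requested covariance away from bounds", {
  # wide prior bounds and a particle far from every constraint: acceptance
  # is ~1, so the sample covariance should approach the kernel covariance
  pr <- prior_spec(3, alpha_range = c(0, 100))
  th <- c(50, 25, 1 / 3, 1 / 3, 1 / 3)
  kc <- diag(c(0.04, 0.04, 0.002, 0.002))
  set.seed(4)
  draws <- t(replicate(4000, perturb_particle(th, kc, pr)[1:4]))
  emp <- stats::cov(draws)
  expect_equal(diag(emp), diag(kc), tolerance = 0.15)
  expect_lt(max(abs(emp[upper.tri(emp)])), 0.01)
})

test_that("importance weights reduce to the closed-form Gaussian case", {
  pr <- prior_spec(2, alpha_range = c(0, 3))
  th <- c(1.0, 0.5, 0.6, 0.4)
  prev <- matrix(th, nrow = 1)
  kc <- diag(c(0.1, 0.1, 0.05))
  # N = 1, theta equal to the single previous particle:
  # weight = pi(theta) / K(theta | theta, Sigma) with K the mvnormal mode
  k_at_mode <- (2 * pi)^(-3 / 2) / sqrt(det(kc))
  expect_equal(compute_weight(th, prev, 1, kc, pr),
               prior_density(pr, th) / k_at_mode, tolerance = 1e-10)
  expect_equal(compute_weight(c(5, 0.5, 0.6, 0.4), prev, 1, kc, pr), 0)
})

test_that("ABC-SMC is seed-deterministic with normalised weights and a
           non-increasing tolerance trace", {
  m <- singapore_model()
  set.seed(9)
  ser <- generate_observed_series(m, c(0.1, 0.8, 0.1), noise_sd = 0.005)
  p1 <- run_abc_smc(ser, n_particles = 30, max_iterations = 6, seed = 5)
  p2 <- run_abc_smc(ser, n_particles = 30, max_iterations = 6, seed = 5)
  expect_identical(p1$particles, p2$particles)
  expect_equal(sum(p1$particles$weight), 1, tolerance = 1e-9)
  expect_true(all(p1$particles$distance <= p1$tolerance))
  expect_true(all(diff(p1$trace$tolerance) <= 0))
  expect_true(all(diff(p1$trace$mean_norm_distance) <= 1e-12))
  # iteration 0 only: weights are uniform 1/N
  p0 <- run_abc_smc(ser, n_particles = 20, max_iterations = 0, seed = 5)
  expect_equal(p0$particles$weight, rep(1 / 20, 20))
})

test_that("the posterior contracts relative to the prior across seeds", {
  m <- singapore_model()
  pr <- prior_spec(3)
  prior_sd <- vapply(sample_prior(pr, 5000, seed = 1)[, 1:2], stats::sd,
                     numeric(1))
  shrunk <- sapply(1:5, function(seed) {
    set.seed(seed)
    ser <- generate_observed_series(m, c(0.1, 0.8, 0.1), noise_sd = 0.005)
    post <- run_abc_smc(ser, n_particles = 30, max_iterations = 8,
                        seed = seed)
    sm <- summarize_posterior(post)
    sm$sd[match(c("alpha", "beta"), sm$parameter)]
  })
  # average posterior spread well below the prior spread for both exponents
  expect_lt(mean(shrunk[1, ]), prior_sd[["alpha"]] / 2)
  expect_lt(mean(shrunk[2, ]), prior_sd[["beta"]] / 2)
})

test_that("posterior summaries use the particle weights", {
  part <- data.frame(alpha = c(1, 2), beta = c(0.5, 1),
                     s_a = c(0.6, 0.4), s_b = c(0.4, 0.6),
                     weight = c(0.5, 0.5), distance = c(0.1, 0.1))
  post <- structure(list(particles = part, iteration = 1, tolerance = 0.2,
                         languages = c("a", "b")),
                    class = "abc_posterior")
  sm <- summarize_posterior(post)
  expect_equal(sm$mean[sm$parameter == "alpha"], 1.5)  # equal weights
  expect_equal(sum(sm$mean[grepl("^s_", sm$parameter)]), 1)
  # a point mass has zero spread and reproduces the particle
  part2 <- part
  part2$weight <- c(1, 0)
  post2 <- post
  post2$particles <- part2
  sm2 <- summarize_posterior(post2)
  expect_equal(sm2$mean[sm2$parameter == "alpha"], 1)
  expect_equal(sm2$sd[sm2$parameter == "alpha"], 0)
})
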