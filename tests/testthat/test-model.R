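test_that("model constructor enforces the parameter invariants", {
  expect_s3_class(competition_model(c(0.5, 0.5), 1, 0.5), "competition_model")
  expect_error(competition_model(c(0.6, 0.5), 1, 0.5), "sum to 1")
  expect_error(competition_model(c(0.5, 0.5), 1, -0.1), ">= 0")
  expect_error(competition_model(c(0.5, 0.5), 0.4, 0.5), "alpha - beta")
  expect_error(competition_model(c(-0.1, 1.1), 1, 0.5), "nonnegative")
  expect_error(competition_model(c(0.5, 0.5), 1, 0.5, names = c("a", "a")),
               "unique")
  expect_error(population_state(c(0.6, 0.6)), "sum to 1")
  expect_error(population_state(c(-0.2, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise rates match hand-computed values and check preconditions", {
  # alpha = beta collapses the aversion term: rate = s_i * x_i
  expect_equal(pairwise_rate(0.5, 0.4, 0.6, alpha = 1, beta = 1), 0.20)
  # an extinct target with beta > 0 attracts nobody
  expect_equal(pairwise_rate(0.36, 0, 0.5, alpha = 1.0, beta = 0.76), 0)
  # on the two-language diagonal x_j = 1 - x_i the exponents add: s_i x_i^alpha
  expect_equal(pairwise_rate(0.35, 0.3, 0.7, alpha = 1.0, beta = 0.76),
               0.35 * 0.3)
  # 0^0 convention: beta = 0 lets an extinct language gain speakers
  expect_equal(pairwise_rate(0.4, 0, 0.5, alpha = 0.5, beta = 0),
               0.4 * 0.5^0.5)
  expect_error(pairwise_rate(0, 0.5, 0.5, 1, 0.5), "> 0")
  expect_error(pairwise_rate(0.5, 1.2, 0.5, 1, 0.5), "\\[0, 1\\]")
  expect_error(pairwise_rate(0.5, 0.5, 0.5, 0.4, 0.5), "alpha - beta")
})

test_that("flow vanishes at symmetric points and absorbing vertices", {
  m <- competition_model(rep(1 / 3, 3), alpha = 1.2, beta = 0.8)
  expect_equal(unname(flow_derivative(rep(1 / 3, 3), m)), rep(0, 3))
  # any vertex is a fixed point when beta > 0
  for (i in 1:3) {
    v <- rep(0, 3); v[i] <- 1
    expect_equal(unname(flow_derivative(v, singapore_model())), rep(0, 3))
  }
})

test_that("flow components cancel pairwise (simplex conservation)", {
  set.seed(42)
  for (rep_i in 1:25) {
    n <- sample(2:5, 1)
    b <- runif(1, 0, 1.5)
    m <- competition_model(random_simplex(n), alpha = b + runif(1, 0, 1),
                           beta = b)
    dx <- flow_derivative(random_simplex(n), m)
    expect_lt(abs(sum(dx)), 1e-12)
  }
})

test_that("two-language dynamics equal the classical closed form", {
  # the aversion/preference split must not matter for n = 2, because
  # 1 - x_j = x_i makes the exponents recombine into x^alpha
  for (x1 in seq(0.05, 0.95, by = 0.15)) {
    for (s1 in c(0.3, 0.5, 0.7)) {
      for (alpha in c(0.5, 1.0, 1.31)) {
        for (beta in c(0, 0.25 * alpha, alpha)) {
          m <- competition_model(c(s1, 1 - s1), alpha, beta)
          dx <- flow_derivative(c(x1, 1 - x1), m)
          expect_equal(unname(dx[1]), as_two_language_oracle(x1, s1, alpha),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # the worked value from the closed form
  expect_equal(as_two_language_oracle(0.7, 0.6, 1.31), 0.05498, tolerance = 1e-3)
  m <- competition_model(c(0.6, 0.4), 1.31, 0.5)
  expect_equal(unname(flow_derivative(c(0.7, 0.3), m)[1]),
               as_two_language_oracle(0.7, 0.6, 1.31))
})

test_that("Euler steps stay on the simplex and converge at order dt^2", {
  m <- singapore_model()
  x <- c(0.3, 0.45, 0.25)
  expect_equal(sum(step_population(x, m, dt = 1)), 1, tolerance = 1e-12)
  # a zero-derivative point does not move
  sym <- competition_model(rep(1 / 3, 3), 1.2, 0.8)
  expect_equal(step_population(rep(1 / 3, 3), sym, dt = 1), rep(1 / 3, 3))
  # Richardson: one dt step vs two dt/2 steps differs at O(dt^2)
  err <- sapply(c(1, 0.5, 0.25), function(dt) {
    full <- step_population(x, m, dt)
    half <- step_population(step_population(x, m, dt / 2), m, dt / 2)
    max(abs(full - half))
  })
  expect_lt(err[2], err[1] / 2)
  expect_lt(err[3], err[2] / 2)
})

test_that("the compiled integrator agrees with the reference R stepper", {
  m <- singapore_model()
  x0 <- singapore_x0()
  tr <- simulate_trajectory(m, x0, horizon = 25, dt = 1)
  x <- unname(x0)
  for (k in 1:25) x <- step_population(x, m, dt = 1)
  expect_equal(unname(tr$fractions[26, ]), x, tolerance = 1e-14)
  expect_equal(nrow(tr$fractions), 26)
  expect_true(all(abs(rowSums(tr$fractions) - 1) <= 1e-9))
})

test_that("trajectories from a vertex are constant and re-simulation is exact", {
  m <- singapore_model()
  tr <- simulate_trajectory(m, c(1, 0, 0), horizon = 10)
  expect_true(all(tr$fractions[, 1] == 1))
  tr1 <- simulate_trajectory(m, singapore_x0(), horizon = 40)
  tr2 <- simulate_trajectory(m, singapore_x0(), horizon = 40)
  expect_identical(tr1$fractions, tr2$fractions)
})

test_that("state classification separates dominance from coexistence", {
  lab <- classify_state(c(0.9995, 0.0003, 0.0002), 1e-3,
                        names = c("a", "b", "c"))
  expect_equal(lab$kind, "dominance")
  expect_equal(lab$top_language, "a")
  expect_equal(lab$survivors, "a")
  lab2 <- classify_state(c(0.5, 0.3, 0.2), 1e-3, names = c("a", "b", "c"))
  expect_equal(lab2$kind, "coexistence")
  expect_equal(lab2$top_language, "a")
  expect_length(lab2$survivors, 3)
  # ties go to the lowest index
  expect_equal(classify_state(c(0.5, 0.5), names = c("x", "y"))$top_language,
               "x")
  expect_error(classify_state(c(0.3, 0.3, 0.4), 0.6), "\\(0, 0.5\\)")
  expect_error(classify_state(c(1e-5, 1e-5, 1e-5), 1e-2), "degenerate")
})

test_that("steady-state search honours its tolerance semantics", {
  m <- singapore_model()
  x0 <- singapore_x0()
  ss <- find_steady_state(m, x0)
  expect_true(ss$converged)
  expect_equal(ss$label$kind, "coexistence")
  expect_equal(ss$label$top_language, "Mandarin")
  # tau is non-increasing as the tolerance loosens
  tau6 <- find_steady_state(m, x0, tol = 1e-6)$tau
  tau4 <- find_steady_state(m, x0, tol = 1e-4)$tau
  expect_gte(tau6, tau4)
  # starting at the converged equilibrium terminates within one step
  ss0 <- find_steady_state(m, ss$equilibrium / sum(ss$equilibrium))
  expect_lte(ss0$tau, 1)
  # never-converging caps at max_time without error
  ssn <- find_steady_state(m, x0, tol = 1e-30, max_time = 50)
  expect_false(ssn$converged)
  expect_equal(ssn$tau, 50)
})

test_that("relabelling languages permutes every output identically", {
  m <- singapore_model()
  x <- c(0.25, 0.6, 0.15)
  perm <- c(3, 1, 2)
  mp <- competition_model(m$utilities[perm], m$alpha, m$beta, m$names[perm])
  expect_equal(unname(flow_derivative(x, m)[perm]),
               unname(flow_derivative(x[perm], mp)))
  ss <- find_steady_state(m, x)
  ssp <- find_steady_state(mp, x[perm])
  expect_equal(unname(ss$equilibrium[perm]), unname(ssp$equilibrium))
  expect_equal(ss$label$kind, ssp$label$kind)
  expect_equal(ss$label$top_language, ssp$label$top_language)
})

test_that("steady-state labels are robust to halving the step size", {
  for (fx in builtin_fixtures()) {
    m <- fixture_model(fx)
    x0 <- fixture_initials(fx)
    l1 <- find_steady_state(m, x0, dt = 1)$label
    l01 <- find_steady_state(m, x0, dt = 0.5)$label
    expect_equal(l1$kind, l01$kind, label = fx$name)
    expect_equal(l1$top_language, l01$top_language, label = fx$name)
  }
})
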