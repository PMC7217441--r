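#' Built-in fitted community fixtures
#'
#' Four fitted parameter sets for real language-competition communities,
#' as printed in the source study: Singapore (whole country), the Chinese
#' community of Singapore, the Indian community of Singapore, and Hong Kong.
#' Every numeric field carries a provenance tag: `"printed"` for values
#' printed in the study, `"assumed"` for values the study does not print
#' (these are deterministic defaults, never presented as study values).
#'
#' Only the Singapore whole-country fixture has all initial fractions
#' printed (1957 census: English 0.018, Dialect 0.975, Mandarin 0.001,
#' normalised before use). For the other three communities only the largest
#' initial fraction is printed; the remaining mass is split evenly among the
#' other languages and tagged `"assumed"`. The printed Hong Kong utilities
#' (0.30, 0.26, 0.27, 0.18) sum to 1.01 due to rounding and are renormalised
#' onto the simplex.
#'
#' @return named list of `dataset_fixture` objects with elements
#'   `singapore`, `chinese_community`, `indian_community`, `hong_kong`.
#'   Each fixture has fields `name`, `languages`, `alpha`, `beta`,
#'   `utilities`, `census_years`, `initials_raw` (pre-normalisation), and
#'   `provenance` (a tag per field).
#' @examples
#' fx <- builtin_fixtures()
#' names(fx)
#' fixture_model(fx$singapore)
#' @export
builtin_fixtures <- function() {
  list(
    singapore = dataset_fixture(
      name = "singapore",
      languages = c("English", "Dialect", "Mandarin"),
      alpha = 1.00, beta = 0.76,
      utilities = c(0.35, 0.29, 0.36),
      census_years = c(1957, 1970, 1980, 1990, 2000, 2010),
      initials_raw = c(0.018, 0.975, 0.001),
      provenance = list(
        alpha = "printed", beta = "printed",
        utilities = rep("printed", 3),
        initials = rep("printed", 3),
        census_years = c("printed", rep("assumed", 4), "printed"))),
    chinese_community = dataset_fixture(
      name = "chinese_community",
      languages = c("English", "Dialect", "Mandarin"),
      alpha = 0.90, beta = 0.87,
      utilities = c(0.34, 0.29, 0.37),
      census_years = c(1957, 1970, 1980, 1990, 2000, 2010),
      initials_raw = c((1 - 0.766) / 2, 0.766, (1 - 0.766) / 2),
      provenance = list(
        alpha = "printed", beta = "printed",
        utilities = rep("printed", 3),
        initials = c("assumed", "printed", "assumed"),
        census_years = c("printed", rep("assumed", 4), "printed"))),
    indian_community = dataset_fixture(
      name = "indian_community",
      languages = c("English", "Tamil", "Malay"),
      alpha = 1.06, beta = 0.10,
      # printed values sum to 1.01; renormalised to satisfy sum(s) = 1
      utilities = c(0.41, 0.40, 0.20) / sum(c(0.41, 0.40, 0.20)),
      census_years = c(1957, 1970, 1980, 1990, 2000, 2010),
      initials_raw = c((1 - 0.613) / 2, 0.613, (1 - 0.613) / 2),
      provenance = list(
        alpha = "printed", beta = "printed",
        utilities = rep("printed (renormalised, printed sum 1.01)", 3),
        initials = c("assumed", "printed", "assumed"),
        census_years = c("printed", rep("assumed", 4), "printed"))),
    hong_kong = dataset_fixture(
      name = "hong_kong",
      languages = c("English", "Hakka", "Hoklo", "Sze Yap"),
      alpha = 1.21, beta = 0.90,
      # printed values sum to 1.01; renormalised to satisfy sum(s) = 1
      utilities = c(0.30, 0.26, 0.27, 0.18) / sum(c(0.30, 0.26, 0.27, 0.18)),
      census_years = c(1949, 1961, 1975, 1990, 2005, 2016),
      initials_raw = c((1 - 0.578) / 3, (1 - 0.578) / 3, (1 - 0.578) / 3,
                       0.578),
      provenance = list(
        alpha = "printed", beta = "printed",
        utilities = rep("printed (renormalised, printed sum 1.01)", 4),
        initials = c("assumed", "assumed", "assumed", "printed"),
        census_years = c("printed", rep("assumed", 4), "printed"))))
}

dataset_fixture <- function(name, languages, alpha, beta, utilities,
                            census_years, initials_raw, provenance) {
  # fixture parameters must form a valid model up-front
  competition_model(utilities, alpha, beta, languages)
  stopifnot(length(initials_raw) == length(languages),
            all(initials_raw >= 0), sum(initials_raw) > 0,
            all(diff(census_years) > 0))
  structure(list(name = name, languages = languages, alpha = alpha,
                 beta = beta, utilities = utilities,
                 census_years = census_years, initials_raw = initials_raw,
                 provenance = provenance),
            class = "dataset_fixture")
}

#' @export
print.dataset_fixture <- function(x, ...) {
  cat("Dataset fixture '", x$name, "': ",
      paste(x$languages, collapse = ", "), "\n", sep = "")
  cat(sprintf("  alpha = %.3g, beta = %.3g; utilities: %s\n", x$alpha,
              x$beta, paste(signif(x$utilities, 3), collapse = ", ")))
  cat("  initial fractions (raw):",
      paste(sprintf("%s = %.3g [%s]", x$languages, x$initials_raw,
                    x$provenance$initials), collapse = ", "), "\n")
  invisible(x)
}

#' Model and initial state of a fixture
#'
#' @param fixture a `dataset_fixture` from [builtin_fixtures()].
#' @return `fixture_model()` returns the `competition_model`;
#'   `fixture_initials()` the initial fractions, normalised onto the simplex
#'   by default (printed census rows sum to slightly less than 1).
#' @export
fixture_model <- function(fixture) {
  stopifnot(inherits(fixture, "dataset_fixture"))
  competition_model(fixture$utilities, fixture$alpha, fixture$beta,
                    fixture$languages)
}

#' @rdname fixture_model
#' @param normalize divide by the sum so the state lies on the simplex.
#' @export
fixture_initials <- function(fixture, normalize = TRUE) {
  stopifnot(inherits(fixture, "dataset_fixture"))
  x <- fixture$initials_raw
  if (normalize) x <- x / sum(x)
  setNames(x, fixture$languages)
}

#' Does a fixture rely on any assumed (unprinted) value?
#'
#' @param fixture a `dataset_fixture`.
#' @param fields which provenance fields to inspect; defaults to the ones
#'   that enter model computations.
#' @return TRUE when every inspected value is printed in the study.
#' @export
fixture_fully_printed <- function(fixture,
                                  fields = c("alpha", "beta", "utilities",
                                             "initials")) {
  stopifnot(inherits(fixture, "dataset_fixture"))
  tags <- unlist(fixture$provenance[fields])
  !any(grepl("assumed", tags))
}

#' Generate a census-like synthetic series from a model
#'
#' Simulates the dynamics with yearly Euler steps, samples the trajectory at
#' the census years, adds independent Gaussian observation noise per entry,
#' clips to \eqn{[0, 1]} and renormalises each row onto the simplex. With
#' `noise_sd = 0` the rows equal the exact simulated states. Fully
#' reproducible under a fixed seed.
#'
#' @param model a `competition_model`.
#' @param x0 initial fractions at the first census year.
#' @param census_years strictly increasing integer years; default emulates
#'   the sparse 1957-2010 census spacing (6 points over 53 years).
#' @param noise_sd standard deviation of the additive observation noise, in
#'   fraction units; default 0.
#' @param seed optional integer seed.
#' @return an `observed_series`.
#' @export
generate_observed_series <- function(model, x0,
                                     census_years = c(1957, 1970, 1980,
                                                      1990, 2000, 2010),
                                     noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "competition_model"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x0 <- population_state(x0)
  offsets <- census_years - census_years[1]
  if (any(abs(offsets - round(offsets)) > 1e-9))
    stop("census years must be whole years")
  tr <- simulate_trajectory(model, x0, horizon = max(offsets), dt = 1,
                            t0 = census_years[1])
  rows <- tr$fractions[round(offsets) + 1, , drop = FALSE]
  if (noise_sd > 0) {
    rows <- rows + matrix(rnorm(length(rows), sd = noise_sd), nrow(rows))
    rows <- pmin(pmax(rows, 0), 1)
    sums <- rowSums(rows)
    if (any(sums <= 0)) stop("noise wiped out an entire census row")
    rows <- rows / sums
  }
  observed_series(census_years, rows, model$names)
}

#' Parameter-recovery experiment for the ABC-SMC sampler
#'
#' Generates a synthetic census series from a known model, calibrates the
#' model to it with [run_abc_smc()], and reports the absolute error of the
#' weighted posterior means against the truth. This is the package's
#' end-to-end check that the calibration stage recovers the generating
#' parameters under census-like sparsity and noise.
#'
#' The default initial state gives the smallest-utility language (the
#' declining historical dominant, in the fitted communities) a 0.8 share and
#' splits the rest evenly. Initials adjacent to a simplex vertex are
#' deliberately avoided: additive observation noise can clip a near-zero
#' fraction to exactly 0, and an extinct language is absorbing whenever
#' \eqn{\beta > 0}, which makes the generating parameters unrecoverable from
#' the observed first row regardless of the sampler.
#'
#' @param true_model the generating `competition_model`.
#' @param x0 initial fractions at the first census year; `NULL` (default)
#'   uses the census-like state described above.
#' @param census_years census sampling years (see
#'   [generate_observed_series()]).
#' @param noise_sd observation noise standard deviation; default 0.005,
#'   matching the small scatter of census points around fitted trajectories.
#' @param seed integer seed driving both the noise and the sampler.
#' @param n_particles,max_iterations,... passed to [run_abc_smc()].
#' @return list with `true` (named vector), `estimate` (named vector of
#'   weighted posterior means), `abs_error`, `posterior` (the
#'   `abc_posterior`), and `series`.
#' @export
recovery_experiment <- function(true_model, x0 = NULL,
                                census_years = c(1957, 1970, 1980, 1990,
                                                 2000, 2010),
                                noise_sd = 0.005, seed = 1,
                                n_particles = 100, max_iterations = 30,
                                ...) {
  stopifnot(inherits(true_model, "competition_model"))
  if (is.null(x0)) {
    n <- n_languages(true_model)
    x0 <- rep(0.2 / (n - 1), n)
    x0[which.min(true_model$utilities)] <- 0.8
  }
  set.seed(seed)
  series <- generate_observed_series(true_model, x0, census_years,
                                     noise_sd = noise_sd)
  post <- run_abc_smc(series, n_particles = n_particles,
                      max_iterations = max_iterations, ...)
  est <- summarize_posterior(post)
  truth <- c(alpha = true_model$alpha, beta = true_model$beta,
             setNames(true_model$utilities,
                      paste0("s_", true_model$names)))
  estimate <- setNames(est$mean, est$parameter)[names(truth)]
  list(true = truth, estimate = estimate,
       abs_error = abs(estimate - truth), posterior = post,
       series = series)
}
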