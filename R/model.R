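#' Construct a multi-language competition model
#'
#' Bundles the parameters of the extended Abrams-Strogatz dynamics: one
#' utility per language plus the two bias exponents. The transition rate from
#' language j to language i is \eqn{P_{ji} = s_i x_i^\beta (1-x_j)^{\alpha-\beta}},
#' and the speaker fractions evolve as
#' \deqn{dx_i/dt = \sum_{j \ne i} x_j P_{ji} - x_i \sum_{j \ne i} P_{ij}.}
#'
#' @param utilities numeric vector of per-language utilities \eqn{s_i};
#'   nonnegative and summing to 1 (within 1e-9). A zero utility is the
#'   boundary case reached by utility sweeps: such a language can only lose
#'   speakers.
#' @param alpha combined bias exponent \eqn{\alpha}; must satisfy
#'   \eqn{\alpha \ge \beta}.
#' @param beta majority-preference exponent \eqn{\beta \ge 0}. The minority
#'   aversion is \eqn{\alpha - \beta}.
#' @param names optional character vector of language identifiers; defaults
#'   to `lang1..langn`.
#' @return an object of class `competition_model`.
#' @examples
#' m <- competition_model(c(0.35, 0.29, 0.36), alpha = 1.00, beta = 0.76,
#'                        names = c("English", "Dialect", "Mandarin"))
#' m
#' @export
competition_model <- function(utilities, alpha, beta, names = NULL) {
  if (!is.numeric(utilities) || length(utilities) < 2)
    stop("`utilities` must be a numeric vector of length >= 2")
  if (any(utilities < 0))
    stop("utilities must be nonnegative")
  if (abs(sum(utilities) - 1) > 1e-9)
    stop("utilities must sum to 1 (within 1e-9); got ", sum(utilities))
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0)
    stop("`beta` must be a single value >= 0")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha - beta < 0)
    stop("`alpha - beta` must be >= 0 (got alpha = ", alpha,
         ", beta = ", beta, ")")
  if (is.null(names)) names <- paste0("lang", seq_along(utilities))
  if (length(names) != length(utilities))
    stop("`names` must have one entry per utility")
  if (anyDuplicated(names)) stop("language names must be unique")
  structure(
    list(names = as.character(names),
         utilities = as.numeric(utilities),
         alpha = as.numeric(alpha), beta = as.numeric(beta)),
    class = "competition_model")
}

#' @export
print.competition_model <- function(x, ...) {
  cat("Language competition model (", length(x$names), " languages)\n",
      sep = "")
  cat(sprintf("  alpha = %.4g, beta = %.4g (minority aversion alpha-beta = %.4g)\n",
              x$alpha, x$beta, x$alpha - x$beta))
  cat("  utilities:\n")
  for (i in seq_along(x$names))
    cat(sprintf("    %-12s s = %.4g\n", x$names[i], x$utilities[i]))
  invisible(x)
}

#' Number of competing languages in a model
#' @param model a `competition_model`.
#' @return integer count of languages.
#' @export
n_languages <- function(model) {
  stopifnot(inherits(model, "competition_model"))
  length(model$names)
}

#' Validate a point on the population simplex
#'
#' A population state is a vector of speaker fractions: every entry in
#' \eqn{[0, 1]} and the entries summing to 1 within 1e-9.
#'
#' @param fractions numeric vector of speaker fractions.
#' @return the validated numeric vector.
#' @export
population_state <- function(fractions) {
  if (!is.numeric(fractions) || length(fractions) < 2)
    stop("`fractions` must be a numeric vector of length >= 2")
  if (any(fractions < 0) || any(fractions > 1))
    stop("fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (within 1e-9); got ", sum(fractions),
         "; divide by the sum first if the data are unnormalised")
  as.numeric(fractions)
}

#' Transition rate between a pair of languages
#'
#' The rate at which speakers of language j adopt language i:
#' \eqn{s_i x_i^\beta (1-x_j)^{\alpha-\beta}}, with the convention
#' \eqn{0^0 = 1} so that an extinct language can still gain speakers when
#' the corresponding exponent is zero.
#'
#' @param s_i utility of the adopting (target) language; > 0.
#' @param x_i current fraction of the target language, in \eqn{[0,1]}.
#' @param x_j current fraction of the source language, in \eqn{[0,1]}.
#' @param alpha,beta bias exponents, \eqn{\beta \ge 0},
#'   \eqn{\alpha - \beta \ge 0}.
#' @return nonnegative transition rate (per year).
#' @export
pairwise_rate <- function(s_i, x_i, x_j, alpha, beta) {
  if (any(s_i <= 0)) stop("`s_i` must be > 0")
  if (any(x_i < 0 | x_i > 1) || any(x_j < 0 | x_j > 1))
    stop("fractions must lie in [0, 1]")
  if (beta < 0) stop("`beta` must be >= 0")
  if (alpha - beta < 0) stop("`alpha - beta` must be >= 0")
  s_i * pow0(x_i, beta) * pow0(1 - x_j, alpha - beta)
}

# x^e with 0^0 := 1, vectorised over the base
pow0 <- function(base, e) {
  if (e == 0) rep(1, length(base)) else base^e
}

#' Instantaneous flow of speakers between languages
#'
#' Evaluates the right-hand side of the competition dynamics at a state:
#' component i is the net gain of language i,
#' \eqn{\sum_{j\ne i} x_j P_{ji} - x_i \sum_{j\ne i} P_{ij}}. The gain and
#' loss terms cancel pairwise, so the components sum to zero.
#'
#' @param state numeric vector of speaker fractions on the simplex.
#' @param model a `competition_model` with matching dimension.
#' @return numeric vector of time derivatives (per year), named after the
#'   languages.
#' @export
flow_derivative <- function(state, model) {
  stopifnot(inherits(model, "competition_model"))
  x <- population_state(state)
  if (length(x) != n_languages(model))
    stop("state has ", length(x), " entries but the model has ",
         n_languages(model), " languages")
  att <- model$utilities * pow0(x, model$beta)
  esc <- pow0(1 - x, model$alpha - model$beta)
  # P[j, i] = att[i] * esc[j]; gain_i = sum_j x_j P[j,i], loss_i = x_i sum_j P[i,j]
  gain <- att * sum(x * esc) - att * x * esc
  loss <- x * (esc * sum(att) - esc * att)
  setNames(gain - loss, model$names)
}

#' Advance a population state by one explicit Euler step
#'
#' New fractions are `state + dt * flow_derivative(state, model)`, clipped to
#' \eqn{[0,1]} and renormalised so the result stays exactly on the simplex
#' (floating-point drift control).
#'
#' @inheritParams flow_derivative
#' @param dt step length in years (> 0); the dynamics were calibrated against
#'   yearly census data, so the default step elsewhere is 1 year.
#' @return the new state vector.
#' @export
step_population <- function(state, model, dt = 1) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0")
  x <- state + dt * flow_derivative(state, model)
  x <- pmin(pmax(x, 0), 1)
  as.numeric(x / sum(x))
}

#' Simulate a trajectory of the competition dynamics
#'
#' Integrates the model with explicit Euler steps from an initial state,
#' recording every step. The integration is deterministic: the same inputs
#' always reproduce the same trajectory.
#'
#' @inheritParams step_population
#' @param x0 initial speaker fractions on the simplex.
#' @param horizon total simulated time in years (>= `dt`).
#' @param t0 time label of the first state (e.g. a census year); defaults
#'   to 0.
#' @return an object of class `trajectory`: a list with `times` (numeric
#'   vector) and `fractions` (matrix, one row per time point, one column per
#'   language). Coerce with [as.data.frame()].
#' @examples
#' m <- competition_model(c(0.35, 0.29, 0.36), 1.00, 0.76,
#'                        c("English", "Dialect", "Mandarin"))
#' x0 <- c(0.018, 0.975, 0.001) / 0.994
#' tr <- simulate_trajectory(m, x0, horizon = 60, t0 = 1957)
#' head(as.data.frame(tr))
#' @export
simulate_trajectory <- function(model, x0, horizon, dt = 1, t0 = 0) {
  stopifnot(inherits(model, "competition_model"))
  x0 <- population_state(x0)
  if (length(x0) != n_languages(model))
    stop("`x0` dimension does not match the model")
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0")
  if (horizon < dt) stop("`horizon` must be >= `dt`")
  n_steps <- floor(horizon / dt)
  frac <- cpp_simulate(model$utilities, model$alpha, model$beta, x0,
                       as.integer(n_steps), dt)
  colnames(frac) <- model$names
  structure(list(times = t0 + seq(0, n_steps) * dt, fractions = frac,
                 model = model),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x$fractions), "time points over [",
      x$times[1], ",", x$times[length(x$times)], "] for",
      ncol(x$fractions), "languages\n")
  cat("final state:",
      paste(sprintf("%s = %.4f", colnames(x$fractions),
                    x$fractions[nrow(x$fractions), ]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$fractions, check.names = FALSE)
}

#' Classify a long-run state into coexistence or dominance
#'
#' A language survives if its equilibrium fraction is at least the extinction
#' threshold. Exactly one survivor is a dominance state; two or more
#' survivors form a coexistence state. The most popular language is the
#' argmax of the fractions (ties broken by the lowest index).
#'
#' @param equilibrium numeric vector of equilibrium speaker fractions.
#' @param extinction_threshold fraction below which a language counts as
#'   extinct; in (0, 0.5). Default 1e-3.
#' @param names optional language identifiers.
#' @return an object of class `state_label` with fields `kind`
#'   ("coexistence" or "dominance"), `top_language`, and `survivors`.
#' @export
classify_state <- function(equilibrium, extinction_threshold = 1e-3,
                           names = NULL) {
  if (extinction_threshold <= 0 || extinction_threshold >= 0.5)
    stop("`extinction_threshold` must lie in (0, 0.5)")
  x <- as.numeric(equilibrium)
  if (is.null(names)) {
    names <- base::names(equilibrium)
    if (is.null(names)) names <- paste0("lang", seq_along(x))
  }
  surv <- which(x >= extinction_threshold)
  if (length(surv) == 0)
    stop("degenerate input: every fraction is below the extinction threshold")
  kind <- if (length(surv) == 1) "dominance" else "coexistence"
  structure(list(kind = kind, top_language = names[which.max(x)],
                 survivors = names[surv]),
            class = "state_label")
}

#' @export
print.state_label <- function(x, ...) {
  cat(x$kind, "state; most popular:", x$top_language,
      "; survivors:", paste(x$survivors, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.state_label <- function(x, ...) {
  paste0(x$kind, " (", x$top_language, ")")
}

#' Integrate to a steady state and classify it
#'
#' Runs the Euler dynamics until the largest per-step change of any fraction
#' falls below `tol`, and reports the convergence time tau, the equilibrium
#' and its state label. Convergence time peaks near tipping points (critical
#' slowing down), so non-convergence within `max_time` is a reported outcome
#' (`converged = FALSE`, `tau = max_time`), not an error.
#'
#' @inheritParams simulate_trajectory
#' @param tol convergence tolerance on the per-step max change; default 1e-6.
#' @param max_time cap on simulated years; default 1e5, generous because
#'   convergence slows down drastically near state-transition tipping points.
#' @param extinction_threshold passed to [classify_state()].
#' @return an object of class `steady_state` with fields `equilibrium`
#'   (named fractions), `tau` (years), `converged`, and `label`
#'   (a `state_label`).
#' @export
find_steady_state <- function(model, x0, tol = 1e-6, max_time = 1e5, dt = 1,
                              extinction_threshold = 1e-3) {
  stopifnot(inherits(model, "competition_model"))
  x0 <- population_state(x0)
  if (length(x0) != n_languages(model))
    stop("`x0` dimension does not match the model")
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be > 0")
  res <- cpp_find_steady(model$utilities, model$alpha, model$beta, x0,
                         tol, max_time, dt)
  eq <- setNames(res$equilibrium, model$names)
  structure(list(equilibrium = eq, tau = res$tau,
                 converged = res$converged,
                 label = classify_state(eq, extinction_threshold)),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("Steady state", if (x$converged) sprintf("reached at tau = %g years",
                                               x$tau)
      else sprintf("NOT reached within %g years", x$tau), "\n")
  cat("  ", format(x$label), "\n")
  cat("  equilibrium:",
      paste(sprintf("%s = %.4f", names(x$equilibrium), x$equilibrium),
            collapse = ", "), "\n")
  invisible(x)
}
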