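#' Set one utility and redistribute the remainder proportionally
#'
#' Raising the utility of one language lowers the utilities of the others in
#' proportion to their current values, keeping the vector on the simplex:
#' \eqn{s_i' = v} and \eqn{s_j' = s_j (1 - v) / \sum_{k \ne i} s_k} for
#' \eqn{j \ne i}.
#'
#' @param base utility vector on the simplex.
#' @param index position of the language whose utility is set.
#' @param new_value the new utility, in \eqn{[0, 1)}; 1 is degenerate because
#'   the remaining languages would need zero utility.
#' @return redistributed utility vector.
#' @export
redistribute_utilities <- function(base, index, new_value) {
  base <- as.numeric(base)
  if (index < 1 || index > length(base)) stop("`index` out of range")
  if (new_value < 0 || new_value >= 1)
    stop("degenerate `new_value`: must lie in [0, 1) so that the other ",
         "languages keep positive utility")
  rest <- sum(base[-index])
  if (rest <= 0) stop("remaining utilities must have positive total")
  out <- base * (1 - new_value) / rest
  out[index] <- new_value
  out
}

#' Set one initial fraction and rescale the others proportionally
#'
#' The same proportional rule as [redistribute_utilities()], applied to
#' initial speaker fractions: used to move a population gradually toward or
#' away from a tipping point while staying on the simplex.
#'
#' @param base fractions on the simplex.
#' @param index position of the language whose initial fraction is set.
#' @param new_value the new fraction, in \eqn{[0, 1)}.
#' @return rescaled state vector.
#' @export
rescale_initials <- function(base, index, new_value) {
  base <- population_state(base)
  if (index < 1 || index > length(base)) stop("`index` out of range")
  if (new_value < 0 || new_value >= 1)
    stop("degenerate `new_value`: must lie in [0, 1)")
  rest <- sum(base[-index])
  if (rest <= 0)
    stop("remaining fractions must have positive total to rescale")
  out <- base * (1 - new_value) / rest
  out[index] <- new_value
  out
}

# shared driver: run find_steady_state over a list of (model, x0) pairs and
# assemble the long-format result table
run_sweep <- function(values, models, x0s, languages, tol, max_time, dt,
                      extinction_threshold) {
  rows <- lapply(seq_along(values), function(i) {
    ss <- find_steady_state(models[[i]], x0s[[i]], tol = tol,
                            max_time = max_time, dt = dt,
                            extinction_threshold = extinction_threshold)
    c(list(value = values[i]),
      as.list(setNames(ss$equilibrium, paste0("X_", languages))),
      list(tau = ss$tau, converged = ss$converged, kind = ss$label$kind,
           top = ss$label$top_language))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Sweep the utility of one language and record long-run states
#'
#' For each grid value, the chosen language's utility is set with
#' [redistribute_utilities()] (the other utilities shrink proportionally),
#' the dynamics are run to a steady state from the given initial fractions,
#' and the equilibrium, convergence time and coexistence/dominance label are
#' recorded.
#'
#' @param model baseline `competition_model` (the fitted dataset parameters).
#' @param x0 initial fractions (the dataset's first-census values).
#' @param index position of the swept language.
#' @param grid strictly increasing utility values in \eqn{[0, 1)}.
#' @param tol,max_time,dt,extinction_threshold passed to
#'   [find_steady_state()].
#' @return a `sweep_result`: data.frame with columns `value`,
#'   `X_<language>..`, `tau`, `converged`, `kind`, `top`.
#' @examples
#' m <- competition_model(c(0.35, 0.29, 0.36), 1.00, 0.76,
#'                        c("English", "Dialect", "Mandarin"))
#' x0 <- c(0.018, 0.975, 0.001) / 0.994
#' sw <- utility_sweep(m, x0, index = 1, grid = seq(0, 0.6, 0.1))
#' sw[, c("value", "kind", "top")]
#' @export
utility_sweep <- function(model, x0, index, grid, tol = 1e-6,
                          max_time = 1e5, dt = 1,
                          extinction_threshold = 1e-3) {
  stopifnot(inherits(model, "competition_model"))
  check_grid(grid)
  x0 <- population_state(x0)
  models <- lapply(grid, function(v)
    competition_model(redistribute_utilities(model$utilities, index, v),
                      model$alpha, model$beta, model$names))
  out <- run_sweep(grid, models, rep(list(x0), length(grid)), model$names,
                   tol, max_time, dt, extinction_threshold)
  as_sweep_result(out, model$names,
                  swept = list(quantity = "utility",
                               language = model$names[index]))
}

#' Sweep one of the two bias exponents and record long-run states
#'
#' Varies either the minority aversion \eqn{\alpha - \beta} (with \eqn{\beta}
#' held at the model's value) or the majority preference \eqn{\beta} (with
#' the aversion held at the model's value), keeping utilities and initial
#' fractions fixed at the dataset values.
#'
#' @inheritParams utility_sweep
#' @param grid strictly increasing bias values (>= 0).
#' @param vary `"aversion"` to sweep \eqn{\alpha-\beta}, `"preference"` to
#'   sweep \eqn{\beta}.
#' @return a `sweep_result` as in [utility_sweep()].
#' @export
bias_sweep <- function(model, x0, grid, vary = c("aversion", "preference"),
                       tol = 1e-6, max_time = 1e5, dt = 1,
                       extinction_threshold = 1e-3) {
  stopifnot(inherits(model, "competition_model"))
  vary <- match.arg(vary)
  check_grid(grid)
  if (any(grid < 0)) stop("bias values must be >= 0")
  x0 <- population_state(x0)
  aversion <- model$alpha - model$beta
  models <- lapply(grid, function(v) {
    if (vary == "aversion")
      competition_model(model$utilities, model$beta + v, model$beta,
                        model$names)
    else
      competition_model(model$utilities, v + aversion, v, model$names)
  })
  out <- run_sweep(grid, models, rep(list(x0), length(grid)), model$names,
                   tol, max_time, dt, extinction_threshold)
  as_sweep_result(out, model$names,
                  swept = list(quantity = vary,
                               held = if (vary == "aversion") model$beta
                                      else aversion))
}

#' Two-parameter phase diagram over majority preference and minority aversion
#'
#' Computes the steady-state label on the full cross-product of a
#' \eqn{\beta} grid and an \eqn{\alpha-\beta} grid, with utilities and
#' initial fractions fixed at the dataset values. Each row of the diagram at
#' a fixed \eqn{\beta} equals the corresponding 1-D [bias_sweep()].
#'
#' @inheritParams utility_sweep
#' @param beta_grid majority-preference values (>= 0), strictly increasing.
#' @param aversion_grid minority-aversion values (>= 0), strictly increasing.
#' @return a `phase_diagram`: list with the two grids plus `kind` and `top`
#'   character matrices (rows = `beta_grid`, columns = `aversion_grid`).
#'   Coerce with [as.data.frame()] for a long-format table.
#' @export
phase_diagram <- function(model, x0, beta_grid, aversion_grid, tol = 1e-6,
                          max_time = 1e5, dt = 1,
                          extinction_threshold = 1e-3) {
  stopifnot(inherits(model, "competition_model"))
  check_grid(beta_grid); check_grid(aversion_grid)
  if (any(beta_grid < 0) || any(aversion_grid < 0))
    stop("bias grids must be >= 0")
  x0 <- population_state(x0)
  kind <- matrix(NA_character_, length(beta_grid), length(aversion_grid))
  top <- kind
  for (b in seq_along(beta_grid)) {
    for (a in seq_along(aversion_grid)) {
      m <- competition_model(model$utilities,
                             beta_grid[b] + aversion_grid[a], beta_grid[b],
                             model$names)
      ss <- find_steady_state(m, x0, tol = tol, max_time = max_time,
                              dt = dt,
                              extinction_threshold = extinction_threshold)
      kind[b, a] <- ss$label$kind
      top[b, a] <- ss$label$top_language
    }
  }
  structure(list(beta_grid = beta_grid, aversion_grid = aversion_grid,
                 kind = kind, top = top, languages = model$names),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("Phase diagram:", length(x$beta_grid), "beta values x",
      length(x$aversion_grid), "aversion values\n")
  tab <- table(paste(x$kind, x$top, sep = "-"))
  for (nm in names(tab)) cat(sprintf("  %-28s %d cells\n", nm, tab[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.phase_diagram <- function(x, ...) {
  grid <- expand.grid(beta = x$beta_grid, aversion = x$aversion_grid)
  data.frame(grid, kind = as.vector(x$kind), top = as.vector(x$top))
}

#' Convergence-time curve along an initial-fraction sweep
#'
#' Gradually changes the initial fraction of one language (the others
#' rescaled proportionally) and records the time to reach the steady state.
#' Convergence time peaks at tipping points where the long-run label changes
#' (critical slowing down), so the curve's peak is an early-warning locator
#' for state transitions. Runs that do not converge within `max_time` are
#' recorded with `tau = max_time` and flagged.
#'
#' @inheritParams utility_sweep
#' @param index position of the language whose initial fraction is varied.
#' @param grid strictly increasing initial fractions in \eqn{[0, 1)}.
#' @return a `convergence_curve` (a `sweep_result` with a `peak` attribute:
#'   the grid value with the largest tau).
#' @export
convergence_time_sweep <- function(model, x0, index, grid, tol = 1e-6,
                                   max_time = 1e5, dt = 1,
                                   extinction_threshold = 1e-3) {
  stopifnot(inherits(model, "competition_model"))
  check_grid(grid)
  x0 <- population_state(x0)
  x0s <- lapply(grid, function(v) rescale_initials(x0, index, v))
  out <- run_sweep(grid, rep(list(model), length(grid)), x0s, model$names,
                   tol, max_time, dt, extinction_threshold)
  out <- as_sweep_result(out, model$names,
                         swept = list(quantity = "initial fraction",
                                      language = model$names[index]))
  attr(out, "peak") <- out$value[which.max(out$tau)]
  class(out) <- c("convergence_curve", class(out))
  out
}

#' Locate the grid threshold where a state predicate flips
#'
#' Evaluates a predicate on the label of every sweep row and reports the
#' adjacent grid pair (last value where it is false, first value where it is
#' true). A predicate that never changes is reported as such, not as an
#' error; a predicate that changes more than once is flagged and all change
#' points are listed.
#'
#' @param result a `sweep_result`.
#' @param predicate function of two arguments `(kind, top)` returning a
#'   single logical; see [dominance_of()] and [coexistence_state()].
#' @return a `threshold_report`: list with `status` (one of `"threshold"`,
#'   `"never_true"`, `"never_false"`, `"multiple"`), `last_false`,
#'   `first_true`, and `changes` (data.frame of every adjacent pair where
#'   the predicate value flips).
#' @examples
#' m <- competition_model(c(0.35, 0.29, 0.36), 1.00, 0.76,
#'                        c("English", "Dialect", "Mandarin"))
#' x0 <- c(0.018, 0.975, 0.001) / 0.994
#' sw <- utility_sweep(m, x0, index = 1, grid = seq(0.3, 0.5, 0.05))
#' detect_threshold(sw, dominance_of("English"))
#' @export
detect_threshold <- function(result, predicate) {
  stopifnot(inherits(result, "sweep_result"))
  p <- vapply(seq_len(nrow(result)), function(i)
    isTRUE(predicate(result$kind[i], result$top[i])), logical(1))
  flips <- which(diff(p) != 0)
  changes <- data.frame(before = result$value[flips],
                        after = result$value[flips + 1],
                        direction = ifelse(p[flips + 1],
                                           "false_to_true", "true_to_false"))
  status <- if (all(p)) "never_false" else if (!any(p)) "never_true"
            else if (length(flips) > 1) "multiple" else "threshold"
  last_false <- NA_real_
  first_true <- NA_real_
  up <- which(!p[-length(p)] & p[-1])
  if (length(up) > 0) {
    last_false <- result$value[up[1]]
    first_true <- result$value[up[1] + 1]
  }
  structure(list(status = status, last_false = last_false,
                 first_true = first_true, changes = changes),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  switch(x$status,
    never_true = cat("no threshold: predicate is false on the whole grid\n"),
    never_false = cat("no threshold: predicate is true on the whole grid\n"),
    multiple = {
      cat("predicate changes more than once; change points:\n")
      print(x$changes, row.names = FALSE)
    },
    cat(sprintf("threshold between %g (last false) and %g (first true)\n",
                x$last_false, x$first_true)))
  invisible(x)
}

#' Predicate builders for threshold detection
#'
#' `dominance_of(language)` is true when the label is a dominance state with
#' the given language as sole survivor; `coexistence_state()` is true for
#' any coexistence label.
#'
#' @param language language identifier.
#' @return a function `(kind, top) -> logical` for [detect_threshold()].
#' @export
dominance_of <- function(language) {
  force(language)
  function(kind, top) kind == "dominance" && top == language
}

#' @rdname dominance_of
#' @export
coexistence_state <- function() {
  function(kind, top) kind == "coexistence"
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 1)
    stop("grid must be a non-empty numeric vector")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  invisible(grid)
}

as_sweep_result <- function(df, languages, swept) {
  attr(df, "languages") <- languages
  attr(df, "swept") <- swept
  class(df) <- c("sweep_result", "data.frame")
  df
}

#' @export
print.sweep_result <- function(x, ...) {
  sw <- attr(x, "swept")
  cat("Sweep over", sw$quantity,
      if (!is.null(sw$language)) paste0("of ", sw$language), ":",
      nrow(x), "grid points\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
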