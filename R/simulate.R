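#' Simulate a cell-cycle model
#'
#' Deterministic integration of a `tow_model` (optionally with a mutant
#' applied) using a stiff-capable solver with root-based event
#' localization. Event triggers are detected as sign changes of their
#' trigger expressions; a trigger's `direction` field restricts firing to
#' downward or upward crossings (the crossing direction is taken from the
#' sign of the trigger's time derivative at the root). Trajectories are
#' bit-reproducible for fixed inputs and settings.
#'
#' @param model a `tow_model` from [load_model()] or [define_model()].
#' @param mutant optional [mutant_spec()] (e.g. from [apply_deletion()]).
#' @param horizon integration end time; defaults to the model's viability
#'   horizon.
#' @param settings list of integrator settings: `method` (default
#'   `"lsoda"`), `rtol` (default `1e-8`), `atol` (default `1e-10`),
#'   `n_out` (output grid size, default 501).
#' @return object of class `tow_sim`: list with `time`, `state` (matrix,
#'   one column per state variable), `events` (data.frame `time`, `event`),
#'   `division_times`, `status` (`"alive"`/`"dead"`, or `NA` if the run is
#'   shorter than the viability horizon), `rule` (the model's viability
#'   rule) and `diagnostics`.
#' @export
simulate_model <- function(model, mutant = NULL, horizon = NULL,
                           settings = list()) {
  stopifnot(inherits(model, "tow_model"))
  set <- utils::modifyList(list(method = "lsoda", rtol = 1e-8, atol = 1e-10,
                                n_out = 501L), settings)
  if (is.null(horizon)) horizon <- as.numeric(model$viability$horizon)
  if (!is.finite(horizon) || horizon <= 0) stop_invalid("horizon must be > 0")

  rm <- resolve_mutant(model, mutant)
  pars <- rm$pars
  y0 <- rm$y0
  env <- make_model_env()
  for (p in names(pars)) assign(p, pars[[p]], envir = env)
  state_names <- names(y0)
  rate_exprs <- model$rates[names(model$species)]
  if (!is.null(model$mass)) rate_exprs <- c(rate_exprs, list(m = model$mass$expr))

  push_state <- function(t, y) {
    assign("t", t, envir = env)
    for (i in seq_along(y)) assign(state_names[[i]], y[[i]], envir = env)
  }
  derivs <- function(t, y, parms) {
    push_state(t, y)
    list(vapply(rate_exprs, eval, numeric(1), envir = env))
  }
  triggers <- lapply(model$events, `[[`, "trigger")
  eval_triggers <- function(t, y) {
    push_state(t, y)
    vapply(triggers, eval, numeric(1), envir = env)
  }
  rec <- new.env(parent = emptyenv())
  rec$times <- numeric()
  rec$names <- character()

  rootfun <- if (length(triggers)) function(t, y, parms) eval_triggers(t, y)
  eventfun <- function(t, y, parms) {
    g <- eval_triggers(t, y)
    idx <- which.min(abs(g))
    ev <- model$events[[idx]]
    # crossing direction from the trigger's time derivative at the root
    f <- unlist(derivs(t, y, parms))
    h <- 1e-7 * max(1, max(abs(y)))
    dgdt <- (eval_triggers(t, y + h * f)[idx] -
               eval_triggers(t, y - h * f)[idx]) / (2 * h)
    fire <- switch(ev$direction,
                   down = dgdt < 0, up = dgdt > 0, both = TRUE)
    if (!fire) return(y)
    push_state(t, y)
    new_vals <- vapply(ev$assignments, eval, numeric(1), envir = env)
    y[names(new_vals)] <- new_vals
    rec$times <- c(rec$times, t)
    rec$names <- c(rec$names, ev$name)
    y
  }

  times <- seq(0, horizon, length.out = as.integer(set$n_out))
  out <- tryCatch(
    if (length(triggers))
      deSolve::ode(y = y0, times = times, func = derivs, parms = NULL,
                   method = set$method, rtol = set$rtol, atol = set$atol,
                   rootfunc = rootfun,
                   events = list(func = eventfun, root = TRUE, maxroot = 10000))
    else
      deSolve::ode(y = y0, times = times, func = derivs, parms = NULL,
                   method = set$method, rtol = set$rtol, atol = set$atol),
    error = function(e)
      stop_simulation("integrator failure: %s", conditionMessage(e)))

  out <- unclass(out)
  state <- out[, state_names, drop = FALSE]
  tgrid <- out[, "time"]
  if (!all(is.finite(state)))
    stop_simulation("non-finite state encountered",
                    last_good_time = suppressWarnings(
                      max(tgrid[apply(is.finite(state), 1, all)], -Inf)))
  if (max(tgrid) < horizon * (1 - 1e-9))
    stop_simulation("integration stopped early at t = %g", max(tgrid),
                    last_good_time = max(tgrid))

  dup <- duplicated(paste(rec$times, rec$names))
  ev_df <- data.frame(time = rec$times[!dup], event = rec$names[!dup],
                      stringsAsFactors = FALSE)
  div_name <- model$viability$division_event %||% "division"
  result <- structure(list(time = tgrid, state = state, events = ev_df,
                           division_times = ev_df$time[ev_df$event == div_name],
                           status = NA_character_,
                           parameters = pars,
                           rule = model$viability,
                           mass_name = if (!is.null(model$mass)) "m",
                           diagnostics = list(method = set$method,
                                              rtol = set$rtol, atol = set$atol,
                                              n_out = set$n_out,
                                              n_events = nrow(ev_df))),
                      class = "tow_sim")
  if (max(tgrid) >= as.numeric(model$viability$horizon))
    result$status <- assess_viability(result)
  result
}

#' Viability verdict for a simulation
#'
#' Division-count form: alive iff at least `min_divisions` firings of the
#' division event occur within the rule horizon *and* the mass variable
#' never exceeds `max_mass` over that window. Predicate form: alive iff
#' the rule's expression is true of the state at the rule horizon.
#' Growth arrest -- too few divisions, or unbounded mass growth -- is
#' what "dead" means here.
#'
#' @param result a `tow_sim` from [simulate_model()].
#' @param rule viability rule list; defaults to the rule stored in the
#'   result (i.e. the model's own).
#' @return `"alive"` or `"dead"`.
#' @export
assess_viability <- function(result, rule = NULL) {
  stopifnot(inherits(result, "tow_sim"))
  if (is.null(rule)) rule <- result$rule
  horizon <- as.numeric(rule$horizon)
  if (max(result$time) < horizon)
    stop_invalid("simulation (t <= %g) does not cover the viability horizon %g",
                 max(result$time), horizon)
  if (identical(rule$form, "predicate")) {
    i <- which.max(result$time[result$time <= horizon * (1 + 1e-9)])
    env <- make_model_env()
    pars <- result$parameters
    for (p in names(pars)) assign(p, pars[[p]], envir = env)
    y <- result$state[i, ]
    for (nm in colnames(result$state)) assign(nm, y[[nm]], envir = env)
    assign("t", result$time[i], envir = env)
    ok <- isTRUE(eval(rule$expr_parsed, envir = env))
    return(if (ok) "alive" else "dead")
  }
  div_name <- rule$division_event %||% "division"
  n_div <- sum(result$events$event == div_name & result$events$time <= horizon)
  alive <- n_div >= as.numeric(rule$min_divisions)
  if (alive && !is.null(result$mass_name) && !is.null(rule$max_mass)) {
    mass <- result$state[result$time <= horizon, result$mass_name]
    alive <- all(mass <= as.numeric(rule$max_mass))
  }
  if (alive) "alive" else "dead"
}

#' @export
print.tow_sim <- function(x, ...) {
  cat(sprintf("simulation: t in [0, %g], %d state variable(s), %d event firing(s)\n",
              max(x$time), ncol(x$state), nrow(x$events)))
  cat(sprintf("divisions: %d; status: %s\n", length(x$division_times),
              if (is.na(x$status)) "not assessed" else x$status))
  invisible(x)
}

#' Trajectory plot
#'
#' @param x a `tow_sim`.
#' @param species which state variables to draw (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tow_sim <- function(x, species = colnames(x$state), ...) {
  graphics::matplot(x$time, x$state[, species, drop = FALSE], type = "l",
                    lty = 1, xlab = "time", ylab = "state", ...)
  graphics::legend("topright", legend = species, lty = 1,
                   col = seq_along(species), bty = "n")
  if (length(x$division_times))
    graphics::abline(v = x$division_times, col = "grey70", lty = 3)
  invisible(x)
}
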