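#' Scan a degradation-rate parameter for its viability limit
#'
#' The in-silico analogue of the tug-of-war: find the largest value of a
#' (typically degradation-rate) parameter at which the model still
#' simulates as alive. `mode = "bisect"` first probes a coarse
#' logarithmic grid to confirm the alive/dead pattern is monotone, then
#' binary-searches the boundary to relative width `tol`; if the coarse
#' probe shows a non-monotone pattern (alive-dead-alive) a warning is
#' issued and the scan falls back to a full grid sweep. `mode = "grid"`
#' sweeps an ascending logarithmic grid and returns the last alive value
#' before the first dead one. If the model is still alive at `hi` the
#' result is censored: only a lower bound on the limit is known.
#'
#' @param model a `tow_model`.
#' @param mutant optional [mutant_spec()]; `NULL` scans the wild type.
#' @param parameter name of the parameter to scan.
#' @param lo,hi scan bracket (`0 < lo < hi`); the model must be alive at
#'   `lo`.
#' @param tol relative bracket width at which bisection stops
#'   (default `1e-3`).
#' @param mode `"bisect"` (default) or `"grid"`.
#' @param grid_n grid size for grid mode and the fallback (default 200).
#' @param settings integrator settings passed to [simulate_model()].
#' @return object of class `tow_scan`: list with `parameter`,
#'   `upper_limit`, `censored`, `mode`, `n_evaluations`, `bracket_history`
#'   (data.frame `value`, `status` in evaluation order) and
#'   `non_monotone` flag.
#' @export
scan_parameter_limit <- function(model, mutant = NULL, parameter,
                                 lo, hi, tol = 1e-3,
                                 mode = c("bisect", "grid"),
                                 grid_n = 200L, settings = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "tow_model"))
  if (!parameter %in% names(model$parameters))
    stop_invalid("parameter '%s' not in model", parameter)
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || lo >= hi)
    stop_invalid("need 0 < lo < hi")
  if (!is.finite(tol) || tol <= 0) stop_invalid("tol must be > 0")

  history <- data.frame(value = numeric(), status = character(),
                        stringsAsFactors = FALSE)
  alive_at <- function(value) {
    m <- if (is.null(mutant)) mutant_spec() else mutant
    m$overrides[parameter] <- value
    sim <- simulate_model(model, m,
                          horizon = as.numeric(model$viability$horizon),
                          settings = settings)
    ok <- identical(sim$status, "alive")
    history <<- rbind(history,
                      data.frame(value = value,
                                 status = if (ok) "alive" else "dead",
                                 stringsAsFactors = FALSE))
    ok
  }

  finish <- function(upper_limit, censored, mode_used, non_monotone = FALSE) {
    structure(list(parameter = parameter, upper_limit = upper_limit,
                   censored = censored, mode = mode_used,
                   n_evaluations = nrow(history),
                   bracket_history = history,
                   non_monotone = non_monotone,
                   lo = lo, hi = hi, tol = tol),
              class = "tow_scan")
  }

  if (!alive_at(lo))
    stop_no_baseline("model is dead at lo = %g for this mutant; no viable baseline",
                     lo)

  grid_sweep <- function() {
    grid <- exp(seq(log(lo), log(hi), length.out = as.integer(grid_n)))
    status <- logical(length(grid))
    status[1] <- TRUE  # lo already verified alive
    for (i in 2:length(grid)) status[i] <- alive_at(grid[i])
    last_alive <- max(which(status))
    non_mono <- any(diff(status) > 0)  # dead followed by alive
    if (non_mono)
      warning("viability is non-monotone over the scanned grid; upper limit taken at the last alive grid point")
    if (all(status)) return(finish(hi, TRUE, "grid", non_mono))
    finish(grid[last_alive], FALSE, "grid", non_mono)
  }

  if (mode == "grid") return(grid_sweep())

  # coarse monotonicity probe, also brackets the boundary for bisection
  n_pre <- max(8L, min(16L, as.integer(grid_n)))
  pre <- exp(seq(log(lo), log(hi), length.out = n_pre))
  pre_status <- c(TRUE, vapply(pre[-1], alive_at, logical(1)))
  if (any(diff(pre_status) > 0)) {
    warning("non-monotone viability detected on the probe grid; falling back to grid mode")
    res <- grid_sweep()
    res$non_monotone <- TRUE
    return(res)
  }
  if (all(pre_status)) return(finish(hi, TRUE, "bisect"))
  a <- pre[max(which(pre_status))]
  b <- pre[max(which(pre_status)) + 1L]
  while ((b - a) > tol * b) {
    mid <- sqrt(a * b)
    if (alive_at(mid)) a <- mid else b <- mid
  }
  finish(a, FALSE, "bisect")
}

#' @export
print.tow_scan <- function(x, ...) {
  cat(sprintf("limit scan of '%s' on [%g, %g] (%s mode): upper limit %g%s after %d evaluation(s)\n",
              x$parameter, x$lo, x$hi, x$mode, x$upper_limit,
              if (x$censored) " (censored at scan ceiling)" else "",
              x$n_evaluations))
  if (isTRUE(x$non_monotone))
    cat("warning: viability non-monotone over the scanned range\n")
  invisible(x)
}

#' Relative degradation-rate change between mutant and wild type
#'
#' `(UL_mutant - UL_wt) / UL_wt`, the simulated counterpart of the
#' experimental relative copy-number change.
#'
#' @param mutant_limit,wt_limit `tow_scan` results for the same parameter.
#' @return dimensionless relative change. If either scan is censored the
#'   value is only a bound and a warning is raised (a censored wild type
#'   makes every mutant change a lower bound).
#' @export
relative_degradation_rate_change <- function(mutant_limit, wt_limit) {
  stopifnot(inherits(mutant_limit, "tow_scan"), inherits(wt_limit, "tow_scan"))
  if (!identical(mutant_limit$parameter, wt_limit$parameter))
    stop_invalid("scans are for different parameters ('%s' vs '%s')",
                 mutant_limit$parameter, wt_limit$parameter)
  if (!is.finite(wt_limit$upper_limit) || wt_limit$upper_limit <= 0)
    stop_invalid("wild-type upper limit must be positive")
  if (mutant_limit$censored || wt_limit$censored)
    warning("censored scan limit(s): the relative change is a bound, not an estimate")
  mutant_limit$upper_limit / wt_limit$upper_limit - 1
}

#' Scan a panel of mutants
#'
#' Runs [scan_parameter_limit()] for the wild type and for each mutant and
#' reports the relative degradation-rate change of every mutant against
#' the wild type. Failures (e.g. a mutant already dead at `lo`) are
#' isolated: the affected mutant gets a failure record, the panel
#' continues.
#'
#' @param model a `tow_model`.
#' @param mutants named list of [mutant_spec()] objects.
#' @param parameter parameter to scan.
#' @inheritParams scan_parameter_limit
#' @return data.frame of class `tow_scan_panel`: `mutant`, `upper_limit`,
#'   `censored`, `relative_change`, `n_evaluations`, `failure` (reason or
#'   `NA`); the wild-type scan is attached as attribute `wild_type`.
#' @export
scan_panel <- function(model, mutants, parameter, lo, hi, tol = 1e-3,
                       mode = c("bisect", "grid"), grid_n = 200L,
                       settings = list()) {
  mode <- match.arg(mode)
  if (length(mutants) && is.null(names(mutants)))
    stop_invalid("mutants must be a named list")
  scan1 <- function(mutant)
    scan_parameter_limit(model, mutant, parameter, lo = lo, hi = hi,
                         tol = tol, mode = mode, grid_n = grid_n,
                         settings = settings)
  wt <- scan1(NULL)
  if (wt$censored)
    warning("wild-type scan censored: all relative changes are lower bounds")
  one <- function(nm) {
    res <- tryCatch(scan1(mutants[[nm]]), tipigtow_error = function(e) e)
    if (inherits(res, "error")) {
      reason <- if (inherits(res, "tipigtow_no_viable_baseline"))
        "no viable baseline" else conditionMessage(res)
      return(data.frame(mutant = nm, upper_limit = NA_real_, censored = NA,
                        relative_change = NA_real_, n_evaluations = NA_integer_,
                        failure = reason, stringsAsFactors = FALSE))
    }
    rel <- suppressWarnings(relative_degradation_rate_change(res, wt))
    data.frame(mutant = nm, upper_limit = res$upper_limit,
               censored = res$censored, relative_change = rel,
               n_evaluations = res$n_evaluations, failure = NA_character_,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(names(mutants), one)
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(mutant = character(), upper_limit = numeric(),
                  censored = logical(), relative_change = numeric(),
                  n_evaluations = integer(), failure = character(),
                  stringsAsFactors = FALSE)
  structure(out, class = c("tow_scan_panel", "data.frame"), wild_type = wt)
}

#' @export
print.tow_scan_panel <- function(x, ...) {
  wt <- attr(x, "wild_type")
  cat(sprintf("panel scan of '%s': wild-type upper limit %g%s\n",
              wt$parameter, wt$upper_limit,
              if (wt$censored) " (censored)" else ""))
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}
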