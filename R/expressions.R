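# Restricted arithmetic grammar for rate, trigger and assignment
# expressions. Expressions are parsed with the R parser but validated
# against a whitelist of operators and functions and against the model's
# symbol table, so a model file cannot execute arbitrary code.

.allowed_calls <- c("+", "-", "*", "/", "^", "(",
                    "min", "max", "exp", "log", "sqrt", "abs", "hill",
                    "<", "<=", ">", ">=", "==", "&", "|", "!")

#' Hill activation term
#'
#' `x^n / (k^n + x^n)`, available inside model rate expressions.
#'
#' @param x input concentration.
#' @param k half-saturation constant.
#' @param n Hill coefficient.
#' @export
hill <- function(x, k, n) {
  xn <- x^n
  xn / (k^n + xn)
}

# Parse a single expression string; returns the unevaluated call.
parse_rate <- function(text, where) {
  ex <- tryCatch(parse(text = text, keep.source = FALSE),
                 error = function(e)
                   stop_parse("%s: cannot parse '%s' (%s)",
                              where, text, conditionMessage(e)))
  if (length(ex) != 1L)
    stop_parse("%s: expected a single expression, got %d", where, length(ex))
  ex[[1]]
}

# Collect symbol names and called function names from an expression tree.
walk_expr <- function(e, syms = character(), calls = character()) {
  if (is.name(e)) {
    syms <- c(syms, as.character(e))
  } else if (is.call(e)) {
    fn <- e[[1]]
    if (!is.name(fn))
      stop_parse("computed function calls are not allowed in model expressions")
    calls <- c(calls, as.character(fn))
    for (arg in as.list(e)[-1]) {
      res <- walk_expr(arg, syms, calls)
      syms <- res$syms; calls <- res$calls
    }
  } else if (!(is.numeric(e) || is.logical(e))) {
    stop_parse("literal of type '%s' not allowed in model expressions",
               typeof(e))
  }
  list(syms = syms, calls = calls)
}

# Validate an expression against the model symbol table; returns the
# parsed call. `known` is a character vector of resolvable symbols.
check_expr <- function(text, known, where) {
  e <- parse_rate(text, where)
  res <- walk_expr(e)
  bad_calls <- setdiff(unique(res$calls), .allowed_calls)
  if (length(bad_calls))
    stop_parse("%s: function(s) not in the model grammar: %s",
               where, paste(bad_calls, collapse = ", "))
  bad_syms <- setdiff(unique(res$syms), known)
  if (length(bad_syms))
    stop_parse("%s: unresolved symbol(s): %s",
               where, paste(bad_syms, collapse = ", "))
  e
}

# Evaluation environment for model expressions: only whitelisted
# functions plus the state/parameter bindings pushed in at call time.
make_model_env <- function() {
  env <- new.env(parent = baseenv())
  env$hill <- hill
  env$min <- min
  env$max <- max
  env
}
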