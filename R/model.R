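#' Load a declarative ODE cell-cycle model
#'
#' Reads a JSON model file into a validated `tow_model` object. The schema
#' has sections:
#' \describe{
#'   \item{species}{named object, species name to initial value.}
#'   \item{parameters}{named object, parameter name to value.}
#'   \item{rates}{named object, species name to rate expression (restricted
#'     grammar: `+ - * / ^`, `min`, `max`, `exp`, `log`, `sqrt`, `abs`,
#'     `hill(x, k, n)`).}
#'   \item{mass}{optional: `init` and `rate` expression for a cell-mass
#'     variable named `m`, grown alongside the species and typically halved
#'     by a division event.}
#'   \item{events}{array of objects `name`, `trigger` (expression whose
#'     zero crossing fires the event), `direction` (`"down"`, `"up"` or
#'     `"both"`), `assignments` (named object, state variable to
#'     expression).}
#'   \item{viability}{either a division-count rule (`min_divisions`,
#'     `horizon`, `max_mass`, optional `division_event`, default
#'     `"division"`) or a final-state predicate (`expression`, `horizon`).}
#'   \item{gene_map}{named object, gene name to `synthesis` (parameter
#'     names) and `products` (species names); the handle used by in-silico
#'     gene deletion.}
#' }
#' All symbols in every expression must resolve to a species, a parameter,
#' the mass variable `m` or the time symbol `t`; every offence in the file
#' is reported in one error.
#'
#' @param model_file path to a JSON model definition.
#' @return object of class `tow_model`.
#' @export
load_model <- function(model_file) {
  raw <- tryCatch(jsonlite::read_json(model_file, simplifyVector = FALSE),
                  error = function(e)
                    stop_parse("cannot read model file '%s': %s",
                               model_file, conditionMessage(e)))
  validate_model(raw, source = model_file)
}

#' Build a model definition from R lists
#'
#' Programmatic counterpart of [load_model()]; takes the same sections as
#' the file schema.
#'
#' @param species named numeric vector/list of initial values.
#' @param parameters named numeric vector/list.
#' @param rates named character vector/list, one expression per species.
#' @param events list of event lists (`name`, `trigger`, `direction`,
#'   `assignments`).
#' @param viability viability rule list (see [load_model()]).
#' @param mass optional list with `init` and `rate`.
#' @param gene_map named list, gene to `list(synthesis=, products=)`.
#' @param name model name.
#' @return object of class `tow_model`.
#' @export
define_model <- function(species, parameters, rates, events = list(),
                         viability, mass = NULL, gene_map = list(),
                         name = "model") {
  validate_model(list(name = name, species = as.list(species),
                      parameters = as.list(parameters),
                      rates = as.list(rates), mass = mass,
                      events = events, viability = viability,
                      gene_map = gene_map),
                 source = "define_model()")
}

validate_model <- function(raw, source) {
  errs <- character()
  add_err <- function(fmt, ...) errs <<- c(errs, sprintf(fmt, ...))

  species <- unlist(raw$species %||% list())
  parameters <- unlist(raw$parameters %||% list())
  if (!length(species)) add_err("section 'species': at least one species required")
  if (is.null(names(species)) || any(!nzchar(names(species))))
    add_err("section 'species': all species must be named")
  has_mass <- !is.null(raw$mass)
  mass <- NULL
  if (has_mass) {
    if (is.null(raw$mass$init) || is.null(raw$mass$rate))
      add_err("section 'mass': needs 'init' and 'rate'")
    else mass <- list(init = as.numeric(raw$mass$init),
                      rate = as.character(raw$mass$rate))
  }
  state_names <- c(names(species), if (has_mass) "m")
  dup <- state_names[duplicated(state_names)]
  if (length(dup)) add_err("duplicate state name(s): %s", paste(dup, collapse = ", "))
  dupp <- names(parameters)[duplicated(names(parameters))]
  if (length(dupp)) add_err("duplicate parameter name(s): %s", paste(dupp, collapse = ", "))
  clash <- intersect(state_names, names(parameters))
  if (length(clash)) add_err("name(s) used as both state and parameter: %s",
                             paste(clash, collapse = ", "))
  known <- c(state_names, names(parameters), "t")

  rates <- lapply(raw$rates %||% list(), as.character)
  missing_rates <- setdiff(names(species), names(rates))
  if (length(missing_rates))
    add_err("section 'rates': no rate for species %s",
            paste(missing_rates, collapse = ", "))
  extra_rates <- setdiff(names(rates), names(species))
  if (length(extra_rates))
    add_err("section 'rates': rate for unknown species %s",
            paste(extra_rates, collapse = ", "))
  rate_exprs <- list()
  for (sp in intersect(names(rates), names(species))) {
    rate_exprs[[sp]] <- tryCatch(
      check_expr(rates[[sp]], known, sprintf("rate of '%s'", sp)),
      tipigtow_parse_error = function(e) { add_err("%s", conditionMessage(e)); NULL })
  }
  mass_expr <- NULL
  if (has_mass && !is.null(mass))
    mass_expr <- tryCatch(check_expr(mass$rate, known, "mass rate"),
                          tipigtow_parse_error = function(e) {
                            add_err("%s", conditionMessage(e)); NULL })

  events <- lapply(raw$events %||% list(), function(ev) {
    ev <- as.list(ev)
    nm <- ev$name %||% "event"
    direction <- ev$direction %||% "both"
    if (!direction %in% c("down", "up", "both"))
      add_err("event '%s': direction '%s' invalid (must be down, up or both)",
              nm, direction)
    trig <- tryCatch(check_expr(as.character(ev$trigger), known,
                                sprintf("trigger of event '%s'", nm)),
                     tipigtow_parse_error = function(e) {
                       add_err("%s", conditionMessage(e)); NULL })
    assigns <- lapply(ev$assignments %||% list(), as.character)
    bad_target <- setdiff(names(assigns), state_names)
    if (length(bad_target))
      add_err("event '%s': assignment to non-state '%s'", nm,
              paste(bad_target, collapse = ", "))
    assign_exprs <- lapply(seq_along(assigns), function(i)
      tryCatch(check_expr(assigns[[i]], known,
                          sprintf("assignment in event '%s'", nm)),
               tipigtow_parse_error = function(e) {
                 add_err("%s", conditionMessage(e)); NULL }))
    names(assign_exprs) <- names(assigns)
    list(name = nm, trigger = trig, direction = direction,
         assignments = assign_exprs)
  })

  via <- as.list(raw$viability %||% list())
  if (!length(via)) {
    add_err("section 'viability' is required")
  } else if (!is.null(via$expression)) {
    if (is.null(via$horizon) || as.numeric(via$horizon) <= 0)
      add_err("viability: predicate form needs horizon > 0")
    via$expr_parsed <- tryCatch(
      check_expr(as.character(via$expression), known, "viability expression"),
      tipigtow_parse_error = function(e) { add_err("%s", conditionMessage(e)); NULL })
    via$form <- "predicate"
  } else {
    if (is.null(via$min_divisions) || as.numeric(via$min_divisions) < 1)
      add_err("viability: min_divisions must be >= 1")
    if (is.null(via$horizon) || as.numeric(via$horizon) <= 0)
      add_err("viability: horizon must be > 0")
    if (is.null(via$max_mass) || as.numeric(via$max_mass) <= 0)
      add_err("viability: max_mass must be > 0")
    via$division_event <- via$division_event %||% "division"
    ev_names <- vapply(events, function(e) e$name, character(1))
    if (length(events) && !via$division_event %in% ev_names)
      add_err("viability: division event '%s' not defined", via$division_event)
    via$form <- "divisions"
  }

  gene_map <- lapply(raw$gene_map %||% list(), function(g) {
    list(synthesis = as.character(unlist(g$synthesis %||% character())),
         products = as.character(unlist(g$products %||% character())))
  })
  for (gn in names(gene_map)) {
    g <- gene_map[[gn]]
    bad_p <- setdiff(g$synthesis, names(parameters))
    if (length(bad_p)) add_err("gene_map '%s': unknown parameter(s) %s", gn,
                               paste(bad_p, collapse = ", "))
    bad_s <- setdiff(g$products, names(species))
    if (length(bad_s)) add_err("gene_map '%s': unknown species %s", gn,
                               paste(bad_s, collapse = ", "))
  }

  if (length(errs))
    stop_parse("invalid model (%s):\n- %s", source, paste(errs, collapse = "\n- "))

  structure(list(name = raw$name %||% "model",
                 species = species,
                 parameters = parameters,
                 rates = rate_exprs,
                 mass = if (has_mass) c(mass, list(expr = mass_expr)),
                 events = events,
                 viability = via,
                 gene_map = gene_map),
            class = "tow_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tow_model <- function(x, ...) {
  cat(sprintf("ODE model '%s': %d species, %d parameters, %d event(s)%s\n",
              x$name, length(x$species), length(x$parameters),
              length(x$events), if (!is.null(x$mass)) ", mass variable" else ""))
  cat(sprintf("viability: %s\n",
              if (x$viability$form == "predicate")
                sprintf("final state satisfies %s within t = %s",
                        deparse(x$viability$expr_parsed), x$viability$horizon)
              else
                sprintf(">= %s '%s' events within t = %s, mass <= %s",
                        x$viability$min_divisions, x$viability$division_event,
                        x$viability$horizon, x$viability$max_mass)))
  if (length(x$gene_map))
    cat("genes:", paste(names(x$gene_map), collapse = ", "), "\n")
  invisible(x)
}

#' In-silico gene deletion
#'
#' Builds a mutant specification that zeroes the gene's synthesis-rate
#' parameter(s) and the initial values of its product species. The state
#' dimension is unchanged, so mutant and wild-type trajectories stay
#' directly comparable.
#'
#' @param model a `tow_model`.
#' @param gene gene name present in the model's `gene_map`.
#' @return object of class `mutant_spec` with fields `deleted_genes` and
#'   `overrides` (parameter name to value).
#' @export
apply_deletion <- function(model, gene) {
  stopifnot(inherits(model, "tow_model"))
  if (!gene %in% names(model$gene_map))
    stop_invalid("gene '%s' is not in the model's gene_map", gene)
  synth <- model$gene_map[[gene]]$synthesis
  mutant_spec(deleted_genes = gene,
              overrides = stats::setNames(rep(0, length(synth)), synth))
}

#' Mutant specification
#'
#' @param deleted_genes character vector of gene names (must exist in the
#'   model's `gene_map` when applied).
#' @param overrides named numeric vector of absolute parameter overrides.
#' @return object of class `mutant_spec`.
#' @export
mutant_spec <- function(deleted_genes = character(), overrides = numeric()) {
  if (length(overrides) && is.null(names(overrides)))
    stop_invalid("parameter overrides must be named")
  structure(list(deleted_genes = as.character(deleted_genes),
                 overrides = unlist(overrides) %||% numeric()),
            class = "mutant_spec")
}

#' @export
print.mutant_spec <- function(x, ...) {
  del <- if (length(x$deleted_genes)) paste(x$deleted_genes, collapse = ", ")
         else "none"
  ov <- if (length(x$overrides))
    paste(sprintf("%s=%g", names(x$overrides), x$overrides), collapse = ", ")
  else "none"
  cat(sprintf("mutant: deletions [%s]; overrides [%s]\n", del, ov))
  invisible(x)
}

# Resolve a model + mutant into the parameter vector and initial state
# actually integrated.
resolve_mutant <- function(model, mutant = NULL) {
  pars <- model$parameters
  y0 <- model$species
  if (!is.null(mutant)) {
    if (!inherits(mutant, "mutant_spec"))
      stop_invalid("mutant must be a mutant_spec")
    bad <- setdiff(mutant$deleted_genes, names(model$gene_map))
    if (length(bad))
      stop_invalid("deleted gene(s) not in gene_map: %s",
                   paste(bad, collapse = ", "))
    for (g in mutant$deleted_genes) {
      gm <- model$gene_map[[g]]
      pars[gm$synthesis] <- 0
      y0[gm$products] <- 0
    }
    bad_p <- setdiff(names(mutant$overrides), names(pars))
    if (length(bad_p))
      stop_invalid("override(s) for unknown parameter(s): %s",
                   paste(bad_p, collapse = ", "))
    pars[names(mutant$overrides)] <- mutant$overrides
  }
  if (!is.null(model$mass)) y0 <- c(y0, m = model$mass$init)
  list(pars = pars, y0 = y0)
}
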