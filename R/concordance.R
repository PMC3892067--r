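#' Read gene-mapping rules
#'
#' Tab-delimited rules mapping experimental deletion strains onto model
#' mutants, with header
#' `strain_gene  mode  model_target  partner`. `mode` is one of
#' `direct` (strain gene exists as a model gene), `lumped-pair` (the
#' strain gene and its `partner` paralog are one lumped model gene,
#' `model_target`) or `complex-component` (the gene contributes to one or
#' more transcription-factor complexes; `model_target` is a
#' comma-separated list of the complexes' activity parameters, which the
#' mutant sets to 0).
#'
#' @param path file path.
#' @return data.frame of rules.
#' @export
read_mapping_rules <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  needed <- c("strain_gene", "mode", "model_target", "partner")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop_invalid("rules table lacks column(s): %s",
                 paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(tab$mode),
                 c("direct", "lumped-pair", "complex-component"))
  if (length(bad))
    stop_invalid("unknown mapping mode(s): %s", paste(bad, collapse = ", "))
  if (any(tab$mode == "lumped-pair" & (is.na(tab$partner) | !nzchar(tab$partner))))
    stop_invalid("lumped-pair rules must name a partner gene")
  tab[needed]
}

#' Packaged paralog-lumping rules for cell-cycle models
#'
#' The conventional lumpings used when a cell-cycle ODE model represents
#' paralog pairs as single genes: Clb1/Clb2, Clb5/Clb6, Cln1/Cln2 and
#' Cln3/Bck2 each map to one lumped model gene, and Swi6 is represented
#' through the activity of the SBF (with Swi4) and MBF (with Mbp1)
#' transcription-factor complexes.
#'
#' @return data.frame of mapping rules (see [read_mapping_rules()]).
#' @export
lumped_gene_rules <- function() {
  read_mapping_rules(system.file("extdata", "lumped_gene_rules.tsv",
                                 package = "tipigtow", mustWork = TRUE))
}

#' Map a deletion strain onto a model mutant
#'
#' Resolves an experimental gene name to a [mutant_spec()] using the
#' mapping rules; genes without a rule fall back to a direct
#' (case-insensitive) match against the model's `gene_map`.
#'
#' For `lumped-pair` rules, `dose = "full-knockout"` (default) deletes the
#' lumped model gene outright; `dose = "half-dose"` halves its synthesis
#' rate(s) instead, reflecting loss of one of the two paralogs.
#' `complex-component` rules zero each affected complex's activity
#' parameter.
#'
#' @param gene experimental gene name (e.g. `"cln1"`).
#' @param rules rules data.frame (see [read_mapping_rules()]); may be
#'   `NULL` for direct-only mapping.
#' @param model a `tow_model`.
#' @param dose `"full-knockout"` or `"half-dose"` for lumped pairs.
#' @return a [mutant_spec()].
#' @export
map_strain_to_mutant <- function(gene, rules = NULL, model,
                                 dose = c("full-knockout", "half-dose")) {
  dose <- match.arg(dose)
  stopifnot(inherits(model, "tow_model"))
  rule <- NULL
  if (!is.null(rules)) {
    hit <- which(tolower(rules$strain_gene) == tolower(gene))
    if (length(hit) > 1L)
      stop_invalid("gene '%s' matches %d rules; rules must be unambiguous",
                   gene, length(hit))
    if (length(hit) == 1L) rule <- rules[hit, ]
  }
  if (is.null(rule)) {
    direct <- names(model$gene_map)[tolower(names(model$gene_map)) ==
                                      tolower(gene)]
    if (!length(direct))
      stop_unmapped("gene '%s' has no mapping rule and no direct model gene",
                    gene)
    return(apply_deletion(model, direct[[1]]))
  }
  switch(rule$mode,
         direct = apply_deletion(model, rule$model_target),
         `lumped-pair` = {
           if (!rule$model_target %in% names(model$gene_map))
             stop_unmapped("lumped model gene '%s' not in gene_map",
                           rule$model_target)
           if (dose == "full-knockout") {
             apply_deletion(model, rule$model_target)
           } else {
             synth <- model$gene_map[[rule$model_target]]$synthesis
             mutant_spec(overrides = stats::setNames(
               0.5 * model$parameters[synth], synth))
           }
         },
         `complex-component` = {
           pars <- trimws(strsplit(rule$model_target, ",")[[1]])
           bad <- setdiff(pars, names(model$parameters))
           if (length(bad))
             stop_unmapped("complex activity parameter(s) not in model: %s",
                           paste(bad, collapse = ", "))
           mutant_spec(overrides = stats::setNames(rep(0, length(pars)), pars))
         })
}

#' Sign concordance between experimental and simulated changes
#'
#' Per-gene comparison of the experimental relative copy-number change
#' with the simulated relative degradation-rate change. Two changes agree
#' when both lie outside the dead band and share a sign, disagree when
#' both lie outside with opposite signs, and are indeterminate when
#' either falls inside the dead band or is missing/censored.
#'
#' @param experimental,simulated named numeric vectors (gene to change) or
#'   data.frames with columns `gene` and `change`.
#' @param dead_band half-width of the indeterminate zone (default 0.05).
#' @return object of class `tow_concordance`: data.frame `gene`,
#'   `experimental_change`, `simulated_change`, `agreement`, with
#'   attributes `summary` (agree/disagree/indeterminate counts) and
#'   `unmatched` (genes present on only one side, not scored).
#' @export
sign_concordance <- function(experimental, simulated, dead_band = 0.05) {
  as_named <- function(x, what) {
    if (is.data.frame(x)) {
      if (!all(c("gene", "change") %in% names(x)))
        stop_invalid("%s data.frame needs columns 'gene' and 'change'", what)
      stats::setNames(x$change, x$gene)
    } else {
      if (is.null(names(x))) stop_invalid("%s vector must be named by gene", what)
      x
    }
  }
  ex <- as_named(experimental, "experimental")
  si <- as_named(simulated, "simulated")
  common <- intersect(names(ex), names(si))
  if (!length(common))
    stop_invalid("no genes shared between experimental and simulated inputs")
  e <- ex[common]; s <- si[common]
  verdict <- function(a, b) {
    if (is.na(a) || is.na(b)) return("indeterminate")
    if (abs(a) <= dead_band || abs(b) <= dead_band) return("indeterminate")
    if (sign(a) == sign(b)) "agree" else "disagree"
  }
  agreement <- mapply(verdict, e, s)
  out <- data.frame(gene = common, experimental_change = unname(e),
                    simulated_change = unname(s),
                    agreement = unname(agreement), stringsAsFactors = FALSE)
  counts <- c(agree = sum(agreement == "agree"),
              disagree = sum(agreement == "disagree"),
              indeterminate = sum(agreement == "indeterminate"))
  structure(out, class = c("tow_concordance", "data.frame"),
            summary = counts, dead_band = dead_band,
            unmatched = list(experimental_only = setdiff(names(ex), common),
                             simulated_only = setdiff(names(si), common)))
}

#' @export
print.tow_concordance <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE, ...)
  s <- attr(x, "summary")
  cat(sprintf("agree %d / disagree %d / indeterminate %d (dead band %.2f)\n",
              s[["agree"]], s[["disagree"]], s[["indeterminate"]],
              attr(x, "dead_band")))
  un <- attr(x, "unmatched")
  if (length(un$experimental_only))
    cat("experimental only:", paste(un$experimental_only, collapse = ", "), "\n")
  if (length(un$simulated_only))
    cat("simulated only:", paste(un$simulated_only, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tow_concordance <- function(object, ...) attr(object, "summary")

#' Side-by-side bar chart of experimental vs simulated changes
#'
#' @param x a `tow_concordance`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.tow_concordance <- function(x, ...) {
  m <- t(as.matrix(x[, c("experimental_change", "simulated_change")]))
  graphics::barplot(m, beside = TRUE, names.arg = x$gene, las = 2,
                    legend.text = c("experimental", "simulated"),
                    ylab = "relative change", ...)
  graphics::abline(h = 0)
  invisible(x)
}
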