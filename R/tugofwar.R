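#' Per-strain copy-number record
#'
#' Bundles the vector-plasmid and TEV-plasmid copy-number estimates of one
#' strain. In a TIPI-gTOW panel the empty vector controls for strain-level
#' differences in plasmid replication and partitioning; the TEV plasmid
#' carries the protease whose copy-number ceiling reports the target
#' protein's lower expression limit.
#'
#' @param strain strain identifier, e.g. `"bck2"` or `"Wild type"`.
#' @param vector,tev copy-number estimates: `cn_estimate` objects from
#'   [summarize_replicates()], or lists/vectors with elements `mean`, `sd`,
#'   `n` (only `mean` is required).
#' @return object of class `strain_record`.
#' @export
strain_record <- function(strain, vector, tev) {
  as_est <- function(x, what) {
    x <- as.list(x)
    if (is.null(x$mean) || !is.finite(x$mean) || x$mean <= 0)
      stop_invalid("%s mean copy number of '%s' must be positive", what, strain)
    structure(list(mean = as.numeric(x$mean),
                   sd = if (is.null(x$sd)) NA_real_ else as.numeric(x$sd),
                   n = if (is.null(x$n)) NA_integer_ else as.integer(x$n)),
              class = "cn_estimate")
  }
  if (!is.character(strain) || length(strain) != 1L || !nzchar(strain))
    stop_invalid("strain identifier must be a non-empty string")
  structure(list(strain = strain,
                 vector = as_est(vector, "vector"),
                 tev = as_est(tev, "TEV")),
            class = "strain_record")
}

#' @export
print.strain_record <- function(x, ...) {
  cat(sprintf("%s: vector %.1f, TEV %.1f, TEV/vector %.3f\n",
              x$strain, x$vector$mean, x$tev$mean, tev_vector_ratio(x)))
  invisible(x)
}

#' TEV/vector copy-number ratio of one strain
#'
#' @param record a [strain_record()].
#' @return `tev$mean / vector$mean` (dimensionless).
#' @export
tev_vector_ratio <- function(record) {
  if (!inherits(record, "strain_record"))
    stop_invalid("record must be a strain_record")
  record$tev$mean / record$vector$mean
}

#' Relative copy-number change of a strain against a reference
#'
#' The per-strain statistic of the tug-of-war panel:
#' `(r - r_ref) / r_ref` where `r` is the strain's TEV/vector ratio and
#' `r_ref` the reference (wild-type) ratio. Normalising by the vector
#' ratio removes strain-level differences in plasmid maintenance before
#' comparing TEV copy-number ceilings.
#'
#' @param record strain of interest.
#' @param reference reference strain (typically wild type).
#' @return dimensionless relative change (always `> -1` for positive
#'   ratios). Negative values mean the TEV ceiling dropped, i.e. the
#'   target's lower limit rose in that background.
#' @export
relative_copy_number_change <- function(record, reference) {
  tev_vector_ratio(record) / tev_vector_ratio(reference) - 1
}

#' Classify the direction of a genetic interaction
#'
#' Maps a relative copy-number change onto the direction of the implied
#' change in the target's lower expression limit, with a dead band around
#' zero to absorb measurement noise.
#'
#' @param relative_change dimensionless relative change(s).
#' @param dead_band half-width of the neutral zone (default 0.05).
#' @return character vector over
#'   `{"lower-limit-increased", "lower-limit-decreased", "neutral"}`.
#'   A negative change (TEV ceiling dropped) means the lower limit rose:
#'   candidate synthetic-lethal / dosage-rescue partner. A positive change
#'   means the lower limit fell: candidate synthetic-rescue /
#'   dosage-lethality partner.
#' @export
classify_interaction <- function(relative_change, dead_band = 0.05) {
  if (!is.numeric(dead_band) || length(dead_band) != 1L || dead_band < 0)
    stop_invalid("dead_band must be a single non-negative number")
  ifelse(is.na(relative_change), NA_character_,
         ifelse(relative_change < -dead_band, "lower-limit-increased",
                ifelse(relative_change > dead_band, "lower-limit-decreased",
                       "neutral")))
}

#' Panel report: ratios, relative changes and interaction calls
#'
#' Computes the TEV/vector ratio for every strain, the relative
#' copy-number change against the named reference strain, and the sign
#' classification, preserving input order. Rounding happens only at
#' serialization ([write_panel_report()]).
#'
#' @param records list of [strain_record()] objects.
#' @param reference_name strain identifier of the reference (default
#'   `"Wild type"`); its own relative change is reported as `NA`.
#' @param dead_band neutral zone half-width for [classify_interaction()].
#' @param delta_method_se also compute a first-order (delta-method)
#'   standard error of each ratio from the replicate SDs. This is an
#'   add-on diagnostic, not part of the original panel statistic.
#' @return data.frame of class `tow_panel` with columns `strain`,
#'   `vector_mean`, `tev_mean`, `ratio`, `relative_change`,
#'   `classification` (plus `ratio_se` if requested).
#' @export
build_panel_report <- function(records, reference_name = "Wild type",
                               dead_band = 0.05, delta_method_se = FALSE) {
  if (!length(records)) stop_invalid("empty strain panel")
  names_vec <- vapply(records, function(r) r$strain, character(1))
  dup <- names_vec[duplicated(names_vec)]
  if (length(dup))
    stop_invalid("duplicate strain name(s) in panel: %s",
                 paste(unique(dup), collapse = ", "))
  ref_idx <- match(reference_name, names_vec)
  if (is.na(ref_idx))
    stop_invalid("reference strain '%s' not present in panel", reference_name)
  reference <- records[[ref_idx]]
  ratio <- vapply(records, tev_vector_ratio, numeric(1))
  rel <- vapply(records, relative_copy_number_change, numeric(1),
                reference = reference)
  rel[ref_idx] <- NA_real_
  out <- data.frame(strain = names_vec,
                    vector_mean = vapply(records, function(r) r$vector$mean,
                                         numeric(1)),
                    tev_mean = vapply(records, function(r) r$tev$mean,
                                      numeric(1)),
                    ratio = ratio,
                    relative_change = rel,
                    classification = classify_interaction(rel, dead_band),
                    stringsAsFactors = FALSE)
  if (delta_method_se) {
    se_one <- function(r) {
      cv2 <- function(e) {
        if (is.na(e$sd) || is.na(e$n) || e$n < 2L) return(NA_real_)
        (e$sd / e$mean)^2 / e$n
      }
      tev_vector_ratio(r) * sqrt(cv2(r$tev) + cv2(r$vector))
    }
    out$ratio_se <- vapply(records, se_one, numeric(1))
  }
  structure(out, class = c("tow_panel", "data.frame"),
            reference = reference_name, dead_band = dead_band)
}

#' @export
print.tow_panel <- function(x, digits = 2, ...) {
  cat(sprintf("TIPI-gTOW panel: %d strains, reference '%s', dead band %.2f\n",
              nrow(x), attr(x, "reference"), attr(x, "dead_band")))
  shown <- as.data.frame(x)
  shown$ratio <- round(shown$ratio, digits)
  shown$relative_change <- round(shown$relative_change, digits)
  print(shown, row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.tow_panel <- function(object, ...) {
  cls <- table(factor(object$classification,
                      levels = c("lower-limit-increased", "neutral",
                                 "lower-limit-decreased")))
  cat(sprintf("strains: %d (reference '%s' excluded from calls)\n",
              nrow(object), attr(object, "reference")))
  print(cls)
  invisible(cls)
}

#' Bar chart of relative copy-number changes
#'
#' @param x a `tow_panel`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.tow_panel <- function(x, ...) {
  keep <- !is.na(x$relative_change)
  graphics::barplot(x$relative_change[keep], names.arg = x$strain[keep],
                    las = 2, ylab = "relative copy-number change", ...)
  graphics::abline(h = 0)
  invisible(x)
}

#' Read a per-strain copy-number summary table
#'
#' Tab-delimited with header
#' `strain  vector_mean  vector_sd  tev_mean  tev_sd  n`.
#'
#' @param path file path.
#' @return list of [strain_record()] objects in file order.
#' @export
read_panel_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("strain", "vector_mean", "vector_sd", "tev_mean", "tev_sd", "n")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop_invalid("panel table lacks column(s): %s",
                 paste(missing_cols, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i)
    strain_record(tab$strain[i],
                  vector = list(mean = tab$vector_mean[i],
                                sd = tab$vector_sd[i], n = tab$n[i]),
                  tev = list(mean = tab$tev_mean[i],
                             sd = tab$tev_sd[i], n = tab$n[i])))
}

#' Write a panel report as TSV
#'
#' Serializes with round-half-to-even at 2 decimal places for the ratio
#' and relative-change columns (matching the precision such panels are
#' conventionally reported at).
#'
#' @param panel a `tow_panel` from [build_panel_report()].
#' @param path output file path.
#' @export
write_panel_report <- function(panel, path) {
  out <- as.data.frame(panel)
  out$ratio <- round(out$ratio, 2)
  out$relative_change <- round(out$relative_change, 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged CDC20 TIPI-gTOW deletion-panel copy numbers
#'
#' The published copy-number summary of the CDC20 TIPI-gTOW experiment:
#' mean and SD of vector and TEV plasmid copy numbers (4 independent
#' qPCR measurements each) for wild type plus 23 cell-cycle-regulator
#' deletion strains. The growth condition (-Ura vs -Ura-Leu) is not
#' recorded in the source and is left unspecified here.
#'
#' @return list of 24 [strain_record()] objects.
#' @export
cdc20_panel <- function() {
  read_panel_table(system.file("extdata", "cdc20_panel.tsv",
                               package = "tipigtow", mustWork = TRUE))
}
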