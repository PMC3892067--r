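#' Plasmid copy number from a qPCR crossing-point pair
#'
#' Converts one pair of real-time PCR crossing points -- one for a
#' plasmid-borne marker, one for a single-copy genomic reference -- into a
#' plasmid copy number per haploid genome, assuming perfect doubling per
#' cycle (PCR efficiency fixed at 2).
#'
#' Because a more abundant template crosses the detection threshold
#' *earlier*, the physically meaningful exponent is
#' `cp_reference - cp_marker`: a marker that crosses 7 cycles before the
#' reference corresponds to `2^7 = 128` copies. The
#' `exponent_order = "marker-reference"` option computes the literal
#' reversed difference `2^(cp_marker - cp_reference)` for comparison with
#' sources that print the formula that way.
#'
#' @param cp_marker crossing point(s) of the plasmid marker amplification
#'   (cycles).
#' @param cp_reference crossing point(s) of the genomic reference
#'   amplification (cycles).
#' @param exponent_order `"reference-marker"` (default, physical
#'   orientation) or `"marker-reference"` (literal reversed difference).
#' @return numeric vector of copies per haploid genome.
#' @examples
#' copy_number_from_cp(12, 12)      # 1
#' copy_number_from_cp(5, 12)       # 2^7 = 128
#' @export
copy_number_from_cp <- function(cp_marker, cp_reference,
                                exponent_order = c("reference-marker",
                                                   "marker-reference")) {
  exponent_order <- match.arg(exponent_order)
  if (length(cp_marker) == 1L) cp_marker <- rep(cp_marker, length(cp_reference))
  if (length(cp_reference) == 1L) cp_reference <- rep(cp_reference, length(cp_marker))
  if (length(cp_marker) != length(cp_reference))
    stop_invalid("cp_marker and cp_reference must have equal length")
  if (!is.numeric(cp_marker) || !is.numeric(cp_reference) ||
      !all(is.finite(cp_marker)) || !all(is.finite(cp_reference)))
    stop_invalid("crossing points must be finite numbers")
  if (any(cp_marker <= 0) || any(cp_reference <= 0))
    stop_invalid("crossing points must be > 0 cycles")
  out_of_range <- cp_marker < 5 | cp_marker > 40 |
    cp_reference < 5 | cp_reference > 40
  if (any(out_of_range))
    warning(sprintf("%d crossing point pair(s) outside the typical 5-40 cycle range",
                    sum(out_of_range)))
  if (exponent_order == "reference-marker")
    2^(cp_reference - cp_marker)
  else
    2^(cp_marker - cp_reference)
}

#' Summarize replicate copy-number measurements
#'
#' @param values numeric vector of positive copy numbers, one per
#'   independent measurement.
#' @return an object of class `cn_estimate`: list with `mean` (arithmetic
#'   mean), `sd` (sample standard deviation, `n - 1` denominator; `NA` for
#'   a single replicate) and `n`.
#' @examples
#' summarize_replicates(c(2, 4, 4, 6))
#' @export
summarize_replicates <- function(values) {
  if (length(values) == 0L) stop_invalid("no replicate values supplied")
  if (!is.numeric(values) || !all(is.finite(values)))
    stop_invalid("replicate values must be finite numbers")
  if (any(values <= 0)) stop_invalid("copy numbers must be positive")
  structure(list(mean = mean(values),
                 sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
                 n = length(values)),
            class = "cn_estimate")
}

#' @export
print.cn_estimate <- function(x, ...) {
  cat(sprintf("copy-number estimate: mean %.3g, sd %s, n = %d\n",
              x$mean, if (is.na(x$sd)) "NA" else sprintf("%.3g", x$sd), x$n))
  invisible(x)
}

#' Student's t-test between two groups of copy numbers
#'
#' Classical two-sided two-sample t-test; pooled (equal-variance) by
#' default, Welch on request.
#'
#' @param group_a,group_b numeric vectors, each with at least two values.
#' @param var_equal pool the variances (classical Student test, default
#'   `TRUE`); `FALSE` gives the Welch test.
#' @return list with `statistic`, `df`, `p_value` and `method`.
#' @examples
#' two_sample_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
two_sample_t_test <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_invalid("each group needs at least 2 values for a t-test")
  if (!all(is.finite(group_a)) || !all(is.finite(group_b)))
    stop_invalid("group values must be finite numbers")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
    stop_degenerate("both groups have zero variance; t statistic undefined")
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = ht$p.value,
       method = if (var_equal) "student" else "welch")
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length, at least 3 values each,
#'   neither constant.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) < 3L) stop_invalid("need at least 3 paired values")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_invalid("values must be finite numbers")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_degenerate("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Read a crossing-point table
#'
#' Expects a UTF-8, tab-delimited file with header
#' `strain  plasmid  replicate  cp_marker  cp_reference`, with `plasmid`
#' one of `"vector"` or `"tev"` and `.` as decimal separator.
#'
#' @param path file path.
#' @return data.frame with the five columns above.
#' @export
read_cp_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("strain", "plasmid", "replicate", "cp_marker", "cp_reference")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop_invalid("crossing-point table lacks column(s): %s",
                 paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(tab$plasmid), c("vector", "tev"))
  if (length(bad))
    stop_invalid("unknown plasmid label(s): %s", paste(bad, collapse = ", "))
  tab[needed]
}

#' Per strain-by-plasmid copy-number estimates from crossing points
#'
#' Converts each crossing-point pair to a copy number and summarizes the
#' replicates of every strain-plasmid combination.
#'
#' @param cp_table data.frame as returned by [read_cp_table()].
#' @inheritParams copy_number_from_cp
#' @return data.frame `strain, plasmid, n, mean_copy, sd_copy`, one row per
#'   strain-plasmid combination, in first-appearance order.
#' @export
estimate_copy_numbers <- function(cp_table,
                                  exponent_order = "reference-marker") {
  copies <- copy_number_from_cp(cp_table$cp_marker, cp_table$cp_reference,
                                exponent_order = exponent_order)
  key <- paste(cp_table$strain, cp_table$plasmid, sep = "\r")
  keys <- unique(key)
  rows <- lapply(keys, function(k) {
    est <- summarize_replicates(copies[key == k])
    i <- match(k, key)
    data.frame(strain = cp_table$strain[i], plasmid = cp_table$plasmid[i],
               n = est$n, mean_copy = est$mean, sd_copy = est$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write per-strain copy-number estimates as TSV
#'
#' @param estimates data.frame from [estimate_copy_numbers()].
#' @param path output file path.
#' @export
write_copy_table <- function(estimates, path) {
  utils::write.table(estimates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
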