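#' Configuration for synthetic qPCR data
#'
#' Ground truth and noise model for simulated crossing-point data. Noise
#' is placed on the crossing points (cycles), not on the copy numbers:
#' qPCR error is multiplicative on template abundance, and a cycle-scale
#' SD of 0.2 reproduces the 10-30% coefficients of variation typical of
#' replicate plasmid copy-number measurements. Four replicates per
#' strain-plasmid combination is the convention for such panels.
#'
#' @param true_copy_numbers data.frame with columns `strain`, `plasmid`,
#'   `copies` (`copies > 0`).
#' @param cp_noise_sd SD of the crossing-point noise in cycles
#'   (default 0.2).
#' @param reference_cp_base mean crossing point of the genomic reference
#'   (default 22 cycles).
#' @param replicates_per_strain independent measurements per
#'   strain-plasmid combination (default 4).
#' @param seed RNG seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(true_copy_numbers, cp_noise_sd = 0.2,
                             reference_cp_base = 22, replicates_per_strain = 4,
                             seed = 1L) {
  if (!is.data.frame(true_copy_numbers) ||
      !all(c("strain", "plasmid", "copies") %in% names(true_copy_numbers)))
    stop_invalid("true_copy_numbers needs columns strain, plasmid, copies")
  if (any(true_copy_numbers$copies <= 0))
    stop_invalid("true copy numbers must be positive")
  if (cp_noise_sd < 0) stop_invalid("cp_noise_sd must be >= 0")
  if (replicates_per_strain < 1) stop_invalid("need at least 1 replicate")
  structure(list(true_copy_numbers = true_copy_numbers,
                 cp_noise_sd = cp_noise_sd,
                 reference_cp_base = reference_cp_base,
                 replicates_per_strain = as.integer(replicates_per_strain),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate synthetic qPCR crossing-point replicates
#'
#' For each strain-plasmid-replicate, draws
#' `cp_reference ~ Normal(reference_cp_base, cp_noise_sd)` and sets
#' `cp_marker = cp_reference - log2(true copies) + Normal(0, cp_noise_sd)`,
#' independently across rows, so the noiseless limit inverts exactly
#' through [copy_number_from_cp()]. Note that the resulting `2^Normal`
#' copy-number estimator is median-unbiased but mean-biased upward.
#'
#' @param config a [synthetic_config()].
#' @return data.frame `strain, plasmid, replicate, cp_marker,
#'   cp_reference`, reproducible from `config$seed`.
#' @export
generate_qpcr_replicates <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tc <- config$true_copy_numbers
  n_rep <- config$replicates_per_strain
  idx <- rep(seq_len(nrow(tc)), each = n_rep)
  n <- length(idx)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  cp_ref <- stats::rnorm(n, config$reference_cp_base, config$cp_noise_sd)
  cp_marker <- cp_ref - log2(tc$copies[idx]) +
    stats::rnorm(n, 0, config$cp_noise_sd)
  data.frame(strain = tc$strain[idx], plasmid = tc$plasmid[idx],
             replicate = rep(seq_len(n_rep), times = nrow(tc)),
             cp_marker = cp_marker, cp_reference = cp_ref,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic tug-of-war strain panel with known ground truth
#'
#' Emulates the observable layer of a TIPI-gTOW deletion panel: vector
#' copy numbers are drawn per strain from a log-normal spread (matching
#' the roughly 20-150 copy range such panels show), TEV copy numbers are
#' `vector * reference_ratio * (1 + effect)`, and both are pushed through
#' the synthetic qPCR generator and the copy-number pipeline. The
#' tug-of-war itself is not modelled mechanistically; only the measured
#' layer is sampled.
#'
#' @param reference_ratio true TEV/vector ratio of the reference strain
#'   (default 0.4).
#' @param strain_effects named numeric vector, gene to true relative
#'   copy-number change (all `> -1`); the reference strain `"Wild type"`
#'   with effect 0 is added automatically.
#' @param cp_noise_sd,replicates_per_strain,seed as in
#'   [synthetic_config()].
#' @param vector_meanlog,vector_sdlog log-normal parameters of the true
#'   vector copy numbers (defaults `log(70)` and `0.4`).
#' @return list with `records` (list of [strain_record()]), `truth`
#'   (data.frame `strain`, `true_vector`, `true_tev`, `true_effect`),
#'   `cp_data` (the synthetic crossing-point table) and `config`.
#' @export
generate_tugofwar_panel <- function(reference_ratio = 0.4, strain_effects,
                                    cp_noise_sd = 0.2,
                                    replicates_per_strain = 4, seed = 1L,
                                    vector_meanlog = log(70),
                                    vector_sdlog = 0.4) {
  if (reference_ratio <= 0) stop_invalid("reference_ratio must be positive")
  if (is.null(names(strain_effects)) || any(!nzchar(names(strain_effects))))
    stop_invalid("strain_effects must be named by gene")
  if (any(strain_effects <= -1))
    stop_invalid("true effects must be > -1 (ratios must stay positive)")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  strains <- c("Wild type", names(strain_effects))
  effects <- c(0, unname(strain_effects))
  true_vector <- stats::rlnorm(length(strains), vector_meanlog, vector_sdlog)
  true_tev <- true_vector * reference_ratio * (1 + effects)
  truth <- data.frame(strain = strains, true_vector = true_vector,
                      true_tev = true_tev, true_effect = effects,
                      stringsAsFactors = FALSE)
  tc <- rbind(data.frame(strain = strains, plasmid = "vector",
                         copies = true_vector, stringsAsFactors = FALSE),
              data.frame(strain = strains, plasmid = "tev",
                         copies = true_tev, stringsAsFactors = FALSE))
  config <- synthetic_config(tc, cp_noise_sd = cp_noise_sd,
                             replicates_per_strain = replicates_per_strain,
                             seed = sample.int(.Machine$integer.max - 1L, 1))
  cp_data <- generate_qpcr_replicates(config)
  est <- estimate_copy_numbers(cp_data)
  records <- lapply(strains, function(s) {
    v <- est[est$strain == s & est$plasmid == "vector", ]
    tv <- est[est$strain == s & est$plasmid == "tev", ]
    strain_record(s, vector = list(mean = v$mean_copy, sd = v$sd_copy, n = v$n),
                  tev = list(mean = tv$mean_copy, sd = tv$sd_copy, n = tv$n))
  })
  list(records = records, truth = truth, cp_data = cp_data, config = config)
}
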