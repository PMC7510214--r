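#' Run the full two-tier screening validation end to end
#'
#' Generates a synthetic cohort with the requested genotype composition,
#' lays it out on 96-well plates with control reactions, simulates melt
#' curves, calls peaks, validates plate QC, applies the first-tier decision
#' rules, resolves retests (each retest re-simulates the well as a fresh
#' reaction), runs the second-tier MLPA simulation and copy-number calling
#' on every sample, and scores the result against generator truth.
#'
#' A sample's final result is positive when the first tier refers it and
#' MLPA confirms 0 SMN1 copies. Specimens carrying a non-deletion
#' pathogenic SMN1 variant (`smn1_functional_copies < smn1_copies`, e.g. an
#' intragenic point mutation) present a normal melt profile by design; the
#' pipeline reports them as `n_designed_misses` rather than hiding them.
#'
#' @param composition Genotype composition data frame (see
#'   [generate_cohort()]); defaults to the 422-sample validation cohort.
#' @param config An [sim_config()] object.
#' @param seed Integer seed; identical inputs and seed give identical
#'   results.
#'
#' @return An object of class `smn_validation`: a list with elements
#'   `samples` (per-sample truth, tier-1 and MLPA results), `plate_qc`,
#'   `peaks`, `metrics` (one-row tibble), `cn_table`, `config`, `seed`.
#'   Use [glance.smn_validation()] for the metrics and
#'   [tidy.smn_validation()] for per-sample rows.
#' @examples
#' \donttest{
#' res <- run_validation(seed = 1)
#' glance(res)
#' }
#' @export
run_validation <- function(composition = validation_composition(),
                           config = sim_config(), seed = 1L) {
  cohort <- generate_cohort(composition, seed = seed, config = config)
  if (nrow(cohort) == 0) abort("empty composition")
  layout <- build_plates(cohort, config)
  curves <- simulate_melt_curves(layout, config,
                                 seed = derive_seed(seed, "plate-curves"))
  peaks <- call_peaks(curves, config)
  qc <- qc_plates(peaks, layout)
  calls <- classify_wells(peaks, layout, qc)

  reanalyze <- function(ids, round) {
    specs <- dplyr::filter(layout, .data$sample_id %in% ids)
    # a retest is a fresh reaction: redraw DNA yield and blood load
    rseed <- derive_seed(seed, paste0("retest-", round))
    withr::with_seed(rseed, {
      specs$input_dna_ng <- rlnorm(nrow(specs), config$dna_meanlog,
                                   config$dna_sdlog)
      specs$blood_load <- runif(nrow(specs), config$blood_load_min,
                                config$blood_load_max)
    })
    retest_plate <- dplyr::bind_rows(
      control_specs(sprintf("RT%d", round), config),
      dplyr::select(specs, -"plate_id", -"well"))
    retest_plate$plate_id <- sprintf("RT%d", round)
    retest_plate$well <- paste0(rep(LETTERS[1:8], 12),
                                sprintf("%02d", rep(1:12, each = 8)))[
                                  seq_len(nrow(retest_plate))]
    rcurves <- simulate_melt_curves(retest_plate, config,
                                    seed = derive_seed(rseed, "curves"))
    rpeaks <- call_peaks(rcurves, config)
    classify_wells(rpeaks, retest_plate, qc_plates(rpeaks, retest_plate))
  }
  calls <- resolve_retests(calls, reanalyze, config$max_retest_rounds)

  mlpa_seed <- derive_seed(seed, "mlpa-tier2")
  profiles <- simulate_mlpa_profiles(cohort, config, seed = mlpa_seed)
  refs <- simulate_mlpa_references(3, config, seed = mlpa_seed)
  cn <- mlpa_call_copy_number(mlpa_normalize(profiles, refs), config)
  cn <- mlpa_retest_ambiguous(cn, cohort, config, seed = mlpa_seed)

  samples <- cohort |>
    dplyr::left_join(dplyr::select(calls, "sample_id", "plate_id", "call",
                                   "reason", "sd074_ref_height",
                                   "n_retests"),
                     by = "sample_id") |>
    dplyr::left_join(cn, by = "sample_id") |>
    dplyr::mutate(
      truth_positive = .data$smn1_copies == 0,
      tier1_positive = !is.na(.data$call) & .data$call == "SECOND_TIER",
      final_positive = .data$tier1_positive & .data$confirmed_positive)

  structure(list(samples = samples, plate_qc = qc, peaks = peaks,
                 metrics = cohort_metrics(samples, qc),
                 cn_table = dplyr::count(samples, .data$smn1_cn,
                                         .data$smn2_cn),
                 config = config, seed = seed),
            class = "smn_validation")
}

cohort_metrics <- function(samples, qc) {
  scored <- dplyr::filter(samples, !is.na(.data$call))
  tp <- sum(scored$truth_positive & scored$final_positive)
  fn <- sum(scored$truth_positive & !scored$final_positive)
  tn <- sum(!scored$truth_positive & !scored$final_positive)
  fp <- sum(!scored$truth_positive & scored$final_positive)
  tibble::tibble(
    n_total = nrow(scored),
    n_screen_positive = sum(scored$tier1_positive),
    n_second_tier_controls = sum(scored$tier1_positive &
                                   !scored$truth_positive),
    n_retested = sum(scored$n_retests > 0),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    concordance = mean(scored$tier1_positive ==
                         (!is.na(scored$smn1_cn) & scored$smn1_cn == 0)),
    n_designed_misses = sum(scored$smn1_functional_copies <
                              scored$smn1_copies &
                              scored$smn1_functional_copies == 0 &
                              !scored$final_positive),
    n_ambiguous_mlpa = sum(scored$ambiguous),
    n_mlpa_retests = sum(scored$mlpa_retested),
    n_plates_failed_qc = sum(!qc$valid),
    n_excluded = nrow(samples) - nrow(scored)
  )
}

#' Input-range experiment: DNA titration and oversaturation
#'
#' Reproduces the assay's input-range behaviour: blood diluted 1x
#' (saturated), 4x, 6x and 8x before spotting gives decreasing input DNA,
#' visible as an increasing Q-fragment peak; an oversaturated spot (double
#' blood load) quenches the fluorophore and lowers the whole signal despite
#' carrying more DNA.
#'
#' @param dilutions Positive dilution factors of the spotted blood
#'   (1 = saturated).
#' @param replicates Wells per condition (>= 1).
#' @param config An [sim_config()] object.
#' @param seed Integer seed.
#' @param include_oversaturated Add an oversaturated condition (blood load
#'   2, double DNA)?
#'
#' @return A tibble with one row per condition: `condition`, `dilution`,
#'   `blood_load`, `mean_input_dna_ng`, `mean_q_height`,
#'   `mean_total_signal` (integrated fluorescence).
#' @examples
#' input_range_experiment(seed = 1)
#' @export
input_range_experiment <- function(dilutions = c(1, 4, 6, 8),
                                   replicates = 4,
                                   config = sim_config(), seed = 1L,
                                   include_oversaturated = TRUE) {
  stopifnot(all(dilutions > 0), replicates >= 1)
  cond <- tibble::tibble(
    condition = c(ifelse(dilutions == 1, "saturated",
                         sprintf("%gx diluted", dilutions)),
                  if (include_oversaturated) "oversaturated"),
    dilution = c(dilutions, if (include_oversaturated) 0.5),
    blood_load = c(1 / dilutions, if (include_oversaturated) 2))
  sat_yield <- exp(config$dna_meanlog)
  wells <- cond |>
    tidyr::uncount(replicates) |>
    dplyr::mutate(sample_id = sprintf("IR%03d", dplyr::row_number()),
                  smn1_copies = 2L, smn2_copies = 2L,
                  smn1_functional_copies = 2L,
                  input_dna_ng = sat_yield * .data$blood_load,
                  tm_shift_c = 0, role = "SPECIMEN")
  curves <- simulate_melt_curves(wells, config,
                                 seed = derive_seed(seed, "input-range"))
  peaks <- call_peaks(curves, config)
  q <- dplyr::filter(peaks, .data$window == "Q")
  totals <- curves |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total_signal = sum(.data$fluorescence), .groups = "drop")
  wells |>
    dplyr::left_join(q[, c("sample_id", "raw_height")], by = "sample_id") |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::group_by(.data$condition, .data$dilution, .data$blood_load) |>
    dplyr::summarise(mean_input_dna_ng = mean(.data$input_dna_ng),
                     mean_q_height = mean(.data$raw_height),
                     mean_total_signal = mean(.data$total_signal),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$dilution))
}
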