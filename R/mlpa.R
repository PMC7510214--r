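# Second-tier copy-number analysis.
#
# Two-stage median normalization (a documented, deterministic replacement
# for the kit vendor's proprietary analysis software):
#   stage 1 (intra-sample): divide every probe height by the median height
#     of the sample's reference probes -- cancels the per-sample scale;
#   stage 2 (inter-sample): divide by the median of the same statistic
#     across >= 3 calibrator samples of known (2,2) genotype -- cancels the
#     fixed per-probe efficiencies.
# A perfect (2,2) sample then has every ratio exactly 1, and a probe ratio
# r estimates copies/2 of its target.

profile_stat <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(ref_median = median(
      .data$height[.data$target_class == "REFERENCE"])) |>
    dplyr::ungroup()
}

#' Normalize MLPA probe heights against reference samples
#'
#' @param profiles Long profile tibble (`sample_id`, `probe_id`,
#'   `target_class`, `height`) from [simulate_mlpa_profiles()] or
#'   [read_mlpa_profiles()].
#' @param reference_profiles Profile tibble of at least 3 calibrator
#'   samples with normal (2,2) genotype, e.g. from
#'   [simulate_mlpa_references()].
#'
#' @return A tibble `sample_id`, `probe_id`, `target_class`, `ratio`.
#'   Samples whose reference probes have zero median height are failed
#'   reactions and are rejected with an error.
#' @examples
#' refs <- simulate_mlpa_references(3, seed = 1)
#' prof <- simulate_mlpa_profiles(generate_cohort(seed = 1)[1:2, ], seed = 1)
#' mlpa_normalize(prof, refs)
#' @export
mlpa_normalize <- function(profiles, reference_profiles) {
  if (dplyr::n_distinct(reference_profiles$sample_id) < 3)
    abort("at least 3 reference profiles are required for normalization")
  refs <- profile_stat(reference_profiles)
  if (any(refs$ref_median <= 0))
    abort("reference profile with zero median reference-probe height: failed reaction")
  ref_factor <- refs |>
    dplyr::mutate(stat = .data$height / .data$ref_median) |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(ref_stat = median(.data$stat), .groups = "drop")

  prof <- profile_stat(profiles)
  bad <- unique(prof$sample_id[prof$ref_median <= 0])
  if (length(bad) > 0)
    abort(paste0("failed MLPA reaction (zero median reference-probe height): ",
                 paste(bad, collapse = ", ")))
  prof |>
    dplyr::left_join(ref_factor, by = "probe_id") |>
    dplyr::mutate(ratio = (.data$height / .data$ref_median) /
                    .data$ref_stat) |>
    dplyr::select("sample_id", "probe_id", "target_class", "ratio")
}

#' Call integer SMN1/SMN2 copy numbers from normalized ratios
#'
#' Per gene, the combined ratio is the median over that gene's probes and
#' the called copy number is `round(2 * ratio)`. A combined ratio farther
#' than `mlpa_band_halfwidth` (ratio scale) from every half-integer band
#' centre is flagged ambiguous (`NA` copies) and marked for an MLPA retest.
#' `confirmed_positive` is `TRUE` exactly when SMN1 is unambiguously called
#' at 0 copies.
#'
#' @param ratios Normalized ratio tibble from [mlpa_normalize()].
#' @param config An [sim_config()] object (banding half-width).
#'
#' @return A tibble with one row per sample: `sample_id`, `smn1_ratio`,
#'   `smn2_ratio`, `smn1_cn`, `smn2_cn`, `ambiguous`, `confirmed_positive`.
#' @export
mlpa_call_copy_number <- function(ratios, config = sim_config()) {
  band <- config$mlpa_band_halfwidth
  gene_of <- function(target_class)
    ifelse(grepl("^SMN1", target_class), "SMN1",
           ifelse(grepl("^SMN2", target_class), "SMN2", NA_character_))
  per_gene <- ratios |>
    dplyr::mutate(gene = gene_of(.data$target_class)) |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::summarise(ratio = median(.data$ratio), .groups = "drop") |>
    dplyr::mutate(
      cn = as.integer(round(2 * .data$ratio)),
      in_band = abs(.data$ratio - .data$cn / 2) <= band,
      cn = ifelse(.data$in_band, .data$cn, NA_integer_))
  wide <- tidyr::pivot_wider(
    dplyr::select(per_gene, "sample_id", "gene", "ratio", "cn"),
    names_from = "gene", values_from = c("ratio", "cn"))
  tibble::tibble(
    sample_id = wide$sample_id,
    smn1_ratio = wide$ratio_SMN1,
    smn2_ratio = wide$ratio_SMN2,
    smn1_cn = wide$cn_SMN1,
    smn2_cn = wide$cn_SMN2,
    ambiguous = is.na(wide$cn_SMN1) | is.na(wide$cn_SMN2),
    confirmed_positive = !is.na(wide$cn_SMN1) & wide$cn_SMN1 == 0L
  )
}

#' Repeat ambiguous MLPA reactions
#'
#' Samples whose combined ratio falls outside every copy-number band are
#' flagged for an MLPA retest; this helper re-simulates those reactions as
#' a fresh batch (same fixed probe efficiencies, new sample-level noise),
#' re-normalizes and re-calls them, and keeps the repeat call.
#'
#' @param cn Copy-number call tibble from [mlpa_call_copy_number()].
#' @param samples Sample tibble with `sample_id`, `smn1_copies`,
#'   `smn2_copies` covering the flagged samples.
#' @param config An [sim_config()] object.
#' @param seed Seed of the original batch; the retest derives its own
#'   stream from it.
#' @return The call tibble with retested rows replaced and a logical
#'   `mlpa_retested` column added.
#' @export
mlpa_retest_ambiguous <- function(cn, samples, config = sim_config(),
                                  seed = 1L) {
  cn$mlpa_retested <- FALSE
  ids <- cn$sample_id[cn$ambiguous]
  if (length(ids) == 0) return(cn)
  redo_samples <- dplyr::filter(samples, .data$sample_id %in% ids)
  prof <- simulate_mlpa_profiles(redo_samples, config, seed = seed,
                                 batch = "ambiguity-retest")
  refs <- simulate_mlpa_references(3, config, seed = seed)
  redo <- mlpa_call_copy_number(mlpa_normalize(prof, refs), config)
  idx <- match(redo$sample_id, cn$sample_id)
  for (col in c("smn1_ratio", "smn2_ratio", "smn1_cn", "smn2_cn",
                "ambiguous", "confirmed_positive"))
    cn[[col]][idx] <- redo[[col]]
  cn$mlpa_retested[idx] <- TRUE
  cn
}

#' Monte-Carlo copy-number recovery experiment
#'
#' Simulates `n` MLPA profiles with genotypes resampled from a composition,
#' runs normalization and copy-number calling, and reports the fraction of
#' samples whose SMN1 and SMN2 copy numbers are both recovered exactly.
#' Ambiguity-flagged samples are repeated once by default, mirroring the
#' screening workflow.
#'
#' @param n Number of simulated samples.
#' @param composition Genotype composition to resample from; defaults to
#'   the validation cohort's.
#' @param config An [sim_config()] object; set `mlpa_cv` here to study
#'   noise dependence.
#' @param seed Integer seed.
#' @param retest_ambiguous Repeat flagged reactions once?
#' @return A list with `recovery` (fraction exact), `n`, and `calls` (the
#'   per-sample tibble including truth).
#' @examples
#' mlpa_recovery_experiment(n = 50, seed = 1)$recovery
#' @export
mlpa_recovery_experiment <- function(n = 500,
                                     composition = validation_composition(),
                                     config = sim_config(), seed = 1L,
                                     retest_ambiguous = TRUE) {
  pool <- tidyr::uncount(composition, weights = .data$n)
  idx <- withr::with_seed(derive_seed(seed, "recovery"),
                          sample.int(nrow(pool), n, replace = TRUE))
  samples <- tibble::tibble(sample_id = sprintf("MC%04d", seq_len(n)),
                            smn1_copies = pool$smn1_copies[idx],
                            smn2_copies = pool$smn2_copies[idx])
  prof <- simulate_mlpa_profiles(samples, config, seed = seed)
  refs <- simulate_mlpa_references(3, config, seed = seed)
  cn <- mlpa_call_copy_number(mlpa_normalize(prof, refs), config)
  if (retest_ambiguous)
    cn <- mlpa_retest_ambiguous(cn, samples, config, seed = seed)
  calls <- dplyr::left_join(samples, cn, by = "sample_id")
  recovered <- !is.na(calls$smn1_cn) & !is.na(calls$smn2_cn) &
    calls$smn1_cn == calls$smn1_copies & calls$smn2_cn == calls$smn2_copies
  list(recovery = mean(recovered), n = n,
       calls = dplyr::mutate(calls, recovered = recovered))
}
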