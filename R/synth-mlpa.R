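# Synthetic MLPA probe panel. The real second-tier kit's exact probe list is
# proprietary; this stand-in panel keeps its structure: two probes per SMN
# gene per exon (7 and 8) plus ten autosomal reference probes at two copies.
mlpa_panel <- function() {
  tibble::tibble(
    probe_id = c(sprintf("SMN1_EX7_p%d", 1:2), sprintf("SMN1_EX8_p%d", 1:2),
                 sprintf("SMN2_EX7_p%d", 1:2), sprintf("SMN2_EX8_p%d", 1:2),
                 sprintf("REF_p%02d", 1:10)),
    target_class = c(rep("SMN1_EX7", 2), rep("SMN1_EX8", 2),
                     rep("SMN2_EX7", 2), rep("SMN2_EX8", 2),
                     rep("REFERENCE", 10)),
    expected_reference_copies = c(rep(NA_integer_, 8), rep(2L, 10))
  )
}

probe_copies <- function(target_class, smn1, smn2) {
  dplyr::case_when(
    target_class %in% c("SMN1_EX7", "SMN1_EX8") ~ smn1,
    target_class %in% c("SMN2_EX7", "SMN2_EX8") ~ smn2,
    TRUE ~ 2L
  )
}

#' Simulate MLPA probe-height profiles
#'
#' Probe heights follow `h = s * k_p * c_p * (1 + eps)`: a lognormal
#' per-sample scale `s` (reaction efficiency), a per-probe efficiency `k_p`
#' drawn once per batch (ligation/amplification bias, shared by every sample
#' in the run), the copy number `c_p` of the probe's target (2 for reference
#' probes), and multiplicative noise with coefficient of variation
#' `mlpa_cv`. A zero-copy target therefore yields height exactly 0.
#'
#' @param samples Tibble with `sample_id`, `smn1_copies`, `smn2_copies`.
#' @param config An [sim_config()] object.
#' @param seed Integer seed. The fixed per-probe efficiencies are derived
#'   from `seed` alone, so calibrators simulated with the same seed (see
#'   [simulate_mlpa_references()]) share them with the specimen batch, as
#'   they would in a real run.
#' @param batch Label salting the per-sample random stream, so that
#'   different batches under one seed share probe efficiencies but not
#'   sample-level noise.
#'
#' @return A long tibble: `sample_id`, `probe_id`, `target_class`, `height`.
#' @examples
#' prof <- simulate_mlpa_profiles(generate_cohort(seed = 1)[1:3, ], seed = 1)
#' dplyr::count(prof, target_class)
#' @export
simulate_mlpa_profiles <- function(samples, config = sim_config(),
                                   seed = 1L, batch = "specimens") {
  stopifnot(all(c("sample_id", "smn1_copies", "smn2_copies")
                %in% names(samples)))
  check_genotypes(samples$smn1_copies, samples$smn2_copies)
  panel <- mlpa_panel()
  k_p <- withr::with_seed(derive_seed(seed, "mlpa-panel"),
                          rlnorm(nrow(panel), 0, config$mlpa_probe_sdlog))
  withr::with_seed(derive_seed(seed, paste0("mlpa-", batch)), {
    s <- rlnorm(nrow(samples), 0, config$mlpa_scale_sdlog)
    out <- tidyr::crossing(
      tibble::tibble(sample_id = samples$sample_id,
                     smn1 = samples$smn1_copies,
                     smn2 = samples$smn2_copies,
                     s = s),
      tibble::tibble(probe_id = panel$probe_id,
                     target_class = panel$target_class,
                     k_p = k_p)
    )
    eps <- rnorm(nrow(out), 0, config$mlpa_cv)
    out$height <- out$s * out$k_p *
      probe_copies(out$target_class, out$smn1, out$smn2) * (1 + eps)
    out$height <- pmax(out$height, 0)
  })
  dplyr::arrange(
    dplyr::select(out, "sample_id", "probe_id", "target_class", "height"),
    .data$sample_id, .data$probe_id)
}

#' Simulate MLPA calibrator profiles
#'
#' Every MLPA batch is normalized against reference samples of known normal
#' genotype (two copies of each gene). This helper simulates `n` such
#' calibrators with the same per-probe efficiencies as a specimen batch when
#' given the same seed.
#'
#' @param n Number of reference samples (the normalization contract needs
#'   at least 3).
#' @param config An [sim_config()] object.
#' @param seed Integer seed; use the specimen batch's seed so that the fixed
#'   per-probe efficiencies match.
#' @return A long profile tibble as from [simulate_mlpa_profiles()], sample
#'   ids `REF1..REFn`.
#' @export
simulate_mlpa_references <- function(n = 3, config = sim_config(),
                                     seed = 1L) {
  refs <- tibble::tibble(sample_id = sprintf("REF%d", seq_len(n)),
                         smn1_copies = 2L, smn2_copies = 2L)
  simulate_mlpa_profiles(refs, config, seed = seed, batch = "references")
}
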