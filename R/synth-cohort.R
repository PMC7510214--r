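#' Genotype composition of the validation cohort
#'
#' The SMN1/SMN2 exon-7 copy-number cross-tabulation of the 422-sample
#' retrospective validation cohort: 47 SMA samples (0 SMN1 copies) and 375
#' negative controls. Used as the default input of [generate_cohort()] and
#' [run_validation()].
#'
#' @return A tibble with columns `smn1_copies`, `smn2_copies`, `n`
#'   (`sum(n) == 422`).
#' @examples
#' comp <- validation_composition()
#' sum(comp$n)
#' sum(comp$n[comp$smn1_copies == 0])
#' @export
validation_composition <- function() {
  tibble::tribble(
    ~smn1_copies, ~smn2_copies, ~n,
    0L, 1L,   1L,
    0L, 2L,  13L,
    0L, 3L,  27L,
    0L, 4L,   6L,
    1L, 1L,   3L,
    1L, 2L,   2L,
    1L, 3L,   4L,
    2L, 0L,  24L,
    2L, 1L, 135L,
    2L, 2L, 165L,
    2L, 3L,   7L,
    2L, 4L,   1L,
    3L, 0L,   3L,
    3L, 1L,  14L,
    3L, 2L,  12L,
    3L, 3L,   1L,
    4L, 0L,   2L,
    4L, 1L,   1L,
    4L, 2L,   1L
  )
}

check_genotypes <- function(smn1, smn2) {
  if (any(smn1 < 0 | smn2 < 0 | smn1 != floor(smn1) | smn2 != floor(smn2)))
    abort("copy numbers must be non-negative integers")
  if (any(smn1 + smn2 < 1))
    abort("genotype (0,0) is not viable: every individual carries at least one SMN1 or SMN2 copy")
  if (any(smn1 > 6 | smn2 > 6))
    abort("copy numbers above 6 are outside the generator's supported range")
  invisible(TRUE)
}

#' Generate a synthetic screening cohort
#'
#' Draws one specimen per requested genotype count, with per-punch DNA yield
#' and blood load drawn from the configured distributions, and returns the
#' specimens in seeded random order (screening samples arrive anonymized and
#' randomized).
#'
#' @param composition Data frame with columns `smn1_copies`, `smn2_copies`,
#'   `n` (counts per genotype). Defaults to [validation_composition()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param config An [sim_config()] object.
#'
#' @return A tibble of sample specifications, one row per specimen, with
#'   columns `sample_id`, `role` (`"SPECIMEN"`), `smn1_copies`,
#'   `smn2_copies`, `smn1_functional_copies`, `input_dna_ng`, `blood_load`,
#'   `tm_shift_c`.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' nrow(cohort)
#' @export
generate_cohort <- function(composition = validation_composition(),
                            seed = 1L,
                            config = sim_config()) {
  stopifnot(all(c("smn1_copies", "smn2_copies", "n") %in% names(composition)))
  if (any(composition$n < 0)) abort("genotype counts must be >= 0")
  composition <- dplyr::filter(composition, .data$n > 0)
  if (nrow(composition) == 0) return(empty_cohort())
  check_genotypes(composition$smn1_copies, composition$smn2_copies)

  specs <- tidyr::uncount(tibble::as_tibble(composition), weights = .data$n)
  n <- nrow(specs)
  withr::with_seed(derive_seed(seed, "cohort"), {
    specs <- specs[sample.int(n), ]
    specs$sample_id <- sprintf("S%04d", seq_len(n))
    specs$role <- "SPECIMEN"
    specs$smn1_functional_copies <-
      if ("smn1_functional_copies" %in% names(composition))
        specs$smn1_functional_copies else specs$smn1_copies
    specs$input_dna_ng <- rlnorm(n, config$dna_meanlog, config$dna_sdlog)
    specs$blood_load <- runif(n, config$blood_load_min, config$blood_load_max)
    specs$tm_shift_c <-
      if ("tm_shift_c" %in% names(composition)) specs$tm_shift_c else 0
  })
  dplyr::select(specs, "sample_id", "role", "smn1_copies", "smn2_copies",
                "smn1_functional_copies", "input_dna_ng", "blood_load",
                "tm_shift_c")
}

empty_cohort <- function() {
  tibble::tibble(sample_id = character(), role = character(),
                 smn1_copies = integer(), smn2_copies = integer(),
                 smn1_functional_copies = integer(),
                 input_dna_ng = double(), blood_load = double(),
                 tm_shift_c = double())
}

# Control reactions carried by every plate: 2 blank DBS cards, 2 wells of
# the SD074 threshold DNA (SMN1:SMN2 = 1:5, defines the referral boundary)
# and 2 wells of the SD075 positive DNA (no SMN1 at all). The synthetic
# control DNAs carry no blood, hence blood_load 0 and no quenching.
control_specs <- function(plate_id, config) {
  tibble::tibble(
    sample_id = paste0(plate_id, "_", c("BLANK1", "BLANK2", "SD074a",
                                        "SD074b", "SD075a", "SD075b")),
    role = c("BLANK", "BLANK", "SD074", "SD074", "SD075", "SD075"),
    smn1_copies = c(0L, 0L, 1L, 1L, 0L, 0L),
    smn2_copies = c(0L, 0L, 5L, 5L, 2L, 2L),
    smn1_functional_copies = c(0L, 0L, 1L, 1L, 0L, 0L),
    input_dna_ng = c(0, 0, rep(config$control_dna_ng, 4)),
    blood_load = 0,
    tm_shift_c = 0
  )
}

#' Assign specimens to 96-well plates
#'
#' Each plate carries at most 90 specimens plus the six mandatory control
#' wells (2 blanks + 2 SD074 + 2 SD075); specimens are partitioned across
#' plates in order, without duplication or loss.
#'
#' @param specimens Cohort tibble from [generate_cohort()].
#' @param config An [sim_config()] object (control DNA amount).
#' @param plate_prefix Prefix for generated plate identifiers.
#'
#' @return A tibble with one row per occupied well: `plate_id`, `well`
#'   (e.g. `"A01"`), plus all sample-specification columns.
#' @examples
#' plates <- build_plates(generate_cohort(seed = 1))
#' table(plates$plate_id)
#' @export
build_plates <- function(specimens, config = sim_config(),
                         plate_prefix = "P") {
  if (nrow(specimens) == 0) abort("specimen list is empty")
  per_plate <- 90L
  n_plates <- ceiling(nrow(specimens) / per_plate)
  wells <- paste0(rep(LETTERS[1:8], times = 12),
                  sprintf("%02d", rep(1:12, each = 8)))
  out <- purrr::map(seq_len(n_plates), function(i) {
    plate_id <- sprintf("%s%02d", plate_prefix, i)
    idx <- ((i - 1L) * per_plate + 1L):min(i * per_plate, nrow(specimens))
    plate <- dplyr::bind_rows(control_specs(plate_id, config),
                              specimens[idx, ])
    plate$plate_id <- plate_id
    plate$well <- wells[seq_len(nrow(plate))]
    plate
  })
  dplyr::relocate(dplyr::bind_rows(out), "plate_id", "well")
}
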