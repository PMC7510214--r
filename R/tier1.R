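# First-tier decision rules.
#
# Rule order per well (after plate QC):
#   1. Q-fragment height is the strict maximum of the three -> RETEST
#      (too little input DNA to interpret);
#   all three peaks absent -> RETEST (failed reaction);
#   2. SMN2 present, SMN1 absent -> SECOND_TIER (putative homozygous
#      SMN1 deletion);
#   3. SMN2 present, SMN1 height <= the plate's SD074 reference height
#      -> SECOND_TIER (SMN2:SMN1 ratio at or beyond the 5:1 boundary;
#      the comparison is inclusive because a ratio equal to five
#      qualifies);
#   4. otherwise NORMAL.
# Referral is deliberately ratio-based: carriers with common ratios are
# indistinguishable from non-carriers and are never flagged.

peaks_wide <- function(peaks) {
  tidyr::pivot_wider(
    dplyr::select(peaks, "sample_id", "window", "height", "present"),
    names_from = "window", values_from = c("height", "present"))
}

#' Plate-level quality control from control-well peaks
#'
#' Validates the six control reactions of each plate: both blanks must show
#' a dominant Q-fragment peak with SMN1 and SMN2 absent; both SD075
#' positive controls must lack SMN1 while showing SMN2; both SD074
#' threshold controls must show both peaks with SMN1 lower than SMN2. A
#' plate missing any control role is invalid with an explicit reason.
#'
#' @param peaks Peak tibble from [call_peaks()] covering the control wells.
#' @param layout Plate layout tibble from [build_plates()] (maps
#'   `sample_id` to `plate_id` and `role`).
#'
#' @return A tibble with one row per plate: `plate_id`, `blanks_ok`,
#'   `sd074_ok`, `sd075_ok`, `valid`, `reason`.
#' @export
qc_plates <- function(peaks, layout) {
  controls <- dplyr::filter(layout, .data$role != "SPECIMEN")
  wide <- dplyr::inner_join(peaks_wide(peaks),
                            dplyr::select(controls, "sample_id", "plate_id",
                                          "role"),
                            by = "sample_id")
  qc_one <- function(df) {
    counts <- table(factor(df$role, levels = c("BLANK", "SD074", "SD075")))
    if (any(counts != 2)) {
      return(tibble::tibble(
        blanks_ok = FALSE, sd074_ok = FALSE, sd075_ok = FALSE, valid = FALSE,
        reason = paste0("missing control reactions: expected 2 of each role, got ",
                        paste(sprintf("%s=%d", names(counts), counts),
                              collapse = ", "))))
    }
    bl <- df[df$role == "BLANK", ]
    s74 <- df[df$role == "SD074", ]
    s75 <- df[df$role == "SD075", ]
    blanks_ok <- all(bl$height_Q > pmax(bl$height_SMN1, bl$height_SMN2) &
                       !bl$present_SMN1 & !bl$present_SMN2 & bl$present_Q)
    sd074_ok <- all(s74$present_SMN1 & s74$present_SMN2 &
                      s74$height_SMN1 < s74$height_SMN2)
    sd075_ok <- all(!s75$present_SMN1 & s75$present_SMN2)
    valid <- blanks_ok && sd074_ok && sd075_ok
    tibble::tibble(blanks_ok = blanks_ok, sd074_ok = sd074_ok,
                   sd075_ok = sd075_ok, valid = valid,
                   reason = if (valid) "ok" else
                     paste0("failed: ",
                            paste(c("blanks", "SD074", "SD075")[
                              !c(blanks_ok, sd074_ok, sd075_ok)],
                              collapse = ", ")))
  }
  wide |>
    dplyr::group_by(plate_id = .data$plate_id) |>
    dplyr::group_modify(~ qc_one(.x)) |>
    dplyr::ungroup()
}

#' First-tier classification of specimen wells
#'
#' Applies the screening decision rules to every specimen well, comparing
#' each SMN1 peak height against the plate's SD074 reference height (the
#' mean of the plate's two SD074 SMN1 peaks, which embodies the 1:5
#' SMN1:SMN2 referral boundary).
#'
#' @param peaks Peak tibble from [call_peaks()] covering specimen and
#'   control wells.
#' @param layout Plate layout from [build_plates()].
#' @param qc Optional QC tibble from [qc_plates()]; wells on invalid plates
#'   are dropped with a warning. Pass `NULL` to skip QC gating.
#'
#' @return A tibble with one row per specimen well: `sample_id`,
#'   `plate_id`, `call` (`NORMAL` / `SECOND_TIER` / `RETEST`), `reason`
#'   (`OK` / `SMN1_ABSENT` / `SMN1_BELOW_SD074` / `Q_DOMINANT` /
#'   `ASSAY_FAILED`), `sd074_ref_height`.
#' @export
classify_wells <- function(peaks, layout, qc = NULL) {
  wide <- dplyr::inner_join(
    peaks_wide(peaks),
    dplyr::select(layout, "sample_id", "plate_id", "role"),
    by = "sample_id")
  if (!is.null(qc)) {
    bad <- qc$plate_id[!qc$valid]
    if (length(bad) > 0) {
      warn(paste0("plate(s) failed control QC and were excluded: ",
                  paste(bad, collapse = ", ")))
      wide <- dplyr::filter(wide, !.data$plate_id %in% bad)
    }
  }
  sd074_ref <- wide |>
    dplyr::filter(.data$role == "SD074") |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(sd074_ref_height = mean(.data$height_SMN1),
                     .groups = "drop")

  wide |>
    dplyr::filter(.data$role == "SPECIMEN") |>
    dplyr::left_join(sd074_ref, by = "plate_id") |>
    dplyr::mutate(
      reason = dplyr::case_when(
        height_Q > pmax(height_SMN1, height_SMN2) ~ "Q_DOMINANT",
        !present_SMN1 & !present_SMN2 & !present_Q ~ "ASSAY_FAILED",
        present_SMN2 & !present_SMN1 ~ "SMN1_ABSENT",
        present_SMN2 & height_SMN1 <= sd074_ref_height ~ "SMN1_BELOW_SD074",
        .default = "OK"),
      call = dplyr::case_when(
        reason %in% c("Q_DOMINANT", "ASSAY_FAILED") ~ "RETEST",
        reason %in% c("SMN1_ABSENT", "SMN1_BELOW_SD074") ~ "SECOND_TIER",
        .default = "NORMAL")) |>
    dplyr::select("sample_id", "plate_id", "call", "reason",
                  "sd074_ref_height")
}

#' Resolve RETEST wells by repeated reanalysis
#'
#' Reruns every `RETEST` well through `reanalyze` for up to `max_rounds`
#' rounds (a retest is a fresh reaction: new punch, new input DNA, new
#' noise). Wells still uninterpretable after the final round escalate,
#' fail-safe, to `SECOND_TIER` with their last failure reason: a screening
#' assay resolves persistent ambiguity towards confirmation, never towards
#' a missed case.
#'
#' @param calls First-tier call tibble from [classify_wells()].
#' @param reanalyze Function taking a character vector of sample ids and a
#'   round number, returning a call tibble of the same shape for those
#'   samples.
#' @param max_rounds Maximum number of retest rounds (>= 1).
#'
#' @return A call tibble with no `RETEST` rows, plus an `n_retests` column
#'   counting the rounds each sample consumed.
#' @export
resolve_retests <- function(calls, reanalyze,
                            max_rounds = sim_config()$max_retest_rounds) {
  stopifnot(max_rounds >= 1)
  calls$n_retests <- 0L
  if (nrow(calls) == 0) return(calls)
  for (round in seq_len(max_rounds)) {
    todo <- calls$sample_id[calls$call == "RETEST"]
    if (length(todo) == 0) break
    redo <- reanalyze(todo, round)
    redo <- dplyr::filter(redo, .data$sample_id %in% todo)
    idx <- match(redo$sample_id, calls$sample_id)
    calls$call[idx] <- redo$call
    calls$reason[idx] <- redo$reason
    calls$sd074_ref_height[idx] <- redo$sd074_ref_height
    calls$n_retests[idx] <- calls$n_retests[idx] + 1L
  }
  still <- calls$call == "RETEST"
  calls$call[still] <- "SECOND_TIER"
  calls
}
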