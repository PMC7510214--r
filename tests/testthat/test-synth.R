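test_that("cohort generation reproduces a requested genotype composition", {
  comp <- validation_composition()
  cohort <- generate_cohort(comp, seed = 7)
  expect_equal(nrow(cohort), 422)
  expect_equal(sum(cohort$smn1_copies == 0), 47)
  got <- dplyr::count(cohort, smn1_copies, smn2_copies)
  expect_equal(
    dplyr::arrange(got, smn1_copies, smn2_copies)$n,
    dplyr::arrange(comp, smn1_copies, smn2_copies)$n)
  expect_true(all(cohort$input_dna_ng > 0))
  expect_true(all(cohort$role == "SPECIMEN"))
})

test_that("cohort generation honours the seed contract", {
  comp <- tibble::tibble(smn1_copies = 2L, smn2_copies = c(0L, 2L),
                         n = c(3L, 2L))
  a <- generate_cohort(comp, seed = 1)
  b <- generate_cohort(comp, seed = 1)
  c <- generate_cohort(comp, seed = 2)
  expect_identical(a, b)
  expect_equal(sort(paste(c$smn1_copies, c$smn2_copies)),
               sort(paste(a$smn1_copies, a$smn2_copies)))
  expect_false(identical(a$input_dna_ng, c$input_dna_ng))
})

test_that("cohort generation rejects invalid compositions", {
  expect_error(generate_cohort(tibble::tibble(smn1_copies = 0L,
                                              smn2_copies = 0L, n = 1L)),
               "not viable")
  expect_error(generate_cohort(tibble::tibble(smn1_copies = 7L,
                                              smn2_copies = 0L, n = 1L)),
               "above 6")
  expect_equal(nrow(generate_cohort(tibble::tibble(
    smn1_copies = integer(), smn2_copies = integer(), n = integer()))), 0)
})

test_that("noiseless melt curves encode only the copy ratio", {
  cfg <- noiseless_config()
  c11 <- simulate_melt_curves(make_spec(1, 1), cfg, seed = 1)
  c22 <- simulate_melt_curves(make_spec(2, 2), cfg, seed = 2)
  expect_equal(c11$fluorescence, c22$fluorescence, tolerance = 1e-12)
  c12 <- simulate_melt_curves(make_spec(1, 2), cfg, seed = 1)
  c24 <- simulate_melt_curves(make_spec(2, 4), cfg, seed = 1)
  expect_equal(c12$fluorescence, c24$fluorescence, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(c11$fluorescence, c12$fluorescence)))
})

test_that("blank wells yield a pure Q-fragment curve", {
  cfg <- noiseless_config()
  blank <- make_spec(0, 0, input_dna_ng = 0, blood_load = 0, role = "BLANK")
  curve <- simulate_melt_curves(blank, cfg, seed = 1)
  # all amplitude goes to the Q transition: F = baseline + A_total * sigmoid
  expected <- cfg$baseline_fluorescence +
    cfg$amplitude_total * plogis((cfg$tm_q_c - curve$temperature_c) /
                                   cfg$transition_width_c)
  expect_equal(curve$fluorescence, expected, tolerance = 1e-12)
})

test_that("SD075-like samples have no SMN1 transition", {
  cfg <- noiseless_config()
  curve <- simulate_melt_curves(make_spec(0, 2), cfg, seed = 1)
  peaks <- call_peaks(curve, cfg)
  expect_false(peaks$present[peaks$window == "SMN1"])
  expect_true(peaks$present[peaks$window == "SMN2"])
})

test_that("Q-fragment amplitude decreases strictly with input DNA", {
  cfg <- noiseless_config()
  dna <- c(0.5, 1, 2, 5, 10, 20)
  heights <- vapply(dna, function(d) {
    curve <- simulate_melt_curves(make_spec(2, 2, input_dna_ng = d),
                                  cfg, seed = 1)
    peaks <- call_peaks(curve, cfg)
    peaks$raw_height[peaks$window == "Q"]
  }, numeric(1))
  expect_true(all(diff(heights) < 0))
})

test_that("blood oversaturation quenches the whole signal", {
  cfg <- noiseless_config()
  sat <- simulate_melt_curves(make_spec(2, 2, blood_load = 1), cfg, seed = 1)
  over <- simulate_melt_curves(make_spec(2, 2, blood_load = 2), cfg, seed = 1)
  expect_lt(sum(over$fluorescence), sum(sat$fluorescence))
  # below saturation there is no quenching at all
  dry <- simulate_melt_curves(make_spec(2, 2, blood_load = 0.5), cfg, seed = 1)
  expect_equal(sum(dry$fluorescence), sum(sat$fluorescence),
               tolerance = 1e-12)
})

test_that("probe-region variants can only lower the SMN1 window signal", {
  cfg <- noiseless_config()
  shifts <- seq(0, -6, by = -0.5)
  win_height <- function(smn2, s, raw = TRUE) {
    curve <- simulate_melt_curves(make_spec(2, smn2, tm_shift_c = s),
                                  cfg, seed = 1)
    d <- melt_derivative(curve, cfg)
    w <- cfg$windows$SMN1
    max(d$neg_dfdt[d$temperature_c >= w[1] & d$temperature_c <= w[2]])
  }
  # with no co-resident SMN2 transition the window height is monotone
  # non-increasing in the shift
  # tolerance: sampling the apex on the 0.2 C grid aliases the maximum by
  # a few parts in a thousand depending on where the apex falls
  h20 <- vapply(shifts, function(s) win_height(0L, s), numeric(1))
  expect_true(all(diff(h20) <= 5e-3 * h20[1]))
  # with SMN2 present the shifted SMN1 apex rides on SMN2's shoulder, so
  # the window maximum may grow by at most that shoulder before the apex
  # leaves the window; it never doubles, and the peak caller marks the
  # boundary maximum non-apical (absent) from -2 C on
  h22 <- vapply(shifts, function(s) win_height(2L, s), numeric(1))
  expect_true(all(h22 <= h22[1] * 1.06))
  expect_true(all(diff(h22[shifts <= -2]) < 0))
  present <- vapply(shifts, function(s) {
    curve <- simulate_melt_curves(make_spec(2, 2, tm_shift_c = s),
                                  cfg, seed = 1)
    p <- call_peaks(curve, cfg)
    p$present[p$window == "SMN1"]
  }, logical(1))
  expect_true(all(present[shifts > -2]))
  expect_false(any(present[shifts <= -2]))
  expect_error(simulate_melt_curves(make_spec(2, 2, tm_shift_c = 0.5), cfg),
               "lower the melting temperature")
})

test_that("derivative peak height of a logistic transition is A/(4w)", {
  # independent oracle: central finite differences on a 0.01 C grid
  cfg <- noiseless_config()
  for (A in c(0.5, 2)) for (w in c(0.9, 1.4)) {
    curve <- single_transition_curve(A, w, 56, cfg, step = 0.01)
    d <- -diff(curve$fluorescence) / 0.01
    expect_equal(max(d), A / (4 * w), tolerance = 1e-4)
    apex <- curve$temperature_c[which.max(d)]
    expect_equal(apex, 56, tolerance = 0.02)
  }
})

test_that("plate builder partitions specimens with full control sets", {
  cohort <- generate_cohort(seed = 3)
  layout <- build_plates(cohort)
  expect_equal(dplyr::n_distinct(layout$plate_id), 5)  # ceiling(422 / 90)
  per_plate <- dplyr::count(dplyr::filter(layout, role == "SPECIMEN"),
                            plate_id)
  expect_equal(sort(per_plate$n), c(62, 90, 90, 90, 90))
  ctrl <- dplyr::count(dplyr::filter(layout, role != "SPECIMEN"),
                       plate_id, role)
  expect_true(all(ctrl$n == 2))
  expect_setequal(layout$sample_id[layout$role == "SPECIMEN"],
                  cohort$sample_id)
  expect_false(any(duplicated(layout$sample_id)))
  expect_false(any(duplicated(paste(layout$plate_id, layout$well))))
})

test_that("plate builder handles minimal and full plates", {
  one <- build_plates(make_spec(2, 2))
  expect_equal(nrow(one), 7)  # 6 controls + 1 specimen
  full <- build_plates(generate_cohort(tibble::tibble(
    smn1_copies = 2L, smn2_copies = 2L, n = 90L), seed = 1))
  expect_equal(nrow(full), 96)
  expect_equal(dplyr::n_distinct(full$plate_id), 1)
  expect_error(build_plates(make_spec(2, 2)[0, ]), "empty")
})

test_that("noiseless MLPA profiles equal scale x efficiency x copies", {
  cfg <- noiseless_config()
  prof <- simulate_mlpa_profiles(
    tibble::tibble(sample_id = "A", smn1_copies = 0L, smn2_copies = 2L),
    cfg, seed = 1)
  expect_equal(nrow(prof), 18)  # 8 SMN probes + 10 reference probes
  smn1 <- prof$height[grepl("^SMN1", prof$target_class)]
  rest <- prof$height[!grepl("^SMN1", prof$target_class)]
  expect_equal(smn1, rep(0, 4))
  expect_equal(rest, rep(2, 14))
})

test_that("MLPA per-sample scale is a pure global factor", {
  cfg <- sim_config(mlpa_cv = 0)  # keep scale/efficiency variation
  prof <- simulate_mlpa_profiles(
    tibble::tibble(sample_id = c("A", "B"),
                   smn1_copies = c(2L, 2L), smn2_copies = c(2L, 2L)),
    cfg, seed = 5)
  wide <- tidyr::pivot_wider(prof[, c("sample_id", "probe_id", "height")],
                             names_from = sample_id, values_from = height)
  ratio <- wide$B / wide$A
  expect_equal(ratio / ratio[1], rep(1, 18), tolerance = 1e-9)
  # and doubling copies doubles every SMN probe relative to references
  prof2 <- simulate_mlpa_profiles(
    tibble::tibble(sample_id = c("C", "D"),
                   smn1_copies = c(1L, 2L), smn2_copies = c(1L, 2L)),
    cfg, seed = 5)
  wide2 <- tidyr::pivot_wider(prof2[, c("sample_id", "probe_id", "height")],
                              names_from = sample_id, values_from = height)
  smn <- grepl("^SMN", wide2$probe_id)
  scale <- (wide2$D / wide2$C)[!smn][1]
  expect_equal((wide2$D / wide2$C)[smn], rep(2 * scale, 8),
               tolerance = 1e-9)
})
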