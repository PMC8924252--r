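# DDA candidate identification: feature detection, adduct grouping,
# accurate-mass search, precursor correction and MS2 mapping.

make_dda <- function(seed = 31, n = 2, noise = 0, jitter = 0) {
  set.seed(seed)
  cms <- sim_compound_set(n, gradient_length = 150)
  d <- sim_design(cms, n_dilutions = 1, n_replicates = 1, gradient_length = 150,
                  ms1_interval = 2, mass_jitter_ppm = jitter, intensity_cv = 0,
                  noise_peaks_per_spectrum = noise, seed = seed)
  list(design = d, compounds = cms, dda = simulate_dda(d))
}

test_that("detect_features recovers simulated compounds with isotope traces", {
  x <- make_dda(n = 2)
  ft <- detect_features(x$dda$run, ppm_tol = 10, min_scans = 5)
  expect_equal(nrow(ft), 2)
  expect_equal(ft$n_isotope_traces, c(3L, 3L))
  for (i in 1:2) {
    cm <- x$compounds[[i]]
    mzt <- adduct_mz(monoisotopic_mass(cm$formula), cm$adduct)
    j <- which.min(abs(ft$mz - mzt))
    expect_lt(abs(ft$mz[j] - mzt) / mzt * 1e6, 10)
    expect_lt(abs(ft$rt_apex[j] - cm$rt), 3)
  }
  # apex order follows elution order
  expect_equal(order(ft$rt_apex), order(vapply(x$compounds, `[[`, numeric(1), "rt")))
  expect_error(detect_features(new_run(list(
    new_spectrum(2, 1, 100, 1, precursor_mz = 50)), "DDA")), "MS1")
})

test_that("a pure-noise run yields no features at min_scans = 5", {
  set.seed(33)
  cms <- sim_compound_set(1, gradient_length = 100)
  d <- sim_design(cms, n_dilutions = 1, n_replicates = 1, gradient_length = 100,
                  ms1_interval = 2, noise_peaks_per_spectrum = 40, seed = 33)
  # strip the compound signal by zeroing base intensity via an empty design:
  d$compounds[[1]]$base_intensity <- 0
  dda <- simulate_dda(d)
  ft <- detect_features(dda$run, ppm_tol = 10, min_scans = 5, min_intensity = 1)
  expect_equal(nrow(ft), 0)
})

test_that("isotope-trace filtering counts correctly", {
  ft <- data.frame(n_isotope_traces = c(1L, 2L, 3L))
  expect_equal(nrow(filter_by_isotope_traces(ft, 2)), 2)
  expect_equal(filter_by_isotope_traces(ft, 1), ft)
  expect_equal(nrow(filter_by_isotope_traces(
    data.frame(n_isotope_traces = c(2L, 2L)), 4)), 0)
})

test_that("adduct grouping pairs co-eluting H/Na features", {
  M <- 300.12
  feat <- function(mz, rt, int = 1e5) data.frame(
    feature_id = NA, mz = mz, rt_apex = rt, rt_start = rt - 5, rt_end = rt + 5,
    intensity = int, area = int, n_isotope_traces = 2L, charge = 1L,
    adduct = NA_character_, neutral_mass = NA_real_)
  ft <- rbind(feat(M + 1.007276, 100), feat(M + 22.989218, 101))
  out <- group_adducts(ft, rt_tol = 10, ppm_tol = 10)
  expect_equal(out$adduct, c("[M+H]+", "[M+Na]+"))
  expect_equal(out$neutral_mass, rep(M, 2), tolerance = 1e-5)
  # single feature defaults to [M+H]+
  out1 <- group_adducts(feat(M, 100))
  expect_equal(out1$adduct, "[M+H]+")
  # co-eluting pair with a non-adduct spacing stays separate
  ft2 <- rbind(feat(M, 100), feat(M + 10.5, 100))
  out2 <- group_adducts(ft2)
  expect_equal(out2$adduct, c("[M+H]+", "[M+H]+"))
  expect_false(isTRUE(all.equal(out2$neutral_mass[1], out2$neutral_mass[2])))
})

test_that("accurate mass search attaches candidates sorted by ppm error", {
  db <- data.frame(name = c("caffeine", "isobar"),
                   formula = c("C8H10N4O2", "C9H14N2S"))
  ft <- data.frame(mz = adduct_mz(monoisotopic_mass("C8H10N4O2"), "[M+H]+"),
                   rt_apex = 10, adduct = "[M+H]+", neutral_mass = NA)
  ft$formula_candidates <- list(NULL)
  out <- accurate_mass_search(ft, db, ppm_tol = 5)
  fc <- out$formula_candidates[[1]]
  expect_equal(fc$name[1], "caffeine")
  expect_lt(abs(fc$ppm_error[1]), 1)
  # 50 ppm off -> nothing
  ft$mz <- ft$mz * (1 + 50e-6)
  out <- accurate_mass_search(ft, db, ppm_tol = 5)
  expect_null(out$formula_candidates[[1]])
  # two isobaric db entries within tolerance: both attached, sorted
  db2 <- data.frame(name = c("a", "b"),
                    formula = c("C8H10N4O2", "C8H10N4O2"))
  db2$shift <- c(0, 1)
  ft2 <- data.frame(mz = adduct_mz(monoisotopic_mass("C8H10N4O2") + 2e-4, "[M+H]+"),
                    rt_apex = 10, adduct = "[M+H]+", neutral_mass = NA)
  ft2$formula_candidates <- list(NULL)
  out2 <- accurate_mass_search(ft2, db2, ppm_tol = 5)
  expect_equal(nrow(out2$formula_candidates[[1]]), 2)
  expect_true(!is.unsorted(abs(out2$formula_candidates[[1]]$ppm_error)))
  expect_error(accurate_mass_search(ft2, db2[0, ], 5), "empty")
})

test_that("precursor correction snaps to the survey-scan centroid", {
  ms1 <- new_spectrum(1, 10, c(200.00, 300.00), c(1e5, 2e5))
  ms2_off <- new_spectrum(2, 11, c(100, 120), c(1, 1), precursor_mz = 200.02,
                          precursor_intensity = 1)
  ms2_far <- new_spectrum(2, 12, c(100, 120), c(1, 1), precursor_mz = 250.00,
                          precursor_intensity = 1)
  ms2_exact <- new_spectrum(2, 13, c(100, 120), c(1, 1), precursor_mz = 300.00,
                            precursor_intensity = 1)
  run <- new_run(list(ms1, ms2_off, ms2_far, ms2_exact), "DDA")
  out <- correct_precursors(run, tol = 0.05)
  expect_equal(out$spectra[[2]]$precursor_mz, 200.00)
  expect_equal(out$spectra[[2]]$precursor_intensity, 1e5)
  expect_true(out$spectra[[2]]$precursor_corrected)
  expect_equal(out$spectra[[3]]$precursor_mz, 250.00)   # unchanged, flagged
  expect_false(out$spectra[[3]]$precursor_corrected)
  expect_equal(out$spectra[[4]]$precursor_mz, 300.00)
  expect_true(out$spectra[[4]]$precursor_corrected)
})

test_that("MS2 spectra map to at most one feature, by ppm then intensity", {
  feat <- function(mz, int) data.frame(
    mz = mz, rt_apex = 100, rt_start = 90, rt_end = 110, intensity = int)
  ft <- rbind(feat(200.000, 1e5), feat(200.004, 2e5))
  ft$ms2_idx <- list(integer(0), integer(0))
  ms1 <- new_spectrum(1, 95, 200.0, 1e5)
  in_rt <- new_spectrum(2, 100, c(100, 110), c(1, 1), precursor_mz = 200.0005,
                        precursor_intensity = 1)
  out_rt <- new_spectrum(2, 150, c(100, 110), c(1, 1), precursor_mz = 200.0005,
                         precursor_intensity = 1)
  run <- new_run(list(ms1, in_rt, out_rt), "DDA")
  out <- map_ms2_to_features(ft, run, ppm_tol = 25)
  expect_equal(out$ms2_idx[[1]], 2L)       # nearer in ppm wins
  expect_length(out$ms2_idx[[2]], 0)
  n_assigned <- sum(lengths(out$ms2_idx))
  expect_equal(n_assigned, 1)              # out-of-RT spectrum unassigned
})

test_that("most injected compounds yield an identified feature with MS2", {
  x <- make_dda(seed = 35, n = 20, noise = 30, jitter = 3)
  db <- data.frame(
    name = vapply(x$compounds, `[[`, character(1), "name"),
    formula = vapply(x$compounds, function(c) formula_to_string(c$formula),
                     character(1)))
  ft <- detect_features(x$dda$run, 10, 5)
  ft <- filter_by_isotope_traces(ft, 2)
  ft <- group_adducts(ft)
  ft <- accurate_mass_search(ft, db, 5)
  run <- correct_precursors(x$dda$run)
  ft <- map_ms2_to_features(ft, run)
  recovered <- vapply(x$compounds, function(cm) {
    any(vapply(seq_len(nrow(ft)), function(i) {
      fc <- ft$formula_candidates[[i]]
      !is.null(fc) && cm$name %in% fc$name && ft$adduct[i] == cm$adduct &&
        length(ft$ms2_idx[[i]]) > 0
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
  # partition property: each MS2 spectrum assigned to at most one feature
  all_idx <- unlist(ft$ms2_idx)
  expect_equal(anyDuplicated(all_idx), 0)
})
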