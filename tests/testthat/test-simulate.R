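# The synthetic DDA/DIA generator: noise-free limits, determinism, window
# exclusivity, signal conservation and the dilution-series structure.

test_that("noise-free DDA puts MS2 peaks exactly at fragment adduct masses", {
  set.seed(1)
  cms <- sim_compound_set(1, gradient_length = 100)
  d <- sim_design(cms, n_dilutions = 1, n_replicates = 1, gradient_length = 100,
                  ms1_interval = 2, mass_jitter_ppm = 0, intensity_cv = 0,
                  noise_peaks_per_spectrum = 0, seed = 1)
  dda <- simulate_dda(d)
  lv <- vapply(dda$run$spectra, `[[`, integer(1), "ms_level")
  ms2 <- dda$run$spectra[lv == 2]
  expect_gte(length(ms2), 1)
  expected <- sort(vapply(cms[[1]]$fragment_template$formula, function(f)
    monoisotopic_mass(f) + 1.00727646, numeric(1)))
  for (s in ms2) {
    expect_equal(s$mz, expected, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(s$precursor_mz,
                 adduct_mz(monoisotopic_mass(cms[[1]]$formula), "[M+H]+"),
                 tolerance = 1e-6)
  }
})

test_that("simulation output is deterministic for a fixed design seed", {
  d <- tiny_design(seed = 9, n = 2, noise = 15)
  a <- simulate_dia(d)
  b <- simulate_dia(d)
  expect_identical(a$truth, b$truth)
  expect_identical(a$runs[[1]]$spectra[[50]]$mz, b$runs[[1]]$spectra[[50]]$mz)
  da <- simulate_dda(d)
  db <- simulate_dda(d)
  expect_identical(da$run$spectra[[10]]$intensity, db$run$spectra[[10]]$intensity)
})

test_that("every compound with a >=4-fragment template gets a >=4-peak MS2", {
  set.seed(2)
  cms <- sim_compound_set(5, gradient_length = 200, n_fragments = 5)
  d <- sim_design(cms, n_dilutions = 1, n_replicates = 1, gradient_length = 200,
                  ms1_interval = 2, seed = 2)
  dda <- simulate_dda(d)
  expect_true(all(dda$truth$n_ms2 >= 1))
  lv <- vapply(dda$run$spectra, `[[`, integer(1), "ms_level")
  ms2 <- dda$run$spectra[lv == 2]
  prem <- vapply(ms2, `[[`, numeric(1), "precursor_mz")
  for (i in seq_len(nrow(dda$truth))) {
    mine <- ms2[abs(prem - dda$truth$precursor_mz[i]) < 0.05]
    expect_true(all(vapply(mine, function(s) length(s$mz) >= 4, logical(1))))
  }
})

test_that("DIA cycles respect window exclusivity and the Gaussian model", {
  set.seed(3)
  cms <- sim_compound_set(3, gradient_length = 150)
  d <- sim_design(cms, n_dilutions = 1, n_replicates = 1, gradient_length = 150,
                  ms1_interval = 1, mass_jitter_ppm = 0, intensity_cv = 0,
                  noise_peaks_per_spectrum = 0, seed = 3)
  sim <- simulate_dia(d)
  run <- sim$runs[[1]]
  for (ci in seq_along(cms)) {
    cm <- cms[[ci]]
    prec <- adduct_mz(monoisotopic_mass(cm$formula), cm$adduct)
    w_home <- assign_window(prec, d$swath_windows)
    fmz <- monoisotopic_mass(cm$fragment_template$formula[1]) + 1.00727646
    for (sp in run$spectra) {
      if (sp$ms_level != 2) next
      w <- assign_window((sp$isolation_lower + sp$isolation_upper) / 2,
                         d$swath_windows)
      hit <- any(abs(sp$mz - fmz) < 1e-6)
      if (w != w_home) expect_false(hit)
    }
    # noise-free apex height equals base intensity x relative intensity
    idx <- index_dia_run(run)
    g <- design_assays(d)[[ci]]
    x <- extract_xics(idx, g, rt_window = 40, ppm_tol = 10)
    j <- which.max(g$transitions$library_intensity)
    apex <- max(x$ms2[[j]]$intensity)
    rel <- cm$fragment_template$rel_intensity[
      match(g$transitions$fragment_formula[j], cm$fragment_template$formula)]
    expect_equal(apex, cm$base_intensity * rel, tolerance = 0.01)
    expect_equal(x$ms2[[j]]$rt[which.max(x$ms2[[j]]$intensity)], cm$rt,
                 tolerance = d$ms1_interval)
  }
})

test_that("total XIC area matches the analytic Gaussian area within 1%", {
  # scan interval at sigma/4 < sigma/3
  set.seed(4)
  cms <- sim_compound_set(1, gradient_length = 100, peak_sigma = 4)
  d <- sim_design(cms, n_dilutions = 1, n_replicates = 1, gradient_length = 100,
                  ms1_interval = 1, mass_jitter_ppm = 0, intensity_cv = 0,
                  noise_peaks_per_spectrum = 0, seed = 4)
  sim <- simulate_dia(d)
  g <- design_assays(d, n = 1)[[1]]
  x <- extract_xics(index_dia_run(sim$runs[[1]]), g, rt_window = 45, ppm_tol = 10)
  ch <- x$ms2[[1]]
  area <- sum(diff(ch$rt) * (ch$intensity[-1] + ch$intensity[-length(ch$intensity)]) / 2)
  cm <- cms[[1]]
  rel <- cm$fragment_template$rel_intensity[
    match(g$transitions$fragment_formula[1], cm$fragment_template$formula)]
  analytic <- cm$base_intensity * rel * cm$peak_sigma * sqrt(2 * pi)
  expect_equal(area, analytic, tolerance = 0.01)
})

test_that("the dilution series is exact at cv = 0 and spans 5 orders", {
  set.seed(5)
  cms <- sim_compound_set(2, gradient_length = 80)
  d <- sim_design(cms, n_dilutions = 10, dilution_factor = 4, n_replicates = 1,
                  gradient_length = 80, ms1_interval = 2, intensity_cv = 0,
                  noise_peaks_per_spectrum = 0, mass_jitter_ppm = 0, seed = 5)
  sim <- simulate_dia(d)
  tr <- sim$truth[sim$truth$compound == "cmpd001", ]
  tr <- tr[order(tr$dilution_step), ]
  expect_equal(tr$true_area[-nrow(tr)] / tr$true_area[-1], rep(4, 9))
  expect_gt(max(sim$truth$true_area) / min(sim$truth$true_area), 1e5)
  expect_equal(4^9, 262144)  # 10-step 4-fold series: > 5 orders of magnitude
})

test_that("absent assays avoid all real traces and are reproducible", {
  d <- tiny_design(seed = 21, n = 5)
  ab <- make_absent_assays(d, 10)
  expect_length(ab, 10)
  real <- unlist(lapply(d$compounds, function(cm) {
    prec <- adduct_mz(monoisotopic_mass(cm$formula), cm$adduct)
    frag <- vapply(cm$fragment_template$formula, function(f)
      monoisotopic_mass(f) + 1.00727646, numeric(1))
    c(prec + 0:2 * 1.0033548, frag)
  }))
  for (g in ab) {
    traces <- c(g$precursor_mz, g$transitions$fragment_mz)
    for (t in traces)
      expect_gt(min(abs(t - real) / t * 1e6), 25)
  }
  expect_length(make_absent_assays(d, 0), 0)
  ab2 <- make_absent_assays(d, 10)
  expect_equal(vapply(ab, `[[`, numeric(1), "precursor_mz"),
               vapply(ab2, `[[`, numeric(1), "precursor_mz"))
})
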