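# Targeted extraction: window assignment, XICs, peak-group detection and
# sub-score computation.

test_that("window assignment is half-open and errors outside coverage", {
  W <- cbind(lower = c(100, 300), upper = c(300, 500))
  expect_equal(assign_window(250, W), 1L)
  expect_equal(assign_window(300, W), 2L)   # boundary belongs to the upper window
  expect_error(assign_window(950, W), "not covered")
})

test_that("noise-free XICs reproduce the true apex and decoys see noise only", {
  d <- tiny_design(seed = 51, n = 3, noise = 0, jitter = 0, cv = 0)
  sim <- simulate_dia(d)
  idx <- index_dia_run(sim$runs[[1]])
  tg <- design_assays(d)
  for (ci in seq_along(tg)) {
    g <- tg[[ci]]
    cm <- d$compounds[[ci]]
    x <- extract_xics(idx, g)
    # same-grid property
    for (ch in x$ms2) expect_identical(ch$rt, x$ms2[[1]]$rt)
    total <- Reduce(`+`, lapply(x$ms2, `[[`, "intensity"))
    expect_lt(abs(x$ms2[[1]]$rt[which.max(total)] - cm$rt), d$ms1_interval + 1e-9)
    j <- which.max(g$transitions$library_intensity)
    rel <- cm$fragment_template$rel_intensity[
      match(g$transitions$fragment_formula[j], cm$fragment_template$formula)]
    # the apex scan samples the Gaussian up to half a cycle off the true rt
    t_apex <- x$ms2[[j]]$rt[which.max(x$ms2[[j]]$intensity)]
    expected <- cm$base_intensity * rel *
      exp(-(t_apex - cm$rt)^2 / (2 * cm$peak_sigma^2))
    expect_equal(max(x$ms2[[j]]$intensity), expected, tolerance = 1e-6)
  }
  # an absent assay's XICs carry no signal at all in the noise-free run
  ab <- make_absent_assays(d, 1)[[1]]
  xa <- extract_xics(idx, ab)
  expect_equal(max(vapply(xa$ms2, function(ch) max(ch$intensity), numeric(1))), 0)
  # an RT window that excludes the peak gives a flat XIC
  g1 <- tg[[1]]
  g1$library_rt <- g1$library_rt + 200
  x1 <- extract_xics(idx, g1, rt_window = 30)
  expect_true(all(vapply(x1$ms2, function(ch) all(ch$intensity == 0), logical(1))))
})

test_that("peak groups recover the analytic Gaussian area within 2%", {
  rt <- seq(0, 100, by = 1)
  A <- 1000; mu <- 50; sg <- 5
  gauss <- A * exp(-(rt - mu)^2 / (2 * sg^2))
  xics <- list(ms2 = list(list(rt = rt, intensity = gauss, target_mz = 200,
                               level = "MS2", role = "fragment_1")),
               ms1 = list())
  pg <- find_peak_groups(xics, smoothing_sigma = 1, max_rank = 5)
  expect_length(pg, 1)
  expect_equal(pg[[1]]$rt_apex, mu, tolerance = 1)
  expect_equal(pg[[1]]$transition_areas[1], A * sg * sqrt(2 * pi),
               tolerance = 0.02)
  # two baseline-separated peaks -> two groups, ranked by apex
  two <- gauss + 0.5 * A * exp(-(rt - 20)^2 / (2 * 3^2))
  xics$ms2[[1]]$intensity <- two
  pg2 <- find_peak_groups(xics, smoothing_sigma = 1, max_rank = 5)
  expect_length(pg2, 2)
  expect_equal(pg2[[1]]$rt_apex, mu, tolerance = 1)
  expect_equal(pg2[[2]]$rt_apex, 20, tolerance = 1)
  expect_equal(vapply(pg2, `[[`, numeric(1), "rank"), c(1, 2))
  # flat zero trace -> nothing
  xics$ms2[[1]]$intensity <- rep(0, length(rt))
  expect_length(find_peak_groups(xics), 0)
})

test_that("sub-scores behave on constructed traces", {
  rt <- seq(0, 60, by = 1)
  shape <- exp(-(rt - 30)^2 / 18)
  mk_group <- function(libint) transition_group(
    "g", "c", "C10H12O2", "[M+H]+", 165.09, 30,
    data.frame(fragment_mz = 100 + seq_along(libint),
               library_intensity = libint))
  # identical duplicated trace: perfect co-elution and shape
  xics <- list(ms2 = list(
    list(rt = rt, intensity = 100 * shape, target_mz = 101, level = "MS2",
         role = "fragment_1"),
    list(rt = rt, intensity = 100 * shape, target_mz = 102, level = "MS2",
         role = "fragment_2")), ms1 = list())
  pg <- find_peak_groups(xics)[[1]]
  sc <- score_peak_group(pg, xics, mk_group(c(1, 1)))$scores
  expect_equal(unname(sc["xcorr_coelution"]), 0)
  expect_equal(unname(sc["xcorr_shape"]), 1, tolerance = 1e-6)
  # trace shifted by exactly 3 scans: pairwise best shift 3
  sh <- c(rep(0, 3), 100 * shape)[seq_along(rt)]
  xics$ms2[[2]]$intensity <- sh
  pg <- find_peak_groups(xics)[[1]]
  sc <- score_peak_group(pg, xics, mk_group(c(1, 1)))$scores
  expect_equal(unname(sc["xcorr_coelution"]), 3)
  # areas proportional to library intensities: perfect library correlation
  xics$ms2[[2]]$intensity <- 40 * shape
  xics$ms2[[3]] <- list(rt = rt, intensity = 10 * shape, target_mz = 103,
                        level = "MS2", role = "fragment_3")
  pg <- find_peak_groups(xics)[[1]]
  sc <- score_peak_group(pg, xics, mk_group(c(1, 0.4, 0.1)))$scores
  expect_equal(unname(sc["library_corr"]), 1, tolerance = 1e-9)
})

test_that("extraction is linear in intensity", {
  d <- tiny_design(seed = 52, n = 2, noise = 0, jitter = 0, cv = 0)
  sim <- simulate_dia(d)
  run2 <- sim$runs[[1]]
  for (i in seq_along(run2$spectra))
    run2$spectra[[i]]$intensity <- 2 * run2$spectra[[i]]$intensity
  tg <- design_assays(d)
  pg1 <- extract_peak_groups(sim$runs[[1]], unname(tg))
  pg2 <- extract_peak_groups(run2, unname(tg))
  expect_equal(pg2$total_area, 2 * pg1$total_area, tolerance = 1e-9)
  expect_equal(pg2$precursor_area, 2 * pg1$precursor_area, tolerance = 1e-9)
})

test_that("decoy peak groups score stochastically below targets", {
  set.seed(53)
  cms <- sim_compound_set(50, gradient_length = 400, n_fragments = 5)
  d <- sim_design(cms, n_dilutions = 1, n_replicates = 1,
                  gradient_length = 400, ms1_interval = 2,
                  noise_peaks_per_spectrum = 800, seed = 53)
  sim <- simulate_dia(d)
  tg <- design_assays(d)
  dec <- generate_decoys(unname(tg), seed = 54, trees = attr(tg, "trees"))
  pg <- extract_peak_groups(sim$runs, dec$library)
  top <- pg[pg$rank == 1, ]
  w <- stats::wilcox.test(top$xcorr_shape[!top$is_decoy],
                          top$xcorr_shape[top$is_decoy],
                          alternative = "greater")
  expect_lt(w$p.value, 0.01)
})
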