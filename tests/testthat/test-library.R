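# Assay library construction: candidate filtering, transition extraction,
# ambiguity resolution, collision-energy merging and the full build chain.

test_that("filter_candidates drops by reason and logs counts", {
  run <- new_run(list(
    new_spectrum(1, 1, c(100, 200), c(1, 1)),
    new_spectrum(2, 2, c(50, 60, 70), c(1, 1, 1), precursor_mz = 100),
    new_spectrum(2, 3, c(50, 60, 70, 80, 90), c(1, 1, 1, 1, 1),
                 precursor_mz = 200)), "DDA")
  ft <- data.frame(mz = c(100, 200, 300), rt_apex = c(2, 3, 4))
  ft$formula_candidates <- list(data.frame(name = "a", formula = "C6H6",
                                           ppm_error = 0),
                                data.frame(name = "b", formula = "C7H8",
                                           ppm_error = 0),
                                NULL)
  ft$ms2_idx <- list(2L, 3L, integer(0))
  out <- filter_candidates(ft, run)
  rep <- attr(out, "drop_report")
  expect_equal(nrow(out), 1)
  expect_equal(out$mz, 200)                      # 5-peak MS2 + formula kept
  expect_equal(unname(rep["ms2_too_small"]), 1)  # 3-peak MS2 dropped
  expect_equal(unname(rep["no_ms1_id"]), 1)      # no formula candidate
})

test_that("extract_transitions takes top-n with documented tie-break", {
  tree <- structure(list(
    root_formula = "C10H10O4",
    nodes = data.frame(
      formula = c("C10H10O4", "C9H6O3", "C8H6O2", "C7H6O", "C6H6", "C5H4"),
      mz = c(NA, 175.039, 135.044, 107.049, 79.054, 65.038),
      intensity = c(NA, 100, 80, 80, 60, 2)),
    edges = data.frame(parent = 1:5, child = 2:6,
                       loss = c("CH4O", "CO", "CO", "CO", "CH2"))),
    class = "frag_tree")
  tr <- extract_transitions(tree, n = 3, min_rel_intensity = 0.05)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$library_intensity[1], 1)
  # intensity tie at 80: lower m/z first
  expect_equal(tr$fragment_mz[2:3], c(107.049, 135.044))
  # threshold: only 2 fragments pass a 0.5 relative floor
  tr2 <- extract_transitions(tree, n = 3, min_rel_intensity = 0.79)
  expect_equal(nrow(tr2), 3)   # 100, 80, 80 all >= 0.79 * 100
  tr3 <- extract_transitions(tree, n = 5, min_rel_intensity = 0.7)
  expect_equal(nrow(tr3), 3)   # the 60 and 2 fragments fail the floor
})

test_that("ambiguity resolves to highest precursor intensity, ties to earlier RT", {
  cands <- list(list(precursor_intensity = 1e4, rt = 10),
                list(precursor_intensity = 1e5, rt = 20))
  expect_equal(resolve_ambiguity(cands)$rt, 20)
  expect_equal(resolve_ambiguity(cands[1])$rt, 10)
  tie <- list(list(precursor_intensity = 1e5, rt = 30),
              list(precursor_intensity = 1e5, rt = 10))
  expect_equal(resolve_ambiguity(tie)$rt, 10)
})

test_that("collision-energy merging keeps the richer assay", {
  mk <- function(id, n, pint = 0) {
    g <- transition_group(id, id, "C10H12O2", "[M+H]+", 165.09, 100,
                          data.frame(fragment_mz = 100 + seq_len(n),
                                     library_intensity = rev(seq_len(n)) / n))
    attr(g, "precursor_intensity") <- pint
    g
  }
  lo <- list(mk("a", 3), mk("b", 2))
  hi <- list(mk("b", 3), mk("c", 1))
  merged <- merge_collision_energies(list(lo, hi))
  byname <- vapply(merged, `[[`, character(1), "compound_name")
  expect_setequal(byname, c("a", "b", "c"))            # union of compounds
  expect_equal(nrow(merged[[which(byname == "b")]]$transitions), 3)
  # disjoint sets: sizes add
  m2 <- merge_collision_energies(list(lapply(letters[1:10], mk, n = 2),
                                      lapply(letters[11:14], mk, n = 2)))
  expect_length(m2, 14)
})

test_that("build_library runs the full chain with correct coverage", {
  # noise-free, all templates >= 4 fragments: full coverage at 3 transitions
  set.seed(41)
  cms <- sim_compound_set(20, gradient_length = 400, n_fragments = 5)
  d <- sim_design(cms, n_dilutions = 1, n_replicates = 1,
                  gradient_length = 400, ms1_interval = 2,
                  mass_jitter_ppm = 0, intensity_cv = 0,
                  noise_peaks_per_spectrum = 0, seed = 41)
  dda <- simulate_dda(d)
  db <- data.frame(name = vapply(cms, `[[`, character(1), "name"),
                   formula = vapply(cms, function(x)
                     formula_to_string(x$formula), character(1)))
  bl <- build_library(dda$run, db)
  expect_true(all(unlist(bl$report$coverage) == 1.0))
  # no duplicate compound/adduct pairs
  keys <- vapply(bl$library, function(g) paste(g$compound_name, g$adduct),
                 character(1))
  expect_equal(anyDuplicated(keys), 0)
  # trees accompany every assay
  expect_setequal(names(bl$trees),
                  vapply(bl$library, `[[`, character(1), "group_id"))
})

test_that("2-fragment templates cap coverage at the 3-transition threshold", {
  # 2 of 20 compounds carry 2-fragment templates; with ambient noise their
  # MS2 spectra still pass the 4-peak validity filter, so they enter the
  # library with 2 transitions: 1-transition coverage 100%, 3-transition 90%
  set.seed(12)
  cms <- sim_compound_set(20, gradient_length = 400,
                          n_fragments = c(rep(5, 18), 2, 2))
  d <- sim_design(cms, n_dilutions = 1, n_replicates = 1,
                  gradient_length = 400, ms1_interval = 2,
                  noise_peaks_per_spectrum = 30, seed = 12)
  dda <- simulate_dda(d)
  db <- data.frame(name = vapply(cms, `[[`, character(1), "name"),
                   formula = vapply(cms, function(x)
                     formula_to_string(x$formula), character(1)))
  cov <- build_library(dda$run, db)$report$coverage
  expect_equal(unname(cov["1_transition"]), 1.0)
  expect_equal(unname(cov["3_transitions"]), 0.9)
})

test_that("an empty DDA run gives an empty library and zero report", {
  run <- new_run(lapply(seq(0, 50, 2), function(t)
    new_spectrum(1, t, numeric(0), numeric(0))), "DDA")
  db <- data.frame(name = "x", formula = "C6H6")
  bl <- build_library(run, db)
  expect_length(bl$library, 0)
  expect_true(all(unlist(bl$report$coverage) == 0))
})
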