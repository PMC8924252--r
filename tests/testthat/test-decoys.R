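# Decoy generation: tree re-rooting conservation, CH2 overlap handling,
# the CH2 fallback and whole-library decoy generation.

template_tree <- function(seed) {
  set.seed(seed)
  cm <- sim_compound_set(1, gradient_length = 100,
                         n_fragments = sample(3:6, 1))[[1]]
  fmz <- vapply(cm$fragment_template$formula, function(x)
    monoisotopic_mass(x) + 1.00727646, numeric(1))
  o <- order(fmz)
  sp <- new_spectrum(2, cm$rt, fmz[o], cm$fragment_template$rel_intensity[o],
                     precursor_mz = adduct_mz(monoisotopic_mass(cm$formula),
                                              "[M+H]+"))
  build_tree(cm$formula, sp, ppm_tol = 5, min_annotated = 1)
}

test_that("re-rooting preserves the loss multiset and node count", {
  tree <- template_tree(81)
  d1 <- reroot_tree(tree, seed = 1)
  expect_equal(sort(tree_losses(d1)), sort(tree_losses(tree)))
  expect_equal(nrow(d1$nodes), nrow(tree$nodes))
  expect_silent(validate_frag_tree(d1))
  # determinism under a fixed seed
  d2 <- reroot_tree(tree, seed = 1)
  expect_identical(d1$nodes$mz, d2$nodes$mz)
  # single-node tree cannot be re-rooted
  single <- structure(list(root_formula = "C6H6",
                           nodes = data.frame(formula = "C6H6", mz = NA,
                                              intensity = NA),
                           edges = data.frame(parent = integer(0),
                                              child = integer(0),
                                              loss = character(0))),
                      class = "frag_tree")
  expect_error(reroot_tree(single), "impossible")
})

test_that("overlapping decoy transitions are CH2-shifted to disjointness", {
  tgt <- transition_group("t1", "x", "C10H14O4", "[M+H]+", 199.09, 50,
                          data.frame(fragment_mz = c(100.0, 150.0, 180.0),
                                     library_intensity = c(1, 0.8, 0.5)))
  # decoy tree whose first fragment sits 0.001 Th from a target fragment
  dt <- structure(list(root_formula = "C10H14O4",
                       nodes = data.frame(
                         formula = c("C10H14O4", "f1", "f2", "f3"),
                         mz = c(NA, 100.001, 120.0, 170.0),
                         intensity = NA),
                       edges = data.frame(parent = c(1, 1, 1), child = 2:4,
                                          loss = c("H2O", "CO", "CH2"))),
                  class = "frag_tree")
  d <- decoy_transitions(tgt, dt, mz_overlap_tol = 0.01)
  expect_true(d$is_decoy)
  expect_equal(d$group_id, "t1")
  expect_equal(d$transitions$fragment_mz[1], 100.001 + 14.015650,
               tolerance = 1e-6)
  expect_equal(d$transitions$fragment_mz[2:3], c(120, 170))
  # no overlaps: masses pass through
  dt$nodes$mz <- c(NA, 101.0, 120.0, 170.0)
  d2 <- decoy_transitions(tgt, dt, mz_overlap_tol = 0.01)
  expect_equal(d2$transitions$fragment_mz, c(101, 120, 170))
  # all-overlapping: every transition shifted, result disjoint from target
  dt$nodes$mz <- c(NA, 100.0, 150.0, 180.0)
  d3 <- decoy_transitions(tgt, dt, mz_overlap_tol = 0.01)
  for (m in d3$transitions$fragment_mz)
    expect_gt(min(abs(m - tgt$transitions$fragment_mz)), 0.01)
})

test_that("the CH2 fallback shifts every fragment once and only once", {
  tgt <- transition_group("t2", "y", NA, "[M+H]+", 400, 60,
                          data.frame(fragment_mz = c(100.0, 150.0),
                                     library_intensity = c(1, 0.5)))
  d <- fallback_ch2(tgt)
  expect_equal(d$transitions$fragment_mz, c(114.015650, 164.015650),
               tolerance = 1e-6)
  expect_equal(d$transitions$library_intensity, c(1, 0.5))
  expect_true(d$is_decoy)
  expect_error(fallback_ch2(d), "accumulate")   # shift must not stack
  expect_error(transition_group("e", "e", NA, "[M+H]+", 400, 60,
                                data.frame(fragment_mz = numeric(0),
                                           library_intensity = numeric(0))))
})

test_that("loss-multiset conservation holds over 100 random trees", {
  set.seed(83)
  seeds <- sample(1e6, 100)
  for (s in seeds) {
    tree <- template_tree(s)
    if (is.null(tree) || nrow(tree$nodes) < 2) next
    dec <- tryCatch(reroot_tree(tree), error = function(e) NULL)
    if (is.null(dec)) next
    expect_equal(sort(tree_losses(dec)), sort(tree_losses(tree)))
    expect_equal(nrow(dec$nodes), nrow(tree$nodes))
    validate_frag_tree(dec)
  }
})

test_that("generate_decoys yields exactly one decoy per target", {
  set.seed(84)
  cms <- sim_compound_set(50, gradient_length = 500, n_fragments = 5)
  d <- sim_design(cms, gradient_length = 500, seed = 84)
  tg <- design_assays(d)
  out <- generate_decoys(unname(tg), seed = 7, trees = attr(tg, "trees"))
  expect_length(out$library, 100)
  expect_equal(sum(vapply(out$library, `[[`, logical(1), "is_decoy")), 50)
  expect_setequal(unique(out$report$method),
                  intersect(c("rerooted", "overlap-shifted", "fallback"),
                            out$report$method))
  # post-overlap disjointness within each pair
  tgt_by_id <- out$library[1:50]
  for (i in 1:50) {
    t <- out$library[[i]]; dd <- out$library[[i + 50]]
    expect_equal(dd$group_id, t$group_id)
    for (m in dd$transitions$fragment_mz)
      expect_gt(min(abs(m - t$transitions$fragment_mz)), 0.01)
  }
  # determinism
  out2 <- generate_decoys(unname(tg), seed = 7, trees = attr(tg, "trees"))
  expect_identical(
    lapply(out$library, `[[`, "transitions"),
    lapply(out2$library, `[[`, "transitions"))
  # without trees everything falls back to the CH2 shift
  nofb <- generate_decoys(unname(tg)[1:5], seed = 7)
  expect_equal(attr(nofb$report, "fallback_fraction"), 1.0)
})
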