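# Decoy assay generation by fragmentation-tree re-rooting with the CH2
# overlap rule and a CH2 fallback, plus library-level decoy generation for
# imported libraries without trees.
#
# Re-rooting keeps the target tree's neutral-loss multiset exactly: the
# decoy root carries the precursor formula, a uniformly chosen non-root
# node's incoming loss is drawn first (promoting that lineage), the
# remaining losses are drawn in random order, and each loss attaches to the
# smallest compatible node, extending lineages downward. Decoy fragment
# masses are then the precursor mass minus cumulative losses along the new
# tree, so their m/z distribution matches that of real fragments — a
# requirement for an unbiased decoy null, since extraction tolerances are
# ppm-scaled. The precursor itself is never altered: no decoy is generated
# on MS1.

#' Re-root a fragmentation tree into a decoy tree
#'
#' @param tree A [build_tree()] result with at least two nodes.
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return A `frag_tree` whose loss multiset equals the target's exactly
#'   and whose node count matches the target's.
#' @export
reroot_tree <- function(tree, seed = NULL) {
  stopifnot(inherits(tree, "frag_tree"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(tree$nodes)
  if (n < 2) stop("re-rooting impossible: tree has a single node")
  losses <- tree$edges$loss
  # promote a uniformly chosen non-root node: its incoming loss is drawn first
  pick <- if (n == 2) 2L else sample(2:n, 1)
  first <- which(tree$edges$child == pick)
  rest <- setdiff(seq_along(losses), first)
  draw_order <- c(first, if (length(rest) > 1) sample(rest) else rest)
  precursor <- parse_formula(tree$nodes$formula[1])
  node_formulas <- list(precursor)
  node_mass <- monoisotopic_mass(precursor)
  nodes <- data.frame(formula = tree$nodes$formula[1], mz = tree$nodes$mz[1],
                      intensity = tree$nodes$intensity[1],
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = integer(0), child = integer(0),
                      loss = character(0), stringsAsFactors = FALSE)
  for (li in draw_order) {
    loss <- parse_formula(losses[li])
    compat <- which(vapply(node_formulas, function(nf) {
      if (!is_subformula(loss, nf)) return(FALSE)
      rem <- nf
      rem[names(loss)] <- rem[names(loss)] - loss
      sum(rem) > 0
    }, logical(1)))
    if (length(compat) == 0)
      stop("re-rooting failed: loss ", losses[li], " cannot attach")
    pmass <- vapply(node_formulas[compat], monoisotopic_mass, numeric(1))
    parent <- compat[which.min(pmass)]
    child <- formula_subtract(node_formulas[[parent]], loss)
    node_formulas[[length(node_formulas) + 1]] <- child
    nodes <- rbind(nodes, data.frame(
      formula = formula_to_string(child),
      mz = monoisotopic_mass(child) + PROTON_MASS,
      intensity = NA_real_, stringsAsFactors = FALSE))
    edges <- rbind(edges, data.frame(parent = parent, child = nrow(nodes),
                                     loss = losses[li], stringsAsFactors = FALSE))
  }
  structure(list(root_formula = tree$nodes$formula[1], nodes = nodes,
                 edges = edges), class = "frag_tree")
}

#' Decoy transitions from a re-rooted tree
#'
#' Decoy fragment m/z values come from the decoy tree's nodes (attachment
#' order); library intensities are copied from the target's intensity ranks.
#' Any decoy m/z within `mz_overlap_tol` of any target fragment m/z is
#' shifted by the CH2 mass (+14.015650 Da). The precursor m/z is unchanged.
#'
#' @param target Target [transition_group()].
#' @param decoy_tree A [reroot_tree()] result.
#' @param mz_overlap_tol Overlap tolerance (Th).
#' @return Decoy transition group (same `group_id`, `is_decoy = TRUE`).
#'   Attribute `"overlap_shifted"` reports whether any CH2 shift was applied.
#' @export
decoy_transitions <- function(target, decoy_tree, mz_overlap_tol = 0.01) {
  stopifnot(!target$is_decoy)
  k <- nrow(target$transitions)
  cand_mz <- decoy_tree$nodes$mz[-1]
  if (length(cand_mz) < k)
    stop("decoy tree has fewer fragments than the target has transitions")
  dmz <- cand_mz[seq_len(k)]
  tmz <- target$transitions$fragment_mz
  shifted <- FALSE
  for (i in seq_len(k)) {
    # a shifted mass may land on another target fragment; keep shifting
    # until clear (bounded: each step moves +14 Da)
    for (guard in 1:5) {
      if (!any(abs(dmz[i] - tmz) <= mz_overlap_tol)) break
      dmz[i] <- dmz[i] + CH2_MASS
      shifted <- TRUE
    }
  }
  o <- order(target$transitions$library_intensity, decreasing = TRUE)
  tr <- data.frame(fragment_mz = dmz,
                   library_intensity = target$transitions$library_intensity[o],
                   fragment_formula = decoy_tree$nodes$formula[-1][seq_len(k)],
                   stringsAsFactors = FALSE)
  g <- transition_group(target$group_id, target$compound_name,
                        if (is.na(target$formula)) NA else target$formula,
                        target$adduct, target$precursor_mz, target$library_rt,
                        tr, is_decoy = TRUE)
  attr(g, "overlap_shifted") <- shifted
  g
}

#' CH2-shift fallback decoy
#'
#' Decoy fragment m/z = target fragment m/z + 14.015650 Da (the CH2 mass),
#' intensities copied. Used when tree re-rooting fails or produces fragments
#' too similar to the target. Refuses to run on a decoy (the shift must not
#' accumulate).
#'
#' @param target Target transition group.
#' @return Decoy transition group.
#' @export
fallback_ch2 <- function(target) {
  if (target$is_decoy)
    stop("fallback_ch2 applied to a decoy: CH2 shift would accumulate")
  tr <- target$transitions
  tr$fragment_mz <- tr$fragment_mz + CH2_MASS
  tr$fragment_formula <- ""
  transition_group(target$group_id, target$compound_name,
                   if (is.na(target$formula)) NA else target$formula,
                   target$adduct, target$precursor_mz, target$library_rt,
                   tr, is_decoy = TRUE)
}

# Fraction of decoy fragments lying within tol of any target fragment.
decoy_target_similarity <- function(decoy, target, tol = 0.01) {
  mean(vapply(decoy$transitions$fragment_mz, function(m)
    any(abs(m - target$transitions$fragment_mz) <= tol), logical(1)))
}

#' Generate one decoy per target assay
#'
#' For each target, tries fragmentation-tree re-rooting (when a tree with at
#' least two fragment nodes is available); falls back to the CH2 shift when
#' re-rooting fails, the tree is missing, or the decoy is too similar to the
#' target (> `similarity_threshold` of decoy fragments within
#' `similarity_tol` of a target fragment). Exactly one decoy is produced per
#' target, so target and decoy counts always match.
#'
#' @param library List of target transition groups.
#' @param params List: `mz_overlap_tol` (Th), `similarity_threshold`,
#'   `similarity_tol` (Th).
#' @param seed Integer seed controlling re-rooting randomness.
#' @param trees Optional named list of fragmentation trees keyed by
#'   group_id (e.g. from [build_library()] or [design_assays()]).
#' @return List with `library` (targets followed by decoys) and `report`
#'   (data frame `group_id`, `method` in rerooted/overlap-shifted/fallback,
#'   plus attribute `fallback_fraction`).
#' @export
generate_decoys <- function(library, params = list(), seed = 1, trees = NULL) {
  p <- utils::modifyList(list(mz_overlap_tol = 0.01, similarity_threshold = 0.8,
                              similarity_tol = 0.01), params)
  stopifnot(all(!vapply(library, `[[`, logical(1), "is_decoy")))
  set.seed(seed)
  decoys <- list()
  method <- character(length(library))
  for (i in seq_along(library)) {
    g <- library[[i]]
    tree <- if (!is.null(trees)) trees[[g$group_id]] else NULL
    d <- NULL
    if (!is.null(tree) && nrow(tree$nodes) >= 2) {
      d <- tryCatch({
        dt <- reroot_tree(tree)
        decoy_transitions(g, dt, p$mz_overlap_tol)
      }, error = function(e) NULL)
      if (!is.null(d) &&
          decoy_target_similarity(d, g, p$similarity_tol) > p$similarity_threshold)
        d <- NULL
    }
    if (is.null(d)) {
      d <- fallback_ch2(g)
      method[i] <- "fallback"
    } else {
      method[i] <- if (isTRUE(attr(d, "overlap_shifted"))) "overlap-shifted"
                   else "rerooted"
    }
    decoys[[i]] <- d
  }
  report <- data.frame(group_id = vapply(library, `[[`, character(1), "group_id"),
                       method = method, stringsAsFactors = FALSE)
  attr(report, "fallback_fraction") <- mean(method == "fallback")
  list(library = c(library, decoys), report = report)
}
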