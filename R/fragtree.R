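# Compositional fragmentation trees: annotate MS2 peaks with subformulas of
# the precursor formula and connect them by neutral-loss edges.
#
# This is a deliberately simple tree builder: fragments are treated as singly
# protonated even-electron ions, the best annotation per peak is the smallest
# |ppm| (ties broken lexicographically), and each annotated fragment attaches
# to the compatible (superset-formula) node that minimizes the neutral-loss
# mass. There is no global tree-score optimization.

# Enumerate the full subformula space of a precursor once: a matrix of
# element counts plus the vector of neutral monoisotopic masses.
subformula_space <- function(precursor, max_atoms = 60) {
  f <- parse_formula(precursor)
  if (sum(f) > max_atoms)
    stop("precursor exceeds the ", max_atoms, "-atom cap for subformula enumeration")
  grids <- lapply(f, function(k) 0:k)
  n_comb <- prod(vapply(grids, length, numeric(1)))
  if (n_comb > 5e6) stop("subformula space too large")
  M <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(M) <- names(f)
  mass <- as.numeric(M %*% ATOMIC_MASS[colnames(M)])
  o <- order(mass)    # mass-sorted so annotation is a binary search
  list(counts = M[o, , drop = FALSE], mass = mass[o], elements = colnames(M))
}

row_formula <- function(space, i) {
  v <- space$counts[i, ]
  parse_formula(v[v > 0])
}

# Vectorized RDBE over the subformula count matrix.
space_rdbe <- function(space) {
  M <- space$counts
  g <- function(el) if (el %in% colnames(M)) M[, el] else 0
  g("C") + 1 + (g("N") + g("P")) / 2 -
    (g("H") + g("F") + g("Cl") + g("Br") + g("I")) / 2
}

#' Enumerate precursor subformulas matching a fragment mass
#'
#' All element-wise subformulas of the precursor whose protonated ion mass
#' (neutral mass + proton) lies within `ppm_tol` of `target_mass`, filtered
#' to ring-double-bond equivalents >= -0.5 and sorted by |ppm error|.
#'
#' @param precursor Precursor formula.
#' @param target_mass Observed fragment ion m/z (Th).
#' @param ppm_tol Mass tolerance (ppm).
#' @param ion_shift Mass added to the neutral subformula to form the ion;
#'   defaults to a proton (singly protonated even-electron fragments).
#' @return List of formulas (named integer vectors), best match first.
#' @export
enumerate_subformulas <- function(precursor, target_mass, ppm_tol = 10,
                                  ion_shift = PROTON_MASS) {
  space <- subformula_space(precursor)
  hits <- annotate_mass(space, target_mass, ppm_tol, ion_shift)
  lapply(hits$idx, function(i) row_formula(space, i))
}

# Indices + ppm errors of subformulas matching one target ion mass.
annotate_mass <- function(space, target_mass, ppm_tol, ion_shift,
                          rdbe_vec = NULL) {
  tol <- target_mass * ppm_tol * 1e-6
  neutral <- target_mass - ion_shift
  lo <- findInterval(neutral - tol, space$mass) + 1
  hi <- findInterval(neutral + tol, space$mass)
  if (hi < lo) return(list(idx = integer(0), ppm = numeric(0)))
  idx <- lo:hi
  ppm <- (space$mass[idx] + ion_shift - target_mass) / target_mass * 1e6
  keep <- abs(ppm) <= ppm_tol
  idx <- idx[keep]; ppm <- ppm[keep]
  if (length(idx) == 0) return(list(idx = integer(0), ppm = numeric(0)))
  if (is.null(rdbe_vec)) rdbe_vec <- space_rdbe(space)
  keep <- rdbe_vec[idx] >= -0.5
  idx <- idx[keep]; ppm <- ppm[keep]
  if (length(idx) == 0) return(list(idx = integer(0), ppm = numeric(0)))
  key <- vapply(idx, function(i) formula_to_string(row_formula(space, i)),
                character(1))
  o <- order(abs(ppm), key)
  list(idx = idx[o], ppm = ppm[o])
}

#' Build a compositional fragmentation tree from an MS2 spectrum
#'
#' Each peak is annotated with its best-matching precursor subformula
#' (smallest |ppm|, ties broken lexicographically); unannotated peaks are
#' dropped. Peaks whose annotation equals the precursor formula become the
#' root observation. The remaining annotated fragments are attached, in
#' order of decreasing mass, to the already-placed node with a superset
#' formula that minimizes the neutral-loss mass; the root is always
#' compatible, so the tree is connected by construction.
#'
#' @param precursor Precursor formula.
#' @param ms2 A [new_spectrum()] MS2 spectrum.
#' @param ppm_tol Annotation tolerance (ppm).
#' @param min_annotated Minimum number of annotated fragment peaks; if fewer
#'   annotate, `NULL` is returned.
#' @param ion_shift Fragment ion shift; see [enumerate_subformulas()].
#' @return Object of class `frag_tree`, or `NULL`. Node 1 is the root
#'   (precursor); `edges$loss` holds neutral-loss formula strings.
#' @export
build_tree <- function(precursor, ms2, ppm_tol = 10, min_annotated = 2,
                       ion_shift = PROTON_MASS) {
  precursor <- parse_formula(precursor)
  space <- subformula_space(precursor)
  rd <- space_rdbe(space)
  prec_str <- formula_to_string(precursor)
  ann <- list()
  for (j in seq_along(ms2$mz)) {
    hit <- annotate_mass(space, ms2$mz[j], ppm_tol, ion_shift, rd)
    if (length(hit$idx) == 0) next
    ann[[length(ann) + 1]] <- list(formula = row_formula(space, hit$idx[1]),
                                   mz = ms2$mz[j], intensity = ms2$intensity[j])
  }
  is_prec <- vapply(ann, function(a) formula_to_string(a$formula) == prec_str,
                    logical(1))
  root_obs <- if (any(is_prec)) ann[is_prec][[which.max(
    vapply(ann[is_prec], `[[`, numeric(1), "intensity"))]] else NULL
  frags <- ann[!is_prec]
  if (length(frags) < min_annotated) return(NULL)
  masses <- vapply(frags, function(a) monoisotopic_mass(a$formula), numeric(1))
  ord <- order(masses, decreasing = TRUE)
  nodes <- data.frame(
    formula = prec_str,
    mz = if (is.null(root_obs)) NA_real_ else root_obs$mz,
    intensity = if (is.null(root_obs)) NA_real_ else root_obs$intensity,
    stringsAsFactors = FALSE)
  node_formulas <- list(precursor)
  node_mass <- monoisotopic_mass(precursor)
  edges <- data.frame(parent = integer(0), child = integer(0),
                      loss = character(0), stringsAsFactors = FALSE)
  for (i in ord) {
    a <- frags[[i]]
    fm <- monoisotopic_mass(a$formula)
    compat <- which(vapply(node_formulas, function(nf)
      is_subformula(a$formula, nf) &&
        formula_to_string(nf) != formula_to_string(a$formula), logical(1)))
    if (length(compat) == 0) next
    pmass <- vapply(node_formulas[compat], monoisotopic_mass, numeric(1))
    parent <- compat[which.min(pmass - fm)]
    loss <- formula_subtract(node_formulas[[parent]], a$formula)
    nodes <- rbind(nodes, data.frame(formula = formula_to_string(a$formula),
                                     mz = a$mz, intensity = a$intensity,
                                     stringsAsFactors = FALSE))
    node_formulas[[nrow(nodes)]] <- a$formula
    edges <- rbind(edges, data.frame(parent = parent, child = nrow(nodes),
                                     loss = formula_to_string(loss),
                                     stringsAsFactors = FALSE))
  }
  if (nrow(nodes) - 1 < min_annotated) return(NULL)
  structure(list(root_formula = prec_str, nodes = nodes, edges = edges),
            class = "frag_tree")
}

#' @export
print.frag_tree <- function(x, ...) {
  cat(sprintf("<frag_tree> root %s, %d fragment node(s)\n",
              x$root_formula, nrow(x$nodes) - 1))
  invisible(x)
}

#' Multiset of neutral losses of a fragmentation tree
#'
#' @param tree A [build_tree()] result.
#' @return Character vector of loss formula strings, one per edge (with
#'   multiplicity).
#' @export
tree_losses <- function(tree) {
  stopifnot(inherits(tree, "frag_tree"))
  tree$edges$loss
}

#' Check fragmentation-tree invariants
#'
#' Asserts element-wise conservation (`parent = child + loss` for every
#' edge), a single root, and that every non-root node has exactly one parent.
#'
#' @param tree A `frag_tree`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_frag_tree <- function(tree) {
  stopifnot(inherits(tree, "frag_tree"))
  n <- nrow(tree$nodes)
  if (n >= 2) {
    if (!setequal(tree$edges$child, 2:n) || anyDuplicated(tree$edges$child))
      stop("every non-root node must have exactly one parent edge")
  }
  for (k in seq_len(nrow(tree$edges))) {
    p <- parse_formula(tree$nodes$formula[tree$edges$parent[k]])
    ch <- parse_formula(tree$nodes$formula[tree$edges$child[k]])
    lo <- parse_formula(tree$edges$loss[k])
    if (formula_to_string(formula_add(ch, lo)) != formula_to_string(p))
      stop("edge ", k, " violates parent = child + loss")
  }
  invisible(TRUE)
}
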