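# Assay (transition group) container and the canonical TSV library format.

TRANSITION_COLUMNS <- c("group_id", "compound_name", "formula", "adduct",
                        "precursor_mz", "library_rt_sec", "fragment_mz",
                        "library_intensity", "fragment_formula", "is_decoy")

#' Construct a transition group (assay)
#'
#' One assay: a compound + adduct with its precursor m/z, library retention
#' time and fragment transitions. Decoy assays keep the paired target's
#' `group_id` and set `is_decoy`.
#'
#' @param group_id Assay identifier (shared between a target and its decoy).
#' @param compound_name Compound name.
#' @param formula Molecular formula (string or named vector), or `NA`.
#' @param adduct Adduct label.
#' @param precursor_mz Precursor m/z (Th).
#' @param library_rt Library retention time (seconds).
#' @param transitions Data frame with columns `fragment_mz`,
#'   `library_intensity` and optionally `fragment_formula` (string, `""` if
#'   unannotated).
#' @param is_decoy Logical.
#' @return Object of class `transition_group`.
#' @export
transition_group <- function(group_id, compound_name, formula, adduct,
                             precursor_mz, library_rt, transitions,
                             is_decoy = FALSE) {
  stopifnot(is.data.frame(transitions), nrow(transitions) >= 1,
            all(c("fragment_mz", "library_intensity") %in% names(transitions)))
  if (is.null(transitions$fragment_formula))
    transitions$fragment_formula <- ""
  if (any(transitions$fragment_mz >= precursor_mz + CH2_MASS + 1))
    stop("fragment m/z exceeds precursor m/z beyond the CH2 allowance")
  fstr <- if (length(formula) == 1 && is.na(formula)) NA_character_
          else formula_to_string(formula)
  structure(list(
    group_id = as.character(group_id), compound_name = as.character(compound_name),
    formula = fstr, adduct = adduct, precursor_mz = as.numeric(precursor_mz),
    library_rt = as.numeric(library_rt),
    transitions = transitions[, c("fragment_mz", "library_intensity", "fragment_formula")],
    is_decoy = isTRUE(is_decoy)
  ), class = "transition_group")
}

#' @export
print.transition_group <- function(x, ...) {
  cat(sprintf("<assay %s%s> %s %s prec=%.4f rt=%.1fs, %d transitions\n",
              x$group_id, if (x$is_decoy) " (decoy)" else "", x$compound_name,
              x$adduct, x$precursor_mz, x$library_rt, nrow(x$transitions)))
  invisible(x)
}

#' Write an assay library as TSV
#'
#' One row per transition; the round trip through [read_transition_list()]
#' is lossless.
#'
#' @param groups List of [transition_group()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(groups, path) {
  rows <- lapply(groups, function(g) {
    data.frame(group_id = g$group_id, compound_name = g$compound_name,
               formula = ifelse(is.na(g$formula), "", g$formula),
               adduct = g$adduct, precursor_mz = g$precursor_mz,
               library_rt_sec = g$library_rt,
               fragment_mz = g$transitions$fragment_mz,
               library_intensity = g$transitions$library_intensity,
               fragment_formula = g$transitions$fragment_formula,
               is_decoy = as.integer(g$is_decoy),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(format(tab, digits = 12, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an assay library from TSV
#'
#' @param path TSV path with the columns written by
#'   [write_transition_list()]. A missing mandatory column raises a schema
#'   error naming the column.
#' @return List of [transition_group()] objects.
#' @export
read_transition_list <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(group_id = "character"))
  missing_cols <- setdiff(TRANSITION_COLUMNS, names(tab))
  if (length(missing_cols) > 0)
    stop("transition list schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  key <- paste(tab$group_id, tab$is_decoy)
  lapply(split(seq_len(nrow(tab)), factor(key, levels = unique(key))), function(i) {
    r1 <- tab[i[1], ]
    transition_group(
      group_id = r1$group_id, compound_name = r1$compound_name,
      formula = if (is.na(r1$formula) || r1$formula == "") NA else r1$formula,
      adduct = r1$adduct, precursor_mz = r1$precursor_mz,
      library_rt = r1$library_rt_sec,
      transitions = data.frame(fragment_mz = tab$fragment_mz[i],
                               library_intensity = tab$library_intensity[i],
                               fragment_formula = ifelse(is.na(tab$fragment_formula[i]),
                                                         "", tab$fragment_formula[i]),
                               stringsAsFactors = FALSE),
      is_decoy = tab$is_decoy[i[1]] == 1
    )
  })
}
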