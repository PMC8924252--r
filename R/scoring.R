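# Semi-supervised target-decoy discriminant learning and decoy-null
# q-value estimation.
#
# The learner mirrors the mProphet/PyProphet scheme: start from the single
# sub-score that best separates targets from decoys, iteratively select
# confident targets (q below a learning threshold) as positives against all
# decoys, refit a two-class linear discriminant (pooled covariance with a
# small ridge), and average the weight vectors over cross-validation folds.
# The d-score scale is defined by standardizing decoys to mean 0, sd 1.

auc_mann_whitney <- function(scores, is_target) {
  r <- rank(scores)
  n1 <- sum(is_target); n0 <- sum(!is_target)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[is_target]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Two-class LDA direction with pooled covariance and ridge stabilization.
lda_direction <- function(X1, X0, ridge = 1e-6) {
  mu1 <- colMeans(X1); mu0 <- colMeans(X0)
  S <- ((nrow(X1) - 1) * stats::cov(X1) + (nrow(X0) - 1) * stats::cov(X0)) /
    (nrow(X1) + nrow(X0) - 2)
  S <- S + diag(ridge * mean(diag(S)) + 1e-12, ncol(S))
  w <- solve(S, mu1 - mu0)
  w / sqrt(sum(w^2))
}

# Best peak group per (run, assay) under the current score; targets and
# decoys of the same group_id are ranked separately.
top_per_group <- function(d, run_id, group_id, is_decoy) {
  key <- paste(run_id, group_id, is_decoy)
  o <- order(key, -d)
  sel <- o[!duplicated(key[o])]
  sort(sel)
}

#' Learn a target-decoy discriminant from peak-group scores
#'
#' @param peak_groups Peak-group table from [extract_peak_groups()]
#'   containing the sub-score columns, `is_decoy`, `run_id` and `group_id`.
#' @param score_cols Character vector of score columns to learn on.
#' @param params List: `learning_threshold` (q-value cutoff for positives,
#'   0.15), `n_iter` (10), `k_folds` (3), `min_groups` (30).
#' @param seed Integer seed (fold assignment).
#' @return List with `weights` (named vector over `score_cols`),
#'   `initial_score` (name of the best single sub-score), `log` (data frame
#'   of per-fold, per-iteration positive counts) and `auc` (final
#'   discriminant AUC on best peak groups).
#' @export
learn_discriminant <- function(peak_groups,
                               score_cols = default_score_columns(peak_groups),
                               params = list(), seed = 1) {
  p <- utils::modifyList(list(learning_threshold = 0.15, n_iter = 10,
                              k_folds = 3, min_groups = 30), params)
  X <- as.matrix(peak_groups[, score_cols, drop = FALSE])
  if (all(apply(X, 2, stats::sd) == 0))
    stop("degenerate score matrix: all sub-scores are constant")
  keep_col <- apply(X, 2, stats::sd) > 0
  tgt_groups <- unique(peak_groups$group_id[!peak_groups$is_decoy])
  dec_groups <- unique(peak_groups$group_id[peak_groups$is_decoy])
  if (length(tgt_groups) < p$min_groups)
    stop("too few target groups for learning (", length(tgt_groups), ")")
  if (length(dec_groups) < p$min_groups)
    stop("too few decoy groups for learning (", length(dec_groups), ")")
  set.seed(seed)
  fold_of <- c(
    stats::setNames(sample(rep_len(seq_len(p$k_folds), length(tgt_groups))), tgt_groups),
    stats::setNames(sample(rep_len(seq_len(p$k_folds), length(dec_groups))), dec_groups))
  # initial score: largest |AUC - 0.5| on best-per-group peak groups,
  # using apex intensity as the provisional ranking score
  prov <- top_per_group(peak_groups$apex_intensity, peak_groups$run_id,
                        peak_groups$group_id, peak_groups$is_decoy)
  auc0 <- vapply(score_cols, function(cn) {
    a <- auc_mann_whitney(peak_groups[[cn]][prov], !peak_groups$is_decoy[prov])
    if (is.na(a)) 0.5 else a
  }, numeric(1))
  init_col <- score_cols[which.max(abs(auc0 - 0.5))]
  init_sign <- if (auc0[init_col] >= 0.5) 1 else -1
  logs <- list()
  fold_w <- list()
  for (f in seq_len(p$k_folds)) {
    train <- peak_groups[fold_of[peak_groups$group_id] != f, , drop = FALSE]
    Xt <- as.matrix(train[, score_cols, drop = FALSE])
    d <- init_sign * Xt[, init_col]
    w <- NULL
    for (it in seq_len(p$n_iter)) {
      sel <- top_per_group(d, train$run_id, train$group_id, train$is_decoy)
      ds <- d[sel]; dec <- train$is_decoy[sel]
      q <- counting_qvalues(ds[!dec], ds[dec])
      pos_rows <- sel[!dec][q <= p$learning_threshold]
      neg_rows <- sel[dec]
      logs[[length(logs) + 1]] <- data.frame(fold = f, iter = it,
                                             n_positives = length(pos_rows))
      if (length(pos_rows) < 5 || length(neg_rows) < 5) break
      w_new <- tryCatch(
        lda_direction(Xt[pos_rows, keep_col, drop = FALSE],
                      Xt[neg_rows, keep_col, drop = FALSE]),
        error = function(e) NULL)
      if (is.null(w_new)) break
      d_new <- Xt[, keep_col, drop = FALSE] %*% w_new
      seln <- top_per_group(d_new, train$run_id, train$group_id, train$is_decoy)
      if (mean(d_new[seln][!train$is_decoy[seln]]) <
          mean(d_new[seln][train$is_decoy[seln]])) w_new <- -w_new
      w <- w_new
      d <- as.numeric(Xt[, keep_col, drop = FALSE] %*% w)
    }
    if (!is.null(w)) fold_w[[length(fold_w) + 1]] <- w
  }
  weights <- stats::setNames(numeric(length(score_cols)), score_cols)
  if (length(fold_w) > 0) {
    wbar <- Reduce(`+`, fold_w) / length(fold_w)
    wbar <- wbar / sqrt(sum(wbar^2))
    weights[names(wbar)] <- wbar
  } else {
    weights[init_col] <- init_sign
  }
  d_all <- as.numeric(X %*% weights)
  sel <- top_per_group(d_all, peak_groups$run_id, peak_groups$group_id,
                       peak_groups$is_decoy)
  final_auc <- auc_mann_whitney(d_all[sel], !peak_groups$is_decoy[sel])
  list(weights = weights, initial_score = init_col,
       initial_auc = max(abs(auc0 - 0.5)) + 0.5,
       log = do.call(rbind, logs), auc = final_auc)
}

#' Sub-score columns of a peak-group table
#'
#' @param peak_groups Peak-group table.
#' @param level `"joint"` (default), `"ms2"` or `"ms1"`.
#' @return Character vector of score column names present in the table.
#' @export
default_score_columns <- function(peak_groups, level = "joint") {
  ms2 <- c("xcorr_coelution", "xcorr_shape", "library_corr", "sn")
  ms1 <- c("ms1_isotope_corr", "ms1_coelution")
  want <- switch(level, joint = c(ms2, ms1), ms2 = ms2, ms1 = ms1,
                 stop("unknown level: ", level))
  intersect(want, names(peak_groups))
}

# Plain counting q-values: q(s) = #decoys >= s / #targets >= s, monotonized.
counting_qvalues <- function(target_scores, decoy_scores) {
  nt <- length(target_scores)
  fdr <- vapply(target_scores, function(s)
    sum(decoy_scores >= s) / sum(target_scores >= s), numeric(1))
  o <- order(target_scores)           # ascending: q = running min of FDR
  q <- numeric(nt)
  q[o] <- cummin(fdr[o])
  pmin(q, 1)
}

#' Decoy-null q-value estimation
#'
#' d-scores are standardized so decoys have mean 0 and sd 1. Each target's
#' p-value is the smoothed empirical decoy exceedance
#' `(1 + #decoys >= s) / (1 + n_decoys)`; q-values are the monotonized
#' minimum over thresholds of `pi0 * n_targets * p / #targets passing`.
#' With `pi0_method = "counting"`, the plain counting estimator
#' `#decoys >= s / #targets >= s` is used instead (pi0 fixed at 1).
#'
#' @param d_scores Numeric discriminant scores (targets and decoys).
#' @param is_decoy Logical vector, same length.
#' @param pi0_method `"storey"` (fixed-lambda 0.5 Storey estimator, clipped
#'   to (0, 1]), `"counting"`, or a number in (0, 1] used as fixed pi0.
#' @return Data frame with `d_score`, `p_value`, `q_value` (decoy rows get
#'   `NA` p/q) in the input order, plus attribute `pi0`.
#' @export
compute_qvalues <- function(d_scores, is_decoy, pi0_method = "storey") {
  if (!any(is_decoy)) stop("q-value estimation requires at least one decoy")
  mu <- mean(d_scores[is_decoy])
  sg <- stats::sd(d_scores[is_decoy])
  if (is.na(sg) || sg == 0) sg <- 1
  d <- (d_scores - mu) / sg
  td <- d[!is_decoy]; dd <- d[is_decoy]
  nt <- length(td); nd <- length(dd)
  p <- vapply(td, function(s) (1 + sum(dd >= s)) / (1 + nd), numeric(1))
  if (is.numeric(pi0_method)) {
    pi0 <- pi0_method
    mode <- "fixed"
  } else if (pi0_method == "counting") {
    pi0 <- 1
    mode <- "counting"
  } else if (pi0_method == "storey") {
    lambda <- 0.5
    pi0 <- min(max(mean(p > lambda) / (1 - lambda), 1e-8), 1)
    mode <- "smoothed"
  } else stop("unknown pi0_method")
  if (mode == "counting") {
    q <- counting_qvalues(td, dd)
  } else {
    fdr <- pi0 * nt * p / vapply(td, function(s) sum(td >= s), numeric(1))
    o <- order(td)
    q <- numeric(nt)
    q[o] <- cummin(fdr[o])
    q <- pmin(q, 1)
  }
  out <- data.frame(d_score = d, p_value = NA_real_, q_value = NA_real_)
  out$p_value[!is_decoy] <- p
  out$q_value[!is_decoy] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Combine MS1 and MS2 sub-score matrices
#'
#' With `strategy = "joint"` the MS1 sub-scores are appended to the MS2
#' sub-score matrix before learning; `"ms2-only"` drops the MS1 columns.
#'
#' @param ms1_scores,ms2_scores Data frames over the same peak groups (same
#'   row count and order).
#' @param strategy `"joint"` or `"ms2-only"`.
#' @return Combined score data frame.
#' @export
merge_levels <- function(ms1_scores, ms2_scores, strategy = c("joint", "ms2-only")) {
  strategy <- match.arg(strategy)
  if (strategy == "ms2-only") return(ms2_scores)
  if (is.null(ms1_scores) || ncol(ms1_scores) == 0 || nrow(ms1_scores) == 0)
    stop("joint strategy requires a non-empty MS1 score matrix")
  if (nrow(ms1_scores) != nrow(ms2_scores))
    stop("MS1 and MS2 score matrices cover different peak-group sets")
  cbind(ms2_scores, ms1_scores)
}

#' Score, rank and q-value a peak-group table
#'
#' Learns the discriminant (joint MS1+MS2 by default), computes d-scores
#' for every peak group, re-ranks peak groups within each (run, assay) by
#' d-score, and estimates q-values on the rank-1 peak groups against the
#' rank-1 decoy null.
#'
#' @param peak_groups Table from [extract_peak_groups()].
#' @param params Passed to [learn_discriminant()]; additionally `level`
#'   (`"joint"` default or `"ms2"`) and `pi0_method` (see
#'   [compute_qvalues()]).
#' @param seed Integer seed.
#' @return The table with `d_score`, `rank` (re-assigned), `p_value`,
#'   `q_value` columns; attributes `weights`, `learning` (the learner
#'   result) and `pi0`.
#' @export
score_peak_groups <- function(peak_groups, params = list(), seed = 1) {
  level <- params$level %||% "joint"
  pi0_method <- params$pi0_method %||% "storey"
  params$level <- NULL; params$pi0_method <- NULL
  cols <- default_score_columns(peak_groups, level)
  fit <- learn_discriminant(peak_groups, cols, params, seed)
  d <- as.numeric(as.matrix(peak_groups[, cols, drop = FALSE]) %*% fit$weights)
  peak_groups$d_score <- d
  key <- paste(peak_groups$run_id, peak_groups$group_id, peak_groups$is_decoy)
  peak_groups$rank <- stats::ave(-d, key, FUN = rank)
  top <- peak_groups$rank == 1
  qv <- compute_qvalues(d[top], peak_groups$is_decoy[top], pi0_method)
  peak_groups$d_score[top] <- qv$d_score
  # rescale the non-top d-scores onto the same decoy-standardized scale
  mu <- mean(d[top & peak_groups$is_decoy])
  sg <- stats::sd(d[top & peak_groups$is_decoy])
  if (is.na(sg) || sg == 0) sg <- 1
  peak_groups$d_score[!top] <- (d[!top] - mu) / sg
  peak_groups$p_value <- NA_real_
  peak_groups$q_value <- NA_real_
  peak_groups$p_value[top] <- qv$p_value
  peak_groups$q_value[top] <- qv$q_value
  attr(peak_groups, "weights") <- fit$weights
  attr(peak_groups, "learning") <- fit
  attr(peak_groups, "pi0") <- attr(qv, "pi0")
  peak_groups
}

#' Filter scored results
#'
#' @param results Scored peak-group table.
#' @param q_threshold Keep rows with `q_value <= q_threshold`.
#' @param best_rank_only Keep only the rank-1 peak group per (run, assay).
#' @return Filtered table.
#' @export
filter_results <- function(results, q_threshold = 0.05, best_rank_only = TRUE) {
  out <- results
  if (best_rank_only) out <- out[out$rank == 1, , drop = FALSE]
  out[!is.na(out$q_value) & out$q_value <= q_threshold, , drop = FALSE]
}
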