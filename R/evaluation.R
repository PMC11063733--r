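#' ROC curve and area under it
#'
#' Sweeps every distinct score as a threshold (equal scores grouped, so ties
#' contribute a single diagonal segment) and integrates TPR against FPR by
#' the trapezoidal rule. Equivalent to the Mann-Whitney pair-counting
#' statistic with ties counted one half.
#'
#' @param scores Numeric vector.
#' @param labels Binary (0/1 or logical) vector of the same length.
#' @return A list with `auc` and `points`, a tibble of
#'   `(threshold, fpr, tpr)` rows starting at (0, 0).
#' @export
roc_auc <- function(scores, labels) {
  pool <- check_score_pool(scores, labels)
  npos <- sum(pool$labels)
  nneg <- sum(!pool$labels)
  if (npos == 0 || nneg == 0) {
    rlang::warn("ROC undefined: need at least one positive and one negative")
    return(list(auc = NA_real_,
                points = tibble::tibble(threshold = numeric(),
                                        fpr = numeric(), tpr = numeric())))
  }
  sw <- sweep_thresholds(pool$scores, pool$labels)
  tpr <- c(0, sw$tp / npos)
  fpr <- c(0, sw$fp / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(
    auc = auc,
    points = tibble::tibble(threshold = c(Inf, sw$threshold), fpr = fpr, tpr = tpr)
  )
}

#' Precision-recall curve and area under it
#'
#' Threshold sweep over the distinct scores with step interpolation: the
#' area is the sum of precision times the recall increment at each
#' threshold. With all scores equal this reduces to the positive prevalence.
#'
#' @inheritParams roc_auc
#' @return A list with `aupr` and `points`, a tibble of
#'   `(threshold, recall, precision)` rows.
#' @export
pr_aupr <- function(scores, labels) {
  pool <- check_score_pool(scores, labels)
  npos <- sum(pool$labels)
  if (npos == 0) {
    rlang::warn("PR curve undefined: no positive labels")
    return(list(aupr = NA_real_,
                points = tibble::tibble(threshold = numeric(),
                                        recall = numeric(), precision = numeric())))
  }
  sw <- sweep_thresholds(pool$scores, pool$labels)
  recall <- sw$tp / npos
  precision <- sw$tp / (sw$tp + sw$fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(
    aupr = aupr,
    points = tibble::tibble(threshold = sw$threshold,
                            recall = recall, precision = precision)
  )
}

check_score_pool <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    rlang::abort("scores and labels differ in length")
  }
  if (anyNA(scores) || anyNA(labels)) rlang::abort("scores/labels contain NA")
  list(scores = as.numeric(scores), labels = as.logical(labels))
}

# cumulative TP/FP at the end of each tied-score group, scores descending
sweep_thresholds <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  list(
    threshold = s[ends],
    tp = cumsum(l)[ends],
    fp = cumsum(!l)[ends]
  )
}

#' Confusion-matrix metrics at a fixed score threshold
#'
#' Predicts positive where `score >= threshold` and reports the confusion
#' counts together with accuracy, precision, recall, F1 (the standard
#' harmonic mean `2PR / (P + R)`) and Matthews correlation coefficient
#' (0 whenever any denominator factor vanishes).
#'
#' @inheritParams roc_auc
#' @param threshold Finite score cutoff.
#' @return A one-row tibble with `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `acc`, `precision`, `recall`, `f1`, `mcc`.
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  if (!is.finite(threshold)) rlang::abort("threshold must be finite")
  pool <- check_score_pool(scores, labels)
  pred <- pool$scores >= threshold
  tp <- sum(pred & pool$labels)
  fp <- sum(pred & !pool$labels)
  tn <- sum(!pred & !pool$labels)
  fn <- sum(!pred & pool$labels)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  tibble::tibble(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
                 acc = acc, precision = precision, recall = recall,
                 f1 = f1, mcc = mcc)
}

youden_threshold <- function(roc) {
  pts <- roc$points[is.finite(roc$points$threshold), ]
  pts$threshold[which.max(pts$tpr - pts$fpr)]
}

new_eval_report <- function(scores, labels, config, method, folds) {
  roc <- roc_auc(scores, labels)
  pr <- pr_aupr(scores, labels)
  threshold <- if (config$threshold_mode == "fixed") {
    config$threshold_value
  } else {
    youden_threshold(roc)
  }
  tm <- threshold_metrics(scores, labels, threshold)
  structure(
    list(
      auc = roc$auc, aupr = pr$aupr, acc = tm$acc, mcc = tm$mcc, f1 = tm$f1,
      precision = tm$precision, recall = tm$recall,
      threshold = threshold, roc_points = roc$points, pr_points = pr$points,
      n_positive = sum(as.logical(labels)),
      n_negative = sum(!as.logical(labels)),
      folds = folds, method = method, config = config
    ),
    class = "scplpa_eval"
  )
}

#' @export
print.scplpa_eval <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<scplpa_eval: %s> %d folds, %d positives vs %d negatives\n",
      "  AUC %.4f  AUPR %.4f  ACC %.4f  MCC %.4f  F1 %.4f (threshold %.4g)\n"
    ),
    x$method, x$folds, x$n_positive, x$n_negative,
    x$auc, x$aupr, x$acc, x$mcc, x$f1, x$threshold
  ))
  invisible(x)
}

#' One-row metric summary of an evaluation report
#'
#' @param x An `scplpa_eval`.
#' @param ... Unused.
#' @return A one-row tibble of the five headline metrics plus threshold and
#'   fold count.
#' @export
glance.scplpa_eval <- function(x, ...) {
  tibble::tibble(
    method = x$method, auc = x$auc, aupr = x$aupr, acc = x$acc,
    mcc = x$mcc, f1 = x$f1, threshold = x$threshold, folds = x$folds,
    n_positive = x$n_positive, n_negative = x$n_negative
  )
}

#' Curve points of an evaluation report in long form
#'
#' @param x An `scplpa_eval`.
#' @param ... Unused.
#' @return A tibble with columns `curve` (`"roc"` or `"pr"`), `x`, `y`,
#'   `threshold`.
#' @export
tidy.scplpa_eval <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(curve = "roc", x = x$roc_points$fpr, y = x$roc_points$tpr,
                   threshold = x$roc_points$threshold),
    tibble::tibble(curve = "pr", x = x$pr_points$recall,
                   y = x$pr_points$precision, threshold = x$pr_points$threshold)
  )
}

#' Leave-one-out cross-validation of the pipeline
#'
#' Each known association is zeroed in turn, the propagation and projection
#' stages are re-run on the masked matrix, and the held-out pair's score is
#' recorded as a positive. The negative pool is the set of never-known pairs
#' scored by the model fitted on the complete data, giving the global
#' ranking protocol. By default the similarity matrices (semantic,
#' functional and Gaussian kernel) are computed once from the full data;
#' `config$refresh_gip_per_fold` switches to recomputing the Gaussian
#' kernels inside every fold.
#'
#' @inheritParams run_scplpa
#' @return An `scplpa_eval` report with AUC, AUPR, ACC, MCC, F1, the ROC
#'   and PR curve points, and the threshold used.
#' @export
loocv <- function(assoc, dags = NULL, disease_sim = NULL, mirna_sim = NULL,
                  config = scplpa_config()) {
  assoc <- association_matrix(unclass(assoc))
  MD <- unclass(assoc)
  pos <- which(MD == 1, arr.ind = TRUE)
  if (nrow(pos) < 2) rlang::abort("LOOCV needs at least 2 known associations")

  if (is.null(disease_sim)) {
    if (is.null(dags)) rlang::abort("supply dags or disease_sim")
    disease_sim <- disease_semantic_similarity(dags, config$log_base)
  }
  DD <- align_disease_sim(disease_sim, colnames(MD))
  if (is.null(mirna_sim)) {
    MM <- mirna_functional_similarity(assoc, DD)
  } else {
    MM <- as.matrix(mirna_sim)[rownames(MD), rownames(MD), drop = FALSE]
  }
  full_args <- if (config$refresh_gip_per_fold) {
    list(disease_sim = DD, mirna_sim = MM)
  } else {
    DDf <- integrate_disease(DD, gip_similarity(t(MD)))
    MMf <- integrate_mirna(MM, gip_similarity(MD))
    list(integrated_disease_sim = DDf, integrated_mirna_sim = MMf)
  }
  fit_masked <- function(m) {
    do.call(run_scplpa, c(list(assoc = association_matrix(m), config = config),
                          full_args))
  }
  full_fit <- fit_masked(MD)
  pos_scores <- vapply(seq_len(nrow(pos)), function(k) {
    m <- MD
    m[pos[k, 1], pos[k, 2]] <- 0
    fit <- tryCatch(
      fit_masked(m),
      error = function(e) rlang::abort(sprintf(
        "LOOCV fold %d (miRNA %s, disease %s) failed: %s",
        k, rownames(MD)[pos[k, 1]], colnames(MD)[pos[k, 2]],
        conditionMessage(e)
      ))
    )
    fit$md_star[pos[k, 1], pos[k, 2]]
  }, numeric(1))
  neg_scores <- full_fit$md_star[MD == 0]
  scores <- c(pos_scores, neg_scores)
  labels <- c(rep(1L, length(pos_scores)), rep(0L, length(neg_scores)))
  new_eval_report(scores, labels, config, method = "loocv",
                  folds = nrow(pos))
}

#' Cold-start cross-validation: new miRNAs and isolated diseases
#'
#' One fold per entity on the chosen axis: all of the entity's known
#' associations are removed (simulating a newly discovered miRNA or an
#' isolated disease), the whole pipeline -- including the profile-derived
#' similarities -- is re-run on the masked matrix, and the entity's true
#' associations are ranked against its non-associations. Scores are pooled
#' over entities into a single report. Entities with no known association
#' carry no test signal and are skipped with a message.
#'
#' @inheritParams run_scplpa
#' @param axis `"mirna"` (new-miRNA protocol, rows) or `"disease"`
#'   (isolated-disease protocol, columns).
#' @return An `scplpa_eval` report; `folds` counts the entities evaluated.
#' @export
leave_one_entity_out <- function(assoc, dags = NULL, disease_sim = NULL,
                                 mirna_sim = NULL, config = scplpa_config(),
                                 axis = c("mirna", "disease")) {
  axis <- rlang::arg_match(axis)
  assoc <- association_matrix(unclass(assoc))
  MD <- unclass(assoc)
  n_axis <- if (axis == "mirna") nrow(MD) else ncol(MD)
  if (n_axis < 2) rlang::abort("need at least 2 entities on the chosen axis")

  if (is.null(disease_sim)) {
    if (is.null(dags)) rlang::abort("supply dags or disease_sim")
    disease_sim <- disease_semantic_similarity(dags, config$log_base)
  }
  DD <- align_disease_sim(disease_sim, colnames(MD))
  # the functional similarity emulates external literature knowledge: it is
  # computed once from the full catalogue and held fixed across folds, like
  # the semantic similarity; only the interaction-profile kernels (which
  # depend on the masked matrix) are refreshed inside each fold
  if (is.null(mirna_sim)) {
    mirna_sim <- mirna_functional_similarity(assoc, DD)
  }

  degree <- if (axis == "mirna") rowSums(MD) else colSums(MD)
  skipped <- which(degree == 0)
  if (length(skipped) > 0) {
    rlang::inform(sprintf(
      "skipping %d %s entit%s with no known association",
      length(skipped), axis, if (length(skipped) == 1) "y" else "ies"
    ))
  }
  use <- which(degree > 0)
  scores <- numeric(0)
  labels <- integer(0)
  for (e in use) {
    m <- MD
    if (axis == "mirna") m[e, ] <- 0 else m[, e] <- 0
    fit <- tryCatch(
      run_scplpa(association_matrix(m), disease_sim = DD,
                 mirna_sim = mirna_sim, config = config),
      error = function(err) rlang::abort(sprintf(
        "entity-out fold for %s %s failed: %s", axis,
        if (axis == "mirna") rownames(MD)[e] else colnames(MD)[e],
        conditionMessage(err)
      ))
    )
    if (axis == "mirna") {
      scores <- c(scores, fit$md_star[e, ])
      labels <- c(labels, as.integer(MD[e, ]))
    } else {
      scores <- c(scores, fit$md_star[, e])
      labels <- c(labels, as.integer(MD[, e]))
    }
  }
  new_eval_report(scores, labels, config,
                  method = paste0("entity_loocv_", axis),
                  folds = length(use))
}

#' Sequential conditional parameter sweep
#'
#' Replicates the staged tuning protocol: with `delta = epsilon = 0.5`,
#' sweep the restart weight `alpha = beta` over its grid and keep the AUC
#' argmax; then sweep `delta` with `epsilon = 0.5`; finally sweep `epsilon`.
#' Every grid point is scored by leave-one-out AUC.
#'
#' @inheritParams loocv
#' @param alpha_grid,delta_grid,epsilon_grid Numeric grids (default
#'   `seq(0.1, 0.9, by = 0.1)`).
#' @return A tibble with columns `stage`, `alpha`, `beta`, `delta`,
#'   `epsilon`, `auc`; the selected optimum is stored in the `"best"`
#'   attribute.
#' @export
parameter_sweep <- function(assoc, dags = NULL, disease_sim = NULL,
                            mirna_sim = NULL, config = scplpa_config(),
                            alpha_grid = seq(0.1, 0.9, by = 0.1),
                            delta_grid = seq(0.1, 0.9, by = 0.1),
                            epsilon_grid = seq(0.1, 0.9, by = 0.1)) {
  if (length(alpha_grid) == 0 || length(delta_grid) == 0 ||
      length(epsilon_grid) == 0) {
    rlang::abort("parameter grids must be nonempty")
  }
  if (is.null(disease_sim)) {
    if (is.null(dags)) rlang::abort("supply dags or disease_sim")
    disease_sim <- disease_semantic_similarity(dags, config$log_base)
  }
  auc_at <- function(a, d, e) {
    cfg <- scplpa_config(
      alpha = a, beta = a, delta = d, epsilon = e,
      tolerance = config$tolerance, max_iterations = config$max_iterations,
      log_base = config$log_base,
      normalization_mode = config$normalization_mode,
      refresh_gip_per_fold = config$refresh_gip_per_fold,
      threshold_mode = config$threshold_mode,
      threshold_value = config$threshold_value
    )
    loocv(assoc, disease_sim = disease_sim, mirna_sim = mirna_sim,
          config = cfg)$auc
  }
  rows <- list()
  add_row <- function(stage, a, d, e, auc) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      stage = stage, alpha = a, beta = a, delta = d, epsilon = e, auc = auc
    )
  }
  for (a in alpha_grid) add_row("alpha", a, 0.5, 0.5, auc_at(a, 0.5, 0.5))
  tab <- dplyr::bind_rows(rows)
  best_a <- tab$alpha[which.max(tab$auc)]
  for (d in delta_grid) add_row("delta", best_a, d, 0.5, auc_at(best_a, d, 0.5))
  tab <- dplyr::bind_rows(rows)
  dtab <- tab[tab$stage == "delta", ]
  best_d <- dtab$delta[which.max(dtab$auc)]
  for (e in epsilon_grid) {
    add_row("epsilon", best_a, best_d, e, auc_at(best_a, best_d, e))
  }
  tab <- dplyr::bind_rows(rows)
  etab <- tab[tab$stage == "epsilon", ]
  best_e <- etab$epsilon[which.max(etab$auc)]
  attr(tab, "best") <- list(alpha = best_a, beta = best_a,
                            delta = best_d, epsilon = best_e)
  tab
}
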