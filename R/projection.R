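#' Network consistency projection on the miRNA side
#'
#' Projects each miRNA's similarity vector onto the estimated score vector of
#' each disease: `MDpm(i, j) = MMf[i, ] %*% Fe[, j] / ||Fe[, j]||`, with the
#' Euclidean norm. A disease column of `Fe` that is all zero (possible in
#' cold-start folds) yields a zero column rather than NaN.
#'
#' @param MMf Integrated miRNA similarity, `nm x nm`.
#' @param Fe Estimated score matrix, `nm x nd`.
#' @return An `nm x nd` matrix of projection scores.
#' @export
project_mirna <- function(MMf, Fe) {
  MMf <- as.matrix(MMf)
  Fe <- as.matrix(Fe)
  if (ncol(MMf) != nrow(Fe)) rlang::abort("MMf and Fe shapes are incompatible")
  num <- MMf %*% Fe
  nrm <- sqrt(colSums(Fe^2))
  sweep(num, 2, ifelse(nrm > 0, 1 / nrm, 0), "*")
}

#' Network consistency projection on the disease side
#'
#' Projects each disease's similarity vector onto the estimated score vector
#' of each miRNA: `MDpd(i, j) = DDf[j, ] %*% Fe[i, ] / ||Fe[i, ]||`. The
#' result is emitted in miRNA x disease orientation by default;
#' `orientation = "disease_mirna"` returns the transposed, disease-major
#' form instead.
#'
#' @param DDf Integrated disease similarity, `nd x nd`.
#' @param Fe Estimated score matrix, `nm x nd`.
#' @param orientation Output orientation.
#' @return A projection score matrix (`nm x nd` by default).
#' @export
project_disease <- function(DDf, Fe,
                            orientation = c("mirna_disease", "disease_mirna")) {
  orientation <- rlang::arg_match(orientation)
  DDf <- as.matrix(DDf)
  Fe <- as.matrix(Fe)
  if (ncol(Fe) != nrow(DDf)) rlang::abort("DDf and Fe shapes are incompatible")
  num <- Fe %*% t(DDf)
  nrm <- sqrt(rowSums(Fe^2))
  out <- sweep(num, 1, ifelse(nrm > 0, 1 / nrm, 0), "*")
  colnames(out) <- rownames(DDf)
  if (orientation == "disease_mirna") t(out) else out
}

#' Blend the two projection scores into the final score matrix
#'
#' `MD* = epsilon * MDpm + (1 - epsilon) * MDpd`, both in miRNA x disease
#' orientation.
#'
#' @param md_pm,md_pd Same-shape projection score matrices.
#' @param epsilon Mixing weight in `[0, 1]`; the share of the miRNA-side
#'   projection.
#' @return The final score matrix.
#' @export
combine_projections <- function(md_pm, md_pd, epsilon) {
  if (epsilon < 0 || epsilon > 1) rlang::abort("epsilon must be in [0, 1]")
  md_pm <- as.matrix(md_pm)
  md_pd <- as.matrix(md_pd)
  if (!identical(dim(md_pm), dim(md_pd))) {
    rlang::abort("projection matrices differ in shape")
  }
  epsilon * md_pm + (1 - epsilon) * md_pd
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the pipeline. The defaults are the
#' optimal values from the sequential leave-one-out sweep protocol:
#' `alpha = beta = 0.9` (restart weights of the two label propagations),
#' `delta = 0.9` (share of the miRNA-network propagation in the estimated
#' score), `epsilon = 0.6` (share of the miRNA-side projection in the final
#' score).
#'
#' @param alpha,beta Restart weights in `(0, 1]` for the disease- and
#'   miRNA-network propagations.
#' @param delta,epsilon Mixing weights in `[0, 1]`.
#' @param tolerance Propagation convergence tolerance.
#' @param max_iterations Propagation iteration cap.
#' @param log_base Base of the ancestor information-content logarithm.
#' @param normalization_mode See [normalize_network()].
#' @param refresh_gip_per_fold Recompute the Gaussian kernel similarities
#'   inside every leave-one-out fold (exact but slower); by default they are
#'   computed once from the full matrix.
#' @param threshold_mode `"youden"` (threshold maximizing TPR - FPR on the
#'   ROC) or `"fixed"`.
#' @param threshold_value Threshold used when `threshold_mode = "fixed"`.
#' @param seed Optional integer seed recorded for provenance.
#' @return An object of class `scplpa_config`.
#' @export
scplpa_config <- function(alpha = 0.9, beta = 0.9, delta = 0.9, epsilon = 0.6,
                          tolerance = 1e-6, max_iterations = 1000,
                          log_base = exp(1),
                          normalization_mode = c("degree_sum", "symmetric"),
                          refresh_gip_per_fold = FALSE,
                          threshold_mode = c("youden", "fixed"),
                          threshold_value = 0.5,
                          seed = NULL) {
  normalization_mode <- rlang::arg_match(normalization_mode)
  threshold_mode <- rlang::arg_match(threshold_mode)
  if (alpha <= 0 || alpha > 1 || beta <= 0 || beta > 1) {
    rlang::abort("alpha and beta must be in (0, 1]")
  }
  if (delta < 0 || delta > 1 || epsilon < 0 || epsilon > 1) {
    rlang::abort("delta and epsilon must be in [0, 1]")
  }
  if (tolerance <= 0) rlang::abort("tolerance must be positive")
  structure(
    list(alpha = alpha, beta = beta, delta = delta, epsilon = epsilon,
         tolerance = tolerance, max_iterations = as.integer(max_iterations),
         log_base = log_base, normalization_mode = normalization_mode,
         refresh_gip_per_fold = refresh_gip_per_fold,
         threshold_mode = threshold_mode, threshold_value = threshold_value,
         seed = seed),
    class = "scplpa_config"
  )
}

#' @export
print.scplpa_config <- function(x, ...) {
  cat(sprintf(
    "<scplpa_config> alpha=%.2g beta=%.2g delta=%.2g epsilon=%.2g tol=%.1g norm=%s\n",
    x$alpha, x$beta, x$delta, x$epsilon, x$tolerance, x$normalization_mode
  ))
  invisible(x)
}

align_disease_sim <- function(sim, diseases) {
  sim <- as.matrix(sim)
  missing <- setdiff(diseases, rownames(sim))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "disease similarity does not cover: ", paste(missing, collapse = ", ")
    ))
  }
  sim[diseases, diseases, drop = FALSE]
}

#' Run the full prediction pipeline
#'
#' Executes similarity construction, heterogeneous-network integration,
#' the two label propagations and the consistency projection, returning all
#' intermediate matrices for inspection. Disease semantic similarity is
#' computed from `dags` unless a precomputed `disease_sim` is supplied;
#' miRNA functional similarity is computed from the associations and the
#' disease similarity unless `mirna_sim` is supplied. Expert callers (and
#' the cross-validation harness) may inject fully integrated similarity
#' matrices directly, bypassing the similarity stage.
#'
#' @param assoc An [association_matrix()].
#' @param dags A [disease_dag_set()] (or `NULL` when `disease_sim` or
#'   `integrated_disease_sim` is given).
#' @param disease_sim,mirna_sim Optional precomputed semantic / functional
#'   similarity matrices.
#' @param config An [scplpa_config()].
#' @param integrated_disease_sim,integrated_mirna_sim Optional fully
#'   integrated similarity matrices; when both are given the Gaussian kernel
#'   stage is skipped.
#' @return An object of class `scplpa_result`: list with the final scores
#'   `md_star`, the projections `md_pm` and `md_pd`, the estimated scores
#'   `fe`, the re-oriented propagation fixed points `fd_star` and `fm_star`,
#'   the integrated similarities `ddf` and `mmf`, convergence information
#'   and the configuration used.
#' @export
#' @examples
#' fx <- generate_fixture(fixture_spec(nm = 10, nd = 8, n_blocks = 2, seed = 7))
#' fit <- run_scplpa(fx$assoc, fx$dags)
#' head(tidy(fit))
run_scplpa <- function(assoc, dags = NULL, disease_sim = NULL,
                       mirna_sim = NULL, config = scplpa_config(),
                       integrated_disease_sim = NULL,
                       integrated_mirna_sim = NULL) {
  MD <- unclass(association_matrix(unclass(assoc)))
  if (is.null(integrated_disease_sim) || is.null(integrated_mirna_sim)) {
    if (is.null(disease_sim)) {
      if (is.null(dags)) {
        rlang::abort("supply dags, disease_sim, or integrated similarities")
      }
      disease_sim <- disease_semantic_similarity(dags, config$log_base)
    }
    DD <- align_disease_sim(disease_sim, colnames(MD))
    if (is.null(mirna_sim)) {
      MM <- mirna_functional_similarity(association_matrix(MD), DD)
    } else {
      MM <- as.matrix(mirna_sim)[rownames(MD), rownames(MD), drop = FALSE]
    }
    GD <- gip_similarity(t(MD))
    GM <- gip_similarity(MD)
    DDf <- integrate_disease(DD, GD)
    MMf <- integrate_mirna(MM, GM)
  } else {
    DDf <- as.matrix(integrated_disease_sim)
    MMf <- as.matrix(integrated_mirna_sim)
  }
  DDs <- normalize_network(DDf, config$normalization_mode)
  MMs <- normalize_network(MMf, config$normalization_mode)
  fd <- label_propagate(DDs, t(MD), config$alpha,
                        config$tolerance, config$max_iterations)
  fm <- label_propagate(MMs, MD, config$beta,
                        config$tolerance, config$max_iterations)
  fe <- estimate_scores(fd, fm, config$delta)
  md_pm <- project_mirna(MMf, fe)
  md_pd <- project_disease(DDf, fe)
  md_star <- combine_projections(md_pm, md_pd, config$epsilon)
  dimnames(md_star) <- dimnames(MD)
  structure(
    list(
      md_star = md_star, md_pm = md_pm, md_pd = md_pd, fe = fe,
      fd_star = t(fd$fixed_point), fm_star = fm$fixed_point,
      ddf = DDf, mmf = MMf, assoc = MD, config = config,
      iterations = c(disease = fd$iterations, mirna = fm$iterations),
      converged = fd$converged && fm$converged
    ),
    class = "scplpa_result"
  )
}

#' @export
print.scplpa_result <- function(x, ...) {
  cat(sprintf(
    "<scplpa_result> %d miRNAs x %d diseases; propagation iterations %d/%d (%s)\n",
    nrow(x$md_star), ncol(x$md_star),
    x$iterations[["disease"]], x$iterations[["mirna"]],
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Tidy a fitted pipeline into a ranked candidate tibble
#'
#' @param x An `scplpa_result`.
#' @param ... Unused.
#' @return See [write_predictions()].
#' @export
tidy.scplpa_result <- function(x, ...) {
  write_predictions(x$md_star, known = x$assoc)
}

#' One-row summary of a fitted pipeline
#'
#' @param x An `scplpa_result`.
#' @param ... Unused.
#' @return A one-row tibble with dimensions, known-link count, iteration
#'   counts and convergence flag.
#' @export
glance.scplpa_result <- function(x, ...) {
  tibble::tibble(
    n_mirna = nrow(x$md_star), n_disease = ncol(x$md_star),
    n_known = sum(x$assoc),
    iterations_disease = x$iterations[["disease"]],
    iterations_mirna = x$iterations[["mirna"]],
    converged = x$converged
  )
}
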