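#' Construct a validated similarity matrix
#'
#' All similarity matrices in the pipeline are square, symmetric, have
#' entries in `[0, 1]`, and (for the semantic, functional and Gaussian-kernel
#' kinds) unit diagonal wherever the quantity is defined. The constructor
#' enforces symmetry to within `1e-12` and clamps floating-point spill
#' outside `[0, 1]`.
#'
#' @param values Square numeric matrix with matching row/column names.
#' @param kind One of `"semantic"`, `"functional"`, `"gip"`, `"integrated"`.
#' @return A `similarity_matrix` (base matrix subclass with a `kind`
#'   attribute).
#' @export
similarity_matrix <- function(values,
                              kind = c("semantic", "functional", "gip", "integrated")) {
  kind <- rlang::arg_match(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) rlang::abort("similarity matrix must be square")
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) %||% sprintf("x%d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (!identical(rownames(values), colnames(values))) {
    rlang::abort("row and column names must match")
  }
  if (anyNA(values)) rlang::abort("similarity matrix contains NA")
  if (max(abs(values - t(values))) > 1e-12) {
    rlang::abort("similarity matrix is not symmetric (tolerance 1e-12)")
  }
  if (min(values) < -1e-9 || max(values) > 1 + 1e-9) {
    rlang::abort("similarity entries must lie in [0, 1]")
  }
  values <- pmin(pmax(values, 0), 1)
  structure(values, kind = kind,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "<similarity_matrix: %s> %d x %d, mean off-diagonal %.3f\n",
    attr(x, "kind"), nrow(x), ncol(x),
    mean(unclass(x)[row(x) != col(x)])
  ))
  invisible(x)
}

#' Information-content contribution of ancestor terms
#'
#' Under the information-content view of a disease hierarchy, an ancestor
#' term that annotates few diseases is specific and therefore informative.
#' The contribution of a term is `-log(k / N)` where `k` is the number of
#' disease DAGs whose ancestor set contains the term and `N` is the disease
#' universe size; a term shared by every disease contributes 0.
#'
#' @param dags A [disease_dag_set()].
#' @param log_base Base of the logarithm; natural log by default.
#' @return Named numeric vector of contributions over every term that occurs
#'   in at least one ancestor set.
#' @export
ancestor_contribution <- function(dags, log_base = exp(1)) {
  stopifnot(inherits(dags, "disease_dag_set"))
  if (dags$universe_size < 1) rlang::abort("universe_size must be at least 1")
  counts <- table(unlist(dags$ancestors, use.names = FALSE))
  contr <- -log(as.numeric(counts) / dags$universe_size, base = log_base)
  names(contr) <- names(counts)
  contr
}

#' Semantic value of a disease
#'
#' The semantic value `DV(d)` is the summed contribution of every term in
#' the disease's ancestor set `N(d)` (itself included).
#'
#' @inheritParams ancestor_contribution
#' @param d Character vector of diseases to score; all diseases by default.
#' @param contributions Optional precomputed [ancestor_contribution()].
#' @return Named numeric vector of semantic values.
#' @export
semantic_value <- function(dags, d = NULL, contributions = NULL,
                           log_base = exp(1)) {
  stopifnot(inherits(dags, "disease_dag_set"))
  if (is.null(contributions)) contributions <- ancestor_contribution(dags, log_base)
  if (is.null(d)) d <- dags$diseases
  unknown <- setdiff(d, dags$diseases)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown disease(s): ", paste(unknown, collapse = ", ")))
  }
  vapply(d, function(di) sum(contributions[dags$ancestors[[di]]]), numeric(1))
}

#' Disease semantic similarity from shared ancestors
#'
#' Scores a disease pair by the contribution mass of their shared ancestor
#' terms relative to their combined semantic values:
#' `DD(i, j) = sum over shared terms t of 2 * D(t) / (DV(i) + DV(j))`.
#' Pairs whose DAGs contain only universal (zero-contribution) terms are
#' undefined and set to 0 with a warning.
#'
#' @inheritParams ancestor_contribution
#' @return A [similarity_matrix()] of kind `"semantic"` over
#'   `dags$diseases`.
#' @export
disease_semantic_similarity <- function(dags, log_base = exp(1)) {
  contr <- ancestor_contribution(dags, log_base)
  dv <- semantic_value(dags, contributions = contr)
  ds <- dags$diseases
  n <- length(ds)
  out <- matrix(0, n, n, dimnames = list(ds, ds))
  degenerate <- FALSE
  for (i in seq_len(n)) {
    for (j in i:n) {
      den <- dv[i] + dv[j]
      if (den <= 0) {
        degenerate <- TRUE
        val <- 0
      } else if (i == j) {
        val <- 1
      } else {
        shared <- intersect(dags$ancestors[[i]], dags$ancestors[[j]])
        val <- 2 * sum(contr[shared]) / den
      }
      out[i, j] <- out[j, i] <- val
    }
  }
  if (degenerate) {
    rlang::warn("some disease pairs have zero combined semantic value; similarity set to 0")
  }
  similarity_matrix(out, kind = "semantic")
}

#' Association of a disease with a disease set
#'
#' The association between disease `d` and a nonempty disease set is the
#' best semantic match: `S(d, D) = max over t in D of DD(d, t)`.
#'
#' @param d A disease name present in `DD`.
#' @param disease_set Nonempty character vector of diseases present in `DD`.
#' @param DD Disease semantic similarity matrix.
#' @return A single number in `[0, 1]`.
#' @export
set_association <- function(d, disease_set, DD) {
  if (length(disease_set) == 0) rlang::abort("disease_set must be nonempty")
  if (!d %in% rownames(DD)) rlang::abort(paste0("unknown disease: ", d))
  missing <- setdiff(disease_set, colnames(DD))
  if (length(missing) > 0) {
    rlang::abort(paste0("disease_set not covered by DD: ", paste(missing, collapse = ", ")))
  }
  max(DD[d, disease_set])
}

#' miRNA functional similarity from associated-disease sets
#'
#' Two miRNAs are functionally similar when the diseases they are associated
#' with are semantically similar. With `D(mi)` the disease set of miRNA `i`
#' (sizes `m` and `n`):
#' `MM(i, j) = (sum_{t in D(mi)} S(t, D(mj)) + sum_{t in D(mj)} S(t, D(mi))) / (m + n)`.
#' miRNAs with no associated diseases (which arise inside cross-validation
#' folds) get an all-zero row/column apart from a unit diagonal, so the
#' Gaussian-kernel fallback takes over at integration.
#'
#' @param assoc An [association_matrix()].
#' @param DD Disease semantic similarity covering all diseases in `assoc`.
#' @return A [similarity_matrix()] of kind `"functional"` over the miRNAs.
#' @export
mirna_functional_similarity <- function(assoc, DD) {
  A <- unclass(assoc)
  if (!all(colnames(A) %in% rownames(DD))) {
    rlang::abort("DD does not cover every disease in the association matrix")
  }
  DDm <- unclass(DD)[colnames(A), colnames(A), drop = FALSE]
  nm <- nrow(A)
  dsets <- lapply(seq_len(nm), function(i) which(A[i, ] == 1))
  # best-match of every disease against each miRNA's disease set
  best <- matrix(0, ncol(A), nm, dimnames = list(colnames(A), rownames(A)))
  for (j in seq_len(nm)) {
    if (length(dsets[[j]]) > 0) {
      best[, j] <- apply(DDm[, dsets[[j]], drop = FALSE], 1, max)
    }
  }
  out <- matrix(0, nm, nm, dimnames = list(rownames(A), rownames(A)))
  for (i in seq_len(nm)) {
    for (j in i:nm) {
      m <- length(dsets[[i]])
      n <- length(dsets[[j]])
      if (m == 0 || n == 0) next
      out[i, j] <- out[j, i] <-
        (sum(best[dsets[[i]], j]) + sum(best[dsets[[j]], i])) / (m + n)
    }
  }
  diag(out) <- 1
  similarity_matrix(out, kind = "functional")
}

#' Gaussian interaction profile kernel similarity
#'
#' Entities are compared through their binary interaction profiles (a
#' disease's profile is its column of the association matrix, a miRNA's its
#' row). The kernel bandwidth is set from the data as the reciprocal mean
#' squared profile norm, `gamma = 1 / mean(||profile_i||^2)`, and
#' `K(i, j) = exp(-gamma * ||profile_i - profile_j||^2)`.
#'
#' @param profiles Numeric matrix, one entity per row.
#' @return A [similarity_matrix()] of kind `"gip"` with the bandwidth stored
#'   in attribute `"gamma"`.
#' @export
gip_similarity <- function(profiles) {
  P <- as.matrix(profiles)
  if (is.null(rownames(P))) rownames(P) <- sprintf("x%d", seq_len(nrow(P)))
  sq <- rowSums(P^2)
  if (all(sq == 0)) {
    rlang::abort("all interaction profiles are zero; kernel bandwidth undefined")
  }
  gamma <- 1 / mean(sq)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2 <- pmax(d2, 0)
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(P), rownames(P))
  out <- similarity_matrix(K, kind = "gip")
  attr(out, "gamma") <- gamma
  out
}

check_same_labels <- function(a, b) {
  if (!identical(dim(a), dim(b))) rlang::abort("similarity matrices differ in shape")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    rlang::abort("similarity matrices differ in labels")
  }
}

#' Integrate semantic and kernel disease similarity
#'
#' The heterogeneous disease similarity is the elementwise mean of the
#' semantic similarity and the Gaussian kernel similarity,
#' `DDf = (DD + GD) / 2`, which fills in the zeros the sparse hierarchy
#' leaves behind.
#'
#' @param DD,GD Same-shape disease similarity matrices.
#' @return A [similarity_matrix()] of kind `"integrated"`.
#' @export
integrate_disease <- function(DD, GD) {
  check_same_labels(DD, GD)
  similarity_matrix((unclass(DD) + unclass(GD)) / 2, kind = "integrated")
}

#' Integrate functional and kernel miRNA similarity
#'
#' The heterogeneous miRNA similarity keeps the functional value where it is
#' informative and falls back on the Gaussian kernel where the functional
#' similarity is exactly 0:
#' `MMf(i, j) = MM(i, j)` if nonzero, else `GM(i, j)`.
#'
#' @param MM,GM Same-shape miRNA similarity matrices.
#' @return A [similarity_matrix()] of kind `"integrated"`.
#' @export
integrate_mirna <- function(MM, GM) {
  check_same_labels(MM, GM)
  M <- unclass(MM)
  out <- ifelse(M != 0, M, unclass(GM))
  dimnames(out) <- dimnames(M)
  similarity_matrix(out, kind = "integrated")
}
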