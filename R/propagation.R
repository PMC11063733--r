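#' Normalize a similarity network for label propagation
#'
#' The default `"degree_sum"` mode divides each entry by the sum of its row
#' and column degrees, `W*(i, j) = W(i, j) / (rowsum_i + colsum_j)` (0 where
#' the denominator is 0). For symmetric nonnegative `W` this guarantees every
#' row sum is at most 1, hence spectral radius at most 1 and convergence of
#' the propagation for any restart weight above 0. The `"symmetric"` mode is
#' the usual graph-Laplacian style `D^{-1/2} W D^{-1/2}`.
#'
#' @param W Nonnegative square matrix (usually a [similarity_matrix()]).
#' @param mode `"degree_sum"` (default) or `"symmetric"`.
#' @return The normalized matrix, with attribute `"normalization_mode"`.
#' @export
normalize_network <- function(W, mode = c("degree_sum", "symmetric")) {
  mode <- rlang::arg_match(mode)
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) rlang::abort("network matrix must be square")
  if (anyNA(W) || min(W) < 0) rlang::abort("network matrix must be nonnegative")
  rs <- rowSums(W)
  if (mode == "degree_sum") {
    den <- outer(rs, colSums(W), "+")
    out <- ifelse(den > 0, W / den, 0)
  } else {
    s <- ifelse(rs > 0, 1 / sqrt(rs), 0)
    out <- W * (s %o% s)
  }
  dimnames(out) <- dimnames(W)
  attr(out, "normalization_mode") <- mode
  out
}

#' Label propagation to a fixed point
#'
#' Diffuses the label matrix `Y` over the normalized network `Wstar` by
#' iterating `F_{t+1} = (1 - weight) * Wstar %*% F_t + weight * Y` from
#' `F_0 = Y` until the maximum absolute elementwise change drops below
#' `tolerance`. `weight` is the restart probability: the share of the
#' original label information re-injected at every step. For row sums of
#' `Wstar` at most 1 the iteration contracts and converges to the linear
#' fixed point `weight * solve(I - (1 - weight) * Wstar) %*% Y`.
#'
#' @param Wstar Square normalized network, `n x n`.
#' @param Y Label matrix with `n` rows.
#' @param weight Restart weight in `(0, 1]`.
#' @param tolerance Convergence tolerance on the max-abs change.
#' @param max_iterations Iteration cap; hitting it flags non-convergence.
#' @return A `propagation_result`: list with `fixed_point`, `iterations`,
#'   `residual`, `converged`.
#' @export
label_propagate <- function(Wstar, Y, weight, tolerance = 1e-6,
                            max_iterations = 1000) {
  Wstar <- as.matrix(Wstar)
  Y <- as.matrix(Y)
  if (nrow(Wstar) != ncol(Wstar)) rlang::abort("Wstar must be square")
  if (nrow(Y) != nrow(Wstar)) rlang::abort("Y rows must match Wstar dimension")
  if (weight <= 0 || weight > 1) rlang::abort("weight must be in (0, 1]")
  f <- Y
  res <- Inf
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    f_new <- (1 - weight) * (Wstar %*% f) + weight * Y
    res <- max(abs(f_new - f))
    f <- f_new
    if (res < tolerance) break
  }
  converged <- res < tolerance
  if (!converged) {
    rlang::warn(sprintf(
      "label propagation did not converge in %d iterations (residual %.3g)",
      max_iterations, res
    ))
  }
  structure(
    list(fixed_point = f, iterations = iter, residual = res,
         converged = converged, weight = weight, tolerance = tolerance),
    class = "propagation_result"
  )
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf(
    "<propagation_result> %d x %d, %d iterations, residual %.3g (%s)\n",
    nrow(x$fixed_point), ncol(x$fixed_point), x$iterations, x$residual,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Combine the two propagation results into estimated scores
#'
#' The disease-network propagation works on `t(MD)` (diseases on the rows)
#' and the miRNA-network propagation on `MD`; the estimated association
#' score re-orients the former and takes the convex combination
#' `Fe = (1 - delta) * t(FD) + delta * FM`, all in miRNA x disease
#' orientation.
#'
#' @param fd Disease-network [label_propagate()] result (or `nd x nm`
#'   matrix).
#' @param fm miRNA-network result (or `nm x nd` matrix).
#' @param delta Mixing weight in `[0, 1]`; the share of the miRNA-network
#'   result.
#' @return An `nm x nd` numeric matrix of estimated scores.
#' @export
estimate_scores <- function(fd, fm, delta) {
  if (inherits(fd, "propagation_result")) fd <- fd$fixed_point
  if (inherits(fm, "propagation_result")) fm <- fm$fixed_point
  if (delta < 0 || delta > 1) rlang::abort("delta must be in [0, 1]")
  fdt <- t(as.matrix(fd))
  fm <- as.matrix(fm)
  if (!identical(dim(fdt), dim(fm))) {
    rlang::abort("fd (transposed) and fm have incompatible shapes")
  }
  (1 - delta) * fdt + delta * fm
}
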