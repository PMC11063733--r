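#' Specification of a synthetic benchmark fixture
#'
#' Describes a block-structured miRNA-disease benchmark: miRNAs and
#' diseases are partitioned into aligned blocks, a pair inside a block is
#' linked with `within_block_prob` and across blocks with
#' `cross_block_prob`, and each disease block carries its own rooted
#' ancestor tree so that semantically similar diseases share miRNAs -- the
#' structural assumption the predictor exploits. The defaults (40 miRNAs,
#' 25 diseases, 4 blocks, link probabilities 0.6 / 0.03) give a sparse
#' matrix whose density is close to real association catalogues while
#' keeping full leave-one-out runs fast.
#'
#' @param nm,nd Numbers of miRNAs and diseases.
#' @param n_blocks Number of planted blocks (at most `min(nm, nd)`).
#' @param within_block_prob,cross_block_prob Link probabilities inside and
#'   across blocks.
#' @param dag_depth Depth of each block's ancestor tree below its root.
#' @param extra_edge_prob Probability that a disease gains one extra parent
#'   higher up in its own block, creating non-tree DAGs.
#' @param seed Integer seed; every generator draw is a deterministic
#'   function of it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(nm = 40, nd = 25, n_blocks = 4,
                         within_block_prob = 0.6, cross_block_prob = 0.03,
                         dag_depth = 3, extra_edge_prob = 0.1, seed = 1) {
  if (nm < n_blocks || nd < n_blocks) {
    rlang::abort("nm and nd must be at least n_blocks")
  }
  probs <- c(within_block_prob, cross_block_prob, extra_edge_prob)
  if (any(probs < 0 | probs > 1)) rlang::abort("probabilities must be in [0, 1]")
  if (dag_depth < 1) rlang::abort("dag_depth must be at least 1")
  structure(
    list(nm = as.integer(nm), nd = as.integer(nd),
         n_blocks = as.integer(n_blocks),
         within_block_prob = within_block_prob,
         cross_block_prob = cross_block_prob,
         dag_depth = as.integer(dag_depth),
         extra_edge_prob = extra_edge_prob,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

block_ids <- function(n, k) {
  sort(rep_len(seq_len(k), n))
}

fixture_names <- function(prefix, n) {
  sprintf("%s%03d", prefix, seq_len(n))
}

#' Generate a block-aligned disease DAG forest
#'
#' Each disease block gets a rooted tree: a non-disease root term, diseases
#' assigned round-robin to depths `1..dag_depth`, every disease parented by
#' a node one level up in the same block, plus (with probability
#' `extra_edge_prob`) one extra parent strictly higher in the block --
#' acyclic by construction. Blocks share no terms, so semantic similarity
#' is zero across blocks and positive within.
#'
#' @param spec A [fixture_spec()].
#' @return A [disease_dag_set()] over all `nd` diseases with
#'   `universe_size = nd`.
#' @export
generate_dag_forest <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  dn <- fixture_names("d", spec$nd)
  db <- block_ids(spec$nd, spec$n_blocks)
  withr::with_seed(spec$seed + 1L, {
    children <- character(0)
    parents <- character(0)
    for (b in seq_len(spec$n_blocks)) {
      ds <- dn[db == b]
      root <- sprintf("blockroot%02d", b)
      depth <- rep_len(seq_len(spec$dag_depth), length(ds))
      for (i in seq_along(ds)) {
        up <- if (depth[i] == 1) root else {
          cand <- ds[depth == depth[i] - 1]
          cand[sample.int(length(cand), 1)]
        }
        children <- c(children, ds[i])
        parents <- c(parents, up)
        shallower <- c(root, ds[depth < depth[i]])
        shallower <- setdiff(shallower, up)
        if (length(shallower) > 0 &&
            stats::runif(1) < spec$extra_edge_prob) {
          children <- c(children, ds[i])
          parents <- c(parents, shallower[sample.int(length(shallower), 1)])
        }
      }
    }
    disease_dag_set(
      tibble::tibble(child = children, parent = parents),
      diseases = dn, universe_size = spec$nd
    )
  })
}

#' Generate a block-structured binary association matrix
#'
#' Links are independent Bernoulli draws at the within/cross-block
#' probability. An all-zero row or column is redrawn once; if it comes up
#' empty again it is kept (exercising the zero-degree guards) and reported.
#'
#' @param spec A [fixture_spec()].
#' @return An [association_matrix()] of shape `nm x nd`.
#' @export
generate_associations <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  mn <- fixture_names("m", spec$nm)
  dn <- fixture_names("d", spec$nd)
  mb <- block_ids(spec$nm, spec$n_blocks)
  db <- block_ids(spec$nd, spec$n_blocks)
  p <- ifelse(outer(mb, db, "=="), spec$within_block_prob,
              spec$cross_block_prob)
  withr::with_seed(spec$seed, {
    A <- matrix(stats::rbinom(length(p), 1, p), spec$nm, spec$nd)
    for (i in which(rowSums(A) == 0)) {
      A[i, ] <- stats::rbinom(spec$nd, 1, p[i, ])
    }
    for (j in which(colSums(A) == 0)) {
      A[, j] <- stats::rbinom(spec$nm, 1, p[, j])
    }
    empty <- sum(rowSums(A) == 0) + sum(colSums(A) == 0)
    if (empty > 0) {
      rlang::inform(sprintf(
        "%d all-zero row(s)/column(s) remain after one resample", empty
      ))
    }
    dimnames(A) <- list(mn, dn)
    association_matrix(A)
  })
}

#' Generate a complete synthetic fixture
#'
#' Couples [generate_associations()] and [generate_dag_forest()] on the
#' same block partition, so that diseases sharing ancestor terms also share
#' associated miRNAs.
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `assoc`, `dags`, and the `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  list(
    assoc = generate_associations(spec),
    dags = generate_dag_forest(spec),
    spec = spec
  )
}
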