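# Small hand-built fixtures shared across test files.

# three diseases under one root: chains A -> R, B -> R, C standalone
three_disease_dags <- function() {
  disease_dag_set(
    tibble::tibble(child = c("A", "B"), parent = c("R", "R")),
    diseases = c("A", "B", "C"),
    universe_size = 3
  )
}

# two fully linked 2x2 blocks, no cross links
two_block_assoc <- function() {
  m <- matrix(0, 4, 4, dimnames = list(
    c("m1", "m2", "m3", "m4"), c("d1", "d2", "d3", "d4")
  ))
  m[1:2, 1:2] <- 1
  m[3:4, 3:4] <- 1
  association_matrix(m)
}

# DAGs matching the two blocks of two_block_assoc()
two_block_dags <- function() {
  disease_dag_set(
    tibble::tibble(
      child = c("d1", "d2", "d3", "d4"),
      parent = c("r1", "r1", "r2", "r2")
    ),
    diseases = c("d1", "d2", "d3", "d4"),
    universe_size = 4
  )
}

random_similarity <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(sprintf("x%d", 1:n), sprintf("x%d", 1:n))
    m
  })
}

random_assoc <- function(nm, nd, density = 0.3, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      m <- matrix(stats::rbinom(nm * nd, 1, density), nm, nd,
                  dimnames = list(sprintf("m%d", 1:nm), sprintf("d%d", 1:nd)))
      if (sum(m) >= 2 && any(m == 0)) break
    }
    association_matrix(m)
  })
}
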