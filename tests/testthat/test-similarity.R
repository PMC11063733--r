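test_that("ancestor contributions follow the information-content form", {
  dags <- three_disease_dags()
  contr <- ancestor_contribution(dags)
  # R appears in 2 of 3 DAGs, each leaf in exactly 1
  expect_equal(contr[["R"]], -log(2 / 3))
  expect_equal(contr[["A"]], log(3))
  expect_equal(contr[["C"]], log(3))

  # a term shared by every DAG contributes zero
  all_shared <- disease_dag_set(
    tibble::tibble(child = c("A", "B"), parent = c("R", "R")),
    diseases = c("A", "B")
  )
  expect_equal(ancestor_contribution(all_shared)[["R"]], 0)

  # base option rescales: log2 of a 1-in-4 term is 2
  four <- disease_dag_set(
    tibble::tibble(child = "A", parent = "R"),
    diseases = c("A", "B", "C", "D")
  )
  expect_equal(ancestor_contribution(four, log_base = 2)[["A"]], 2)
})

test_that("semantic values sum contributions over the ancestor set", {
  dags <- three_disease_dags()
  contr <- ancestor_contribution(dags)
  dv <- semantic_value(dags)
  expect_equal(dv[["C"]], log(3)) # singleton DAG
  expect_equal(dv[["A"]], contr[["A"]] + contr[["R"]])
  # brute-force per-term enumeration agrees
  manual <- sum(vapply(dags$ancestors$B, function(t) contr[[t]], numeric(1)))
  expect_equal(dv[["B"]], manual)
  expect_error(semantic_value(dags, d = "nope"), "unknown")
})

test_that("disease semantic similarity matches the nested-loop oracle", {
  dags <- three_disease_dags()
  DD <- disease_semantic_similarity(dags)
  expect_equal(unclass(DD), oracle_semantic_dd(dags), ignore_attr = TRUE)
  expect_equal(diag(unclass(DD)), rep(1, 3), ignore_attr = TRUE)
  expect_equal(DD["A", "C"], 0) # disjoint ancestor sets
  expect_gt(DD["A", "B"], 0)    # shared root

  # random DAG forests: exact agreement with the oracle
  for (seed in 1:10) {
    spec <- fixture_spec(nm = 4, nd = 3 + (seed %% 8), n_blocks = 2,
                         dag_depth = 1 + (seed %% 3), seed = seed)
    dg <- generate_dag_forest(spec)
    got <- disease_semantic_similarity(dg)
    expect_equal(unclass(got), oracle_semantic_dd(dg),
                 tolerance = 1e-14, ignore_attr = TRUE)
  }
})

test_that("zero combined semantic value yields 0 with a warning", {
  both_universal <- disease_dag_set(
    tibble::tibble(child = c("A", "B"), parent = c("B", "R"))[0, ],
    diseases = c("A", "B"), universe_size = 1
  )
  # universe 1 with singleton DAGs: every term is in 1/1 DAGs, contribution 0
  expect_warning(
    DD <- disease_semantic_similarity(both_universal),
    "zero combined semantic value"
  )
  expect_true(all(unclass(DD) == 0))
})

test_that("set association is the best semantic match", {
  dags <- three_disease_dags()
  DD <- disease_semantic_similarity(dags)
  expect_equal(set_association("A", c("A", "C"), DD), 1)
  expect_equal(set_association("A", "C", DD), 0)
  # exhaustive scan agrees on a random instance
  S <- random_similarity(5, seed = 3)
  expect_equal(set_association("x1", c("x3", "x4"), S),
               max(S["x1", "x3"], S["x1", "x4"]))
  expect_error(set_association("A", character(0), DD), "nonempty")
})

test_that("miRNA functional similarity matches the exhaustive-loop oracle", {
  dags <- three_disease_dags()
  DD <- unclass(disease_semantic_similarity(dags))
  A <- association_matrix(matrix(
    c(1, 1, 0,   # m1: {A, B}
      0, 0, 1),  # m2: {C}
    nrow = 2, byrow = TRUE,
    dimnames = list(c("m1", "m2"), c("A", "B", "C"))
  ))
  MM <- mirna_functional_similarity(A, DD)
  expect_equal(unclass(MM), oracle_functional_mm(A, DD), ignore_attr = TRUE)
  expect_equal(MM["m1", "m1"], 1)
  expect_equal(MM["m1", "m2"], 0) # all cross-similarities are 0

  # random instances: exact agreement
  for (seed in 1:10) {
    spec <- fixture_spec(nm = 2 + (seed %% 7), nd = 3 + (seed %% 6),
                         n_blocks = 2, seed = 100 + seed)
    fx <- generate_fixture(spec)
    DDr <- unclass(disease_semantic_similarity(fx$dags))
    got <- mirna_functional_similarity(fx$assoc, DDr)
    expect_equal(unclass(got), oracle_functional_mm(fx$assoc, DDr),
                 tolerance = 1e-14, ignore_attr = TRUE)
  }
})

test_that("miRNAs with no diseases get zero similarity except unit diagonal", {
  dags <- three_disease_dags()
  DD <- unclass(disease_semantic_similarity(dags))
  A <- association_matrix(matrix(
    c(1, 1, 0,
      0, 0, 0),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("m1", "m2"), c("A", "B", "C"))
  ))
  MM <- mirna_functional_similarity(A, DD)
  expect_equal(MM["m2", "m1"], 0)
  expect_equal(MM["m2", "m2"], 1)
})

test_that("Gaussian profile kernel matches direct arithmetic", {
  P <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  K <- gip_similarity(P)
  expect_equal(attr(K, "gamma"), 1) # mean squared norm is 1
  expect_equal(K["a", "b"], exp(-2))
  expect_equal(diag(unclass(K)), c(1, 1), ignore_attr = TRUE)

  # identical profiles are fully similar; K = 1 only for identical profiles
  P2 <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 1, 1))
  K2 <- gip_similarity(P2)
  expect_equal(K2["a", "b"], 1)
  expect_lt(K2["a", "c"], 1)

  expect_error(gip_similarity(matrix(0, 3, 3)), "zero")
})

test_that("permuting entities permutes the kernel identically", {
  A <- unclass(random_assoc(7, 5, seed = 21))
  K <- unclass(gip_similarity(A))
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  Kp <- unclass(gip_similarity(A[perm, ]))
  expect_equal(Kp, K[perm, perm], ignore_attr = TRUE)
})

test_that("integration follows the mean / fallback rules", {
  DD <- random_similarity(4, seed = 5)
  GD <- random_similarity(4, seed = 6)
  DDf <- integrate_disease(DD, GD)
  expect_equal(unclass(DDf), (DD + GD) / 2, ignore_attr = TRUE)
  expect_equal(unclass(integrate_disease(DD, DD)), DD, ignore_attr = TRUE)

  MM <- random_similarity(4, seed = 7)
  MM[1, 2] <- MM[2, 1] <- 0
  GM <- random_similarity(4, seed = 8)
  MMf <- integrate_mirna(MM, GM)
  expect_equal(MMf[1, 2], GM[1, 2]) # fallback branch
  expect_equal(MMf[3, 4], MM[3, 4]) # functional value kept
  # all-zero off-diagonal functional similarity: full fallback
  Z <- diag(4)
  dimnames(Z) <- dimnames(MM)
  MMz <- unclass(integrate_mirna(Z, GM))
  off <- row(Z) != col(Z)
  expect_equal(MMz[off], GM[off])

  expect_error(integrate_disease(DD, random_similarity(5, seed = 9)), "shape")
})

test_that("all similarity outputs are symmetric, unit-diagonal, in [0, 1]", {
  fx <- generate_fixture(fixture_spec(nm = 12, nd = 9, n_blocks = 3, seed = 42))
  DD <- disease_semantic_similarity(fx$dags)
  MM <- mirna_functional_similarity(fx$assoc, DD)
  GD <- gip_similarity(t(unclass(fx$assoc)))
  GM <- gip_similarity(unclass(fx$assoc))
  for (S in list(DD, MM, GD, GM,
                 integrate_disease(DD, GD), integrate_mirna(MM, GM))) {
    m <- unclass(S)
    expect_lte(max(abs(m - t(m))), 1e-12)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(diag(m), rep(1, nrow(m)), ignore_attr = TRUE)
  }
})
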