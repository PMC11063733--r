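test_that("trapezoidal AUC equals the Mann-Whitney pair-count oracle", {
  # perfect and anti-perfect separation
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0))$auc, 0)
  # tied instance from the oracle
  s <- c(0.9, 0.8, 0.8, 0.6, 0.5, 0.4)
  l <- c(1, 1, 0, 1, 0, 0)
  expect_equal(roc_auc(s, l)$auc, oracle_auc_mw(s, l))
  # constant scores carry no information
  expect_equal(roc_auc(rep(1, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  # random instances, exact agreement
  for (seed in 1:25) {
    n <- 5 + (seed %% 30)
    withr::with_seed(seed, {
      s <- round(stats::runif(n), 2) # rounding forces ties
      l <- stats::rbinom(n, 1, 0.4)
    })
    if (sum(l) == 0 || sum(l) == n) next
    expect_equal(roc_auc(s, l)$auc, oracle_auc_mw(s, l), tolerance = 1e-14)
  }
  expect_warning(out <- roc_auc(1:3, c(1, 1, 1)), "undefined")
  expect_true(is.na(out$auc))
})

test_that("AUPR matches threshold enumeration and prevalence limits", {
  expect_equal(pr_aupr(c(3, 4, 1, 2), c(1, 1, 0, 0))$aupr, 1)
  # all scores tied: area is the positive prevalence
  expect_equal(pr_aupr(rep(0.5, 8), c(1, 0, 0, 0, 1, 0, 0, 0))$aupr, 0.25)
  for (seed in 1:15) {
    withr::with_seed(seed, {
      s <- round(stats::runif(10), 1)
      l <- stats::rbinom(10, 1, 0.3)
    })
    if (sum(l) == 0) next
    expect_equal(pr_aupr(s, l)$aupr, oracle_aupr_enum(s, l), tolerance = 1e-14)
  }
  expect_warning(out <- pr_aupr(1:3, c(0, 0, 0)), "undefined")
  expect_true(is.na(out$aupr))
})

test_that("ranking metrics are invariant to strictly monotone transforms", {
  withr::with_seed(99, {
    s <- stats::runif(40)
    l <- stats::rbinom(40, 1, 0.3)
  })
  expect_equal(roc_auc(s^3, l)$auc, roc_auc(s, l)$auc)
  expect_equal(pr_aupr(s^3, l)$aupr, pr_aupr(s, l)$aupr)
})

test_that("confusion metrics match direct formula evaluation", {
  # balanced confusion: TP=FP=TN=FN=1
  m <- threshold_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0), 0.5)
  expect_equal(m$acc, 0.5)
  expect_equal(m$mcc, 0)
  expect_equal(m$f1, 0.5)
  # perfect classification
  p <- threshold_metrics(c(0.9, 0.8, 0.2), c(1, 1, 0), 0.5)
  expect_equal(c(p$acc, p$mcc, p$f1), c(1, 1, 1))
  # TP=2, FP=1, TN=3, FN=0 against scalar arithmetic
  q <- threshold_metrics(c(.9, .8, .7, .3, .2, .1), c(1, 1, 0, 0, 0, 0), 0.5)
  expect_equal(unlist(q[c("tp", "fp", "tn", "fn")]),
               c(tp = 2, fp = 1, tn = 3, fn = 0))
  expect_equal(q$acc, 5 / 6)
  prec <- 2 / 3; rec <- 1
  expect_equal(q$f1, 2 * prec * rec / (prec + rec))
  expect_equal(q$mcc, (2 * 3 - 1 * 0) / sqrt(3 * 2 * 4 * 3))
  # degenerate denominator: MCC defined as 0
  z <- threshold_metrics(c(0.9, 0.8), c(1, 1), 0.5)
  expect_equal(z$mcc, 0)
  expect_error(threshold_metrics(1:3, c(1, 0, 1), Inf), "finite")
})

test_that("MCC is centred at zero under label permutation", {
  withr::with_seed(7, {
    s <- stats::runif(60)
    l <- stats::rbinom(60, 1, 0.4)
    mccs <- vapply(1:100, function(i) {
      threshold_metrics(s, sample(l), 0.5)$mcc
    }, numeric(1))
  })
  se <- stats::sd(mccs) / sqrt(length(mccs))
  expect_lt(abs(mean(mccs)), 3 * se + 1e-12)
})

test_that("LOOCV recovers held-out links on a separable block fixture", {
  ev <- loocv(two_block_assoc(), two_block_dags())
  expect_equal(ev$auc, 1)
  expect_equal(ev$folds, 8)
  expect_s3_class(glance(ev), "tbl_df")
  # determinism: identical report on rerun
  ev2 <- loocv(two_block_assoc(), two_block_dags())
  expect_identical(glance(ev), glance(ev2))
  expect_identical(ev$roc_points, ev2$roc_points)
  expect_error(
    loocv(association_matrix(matrix(c(1, 0), 1, 2,
                                    dimnames = list("m1", c("d1", "d2")))),
          two_block_dags()),
    "at least 2"
  )
})

test_that("per-fold kernel refresh changes scores but keeps the protocol", {
  fx <- generate_fixture(fixture_spec(nm = 10, nd = 8, n_blocks = 2, seed = 3))
  ev_fast <- loocv(fx$assoc, fx$dags)
  ev_exact <- loocv(fx$assoc, fx$dags,
                    config = scplpa_config(refresh_gip_per_fold = TRUE))
  expect_equal(ev_fast$folds, ev_exact$folds)
  expect_true(is.finite(ev_exact$auc))
})

test_that("entity-out cross-validation handles cold starts", {
  fx <- generate_fixture(fixture_spec(nm = 12, nd = 8, n_blocks = 2, seed = 5))
  ev_m <- leave_one_entity_out(fx$assoc, fx$dags, axis = "mirna")
  ev_d <- leave_one_entity_out(fx$assoc, fx$dags, axis = "disease")
  expect_true(ev_m$auc > 0.5 && ev_d$auc > 0.5)
  expect_lte(ev_m$folds, 12)
  expect_lte(ev_d$folds, 8)

  # a zero-degree entity is skipped with a message
  m <- unclass(fx$assoc)
  m[3, ] <- 0
  expect_message(
    ev_skip <- leave_one_entity_out(association_matrix(m), fx$dags,
                                    axis = "mirna"),
    "skipping"
  )
  expect_equal(ev_skip$folds, 11)
  expect_error(
    leave_one_entity_out(
      association_matrix(matrix(1, 1, 2, dimnames = list("m1", c("d1", "d2")))),
      fx$dags, axis = "mirna"
    ),
    "at least 2"
  )
})

test_that("scores are transpose-symmetric on a transpose-symmetric problem", {
  # symmetric associations, a shared similarity on both sides, and balanced
  # mixing weights make the pipeline commute with transposition
  S <- random_similarity(6, seed = 31)
  MD <- withr::with_seed(32, {
    m <- matrix(stats::rbinom(36, 1, 0.4), 6, 6)
    m <- 1 * ((m + t(m)) > 0)
    dimnames(m) <- list(rownames(S), rownames(S))
    m
  })
  cfg <- scplpa_config(alpha = 0.9, beta = 0.9, delta = 0.5, epsilon = 0.5)
  fit <- run_scplpa(association_matrix(MD), config = cfg,
                    integrated_disease_sim = S, integrated_mirna_sim = S)
  expect_equal(fit$md_star, t(fit$md_star), tolerance = 1e-10)
})

test_that("the sequential sweep emits one AUC per grid point, reproducibly", {
  fx <- generate_fixture(fixture_spec(nm = 10, nd = 8, n_blocks = 2, seed = 9))
  tab <- parameter_sweep(fx$assoc, fx$dags,
                         alpha_grid = c(0.5, 0.9),
                         delta_grid = c(0.5, 0.9),
                         epsilon_grid = c(0.4, 0.6))
  expect_equal(nrow(tab), 6)
  expect_equal(as.character(tab$stage), rep(c("alpha", "delta", "epsilon"), each = 2))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  best <- attr(tab, "best")
  expect_true(best$alpha %in% c(0.5, 0.9))
  tab2 <- parameter_sweep(fx$assoc, fx$dags,
                          alpha_grid = c(0.5, 0.9),
                          delta_grid = c(0.5, 0.9),
                          epsilon_grid = c(0.4, 0.6))
  expect_identical(tab$auc, tab2$auc)
  expect_error(parameter_sweep(fx$assoc, fx$dags, alpha_grid = numeric(0)),
               "nonempty")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    s <- stats::runif(80)
    l <- stats::rbinom(80, 1, 0.35)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(s, l)$auc, ref, tolerance = 1e-12)
})
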