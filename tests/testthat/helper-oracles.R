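# Independent oracles: deliberately naive nested-loop / closed-form
# implementations used only to check the package's vectorized code paths.

# Mann-Whitney pair counting, ties worth one half
oracle_auc_mw <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# AUPR by explicit enumeration of every distinct threshold, step interpolation
oracle_aupr_enum <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    precision <- tp / (tp + fp)
    recall <- tp / npos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# information-content semantic similarity by brute-force set enumeration
oracle_semantic_dd <- function(dags, log_base = exp(1)) {
  ds <- dags$diseases
  n_dag_with <- function(term) {
    sum(vapply(ds, function(d) term %in% dags$ancestors[[d]], logical(1)))
  }
  contr <- function(term) -log(n_dag_with(term) / dags$universe_size, base = log_base)
  dv <- function(d) {
    s <- 0
    for (t in dags$ancestors[[d]]) s <- s + contr(t)
    s
  }
  out <- matrix(0, length(ds), length(ds), dimnames = list(ds, ds))
  for (i in seq_along(ds)) {
    for (j in seq_along(ds)) {
      den <- dv(ds[i]) + dv(ds[j])
      if (den <= 0) next
      if (i == j) {
        out[i, j] <- 1
        next
      }
      num <- 0
      for (t in dags$ancestors[[ds[i]]]) {
        if (t %in% dags$ancestors[[ds[j]]]) num <- num + 2 * contr(t)
      }
      out[i, j] <- num / den
    }
  }
  out
}

# miRNA functional similarity by exhaustive double loop over disease sets
oracle_functional_mm <- function(A, DD) {
  A <- unclass(A)
  nm <- nrow(A)
  out <- matrix(0, nm, nm, dimnames = list(rownames(A), rownames(A)))
  best <- function(d, set) {
    m <- -Inf
    for (t in set) m <- max(m, DD[d, t])
    m
  }
  for (i in seq_len(nm)) {
    for (j in seq_len(nm)) {
      si <- colnames(A)[A[i, ] == 1]
      sj <- colnames(A)[A[j, ] == 1]
      if (length(si) == 0 || length(sj) == 0) next
      tot <- 0
      for (t in si) tot <- tot + best(t, sj)
      for (t in sj) tot <- tot + best(t, si)
      out[i, j] <- tot / (length(si) + length(sj))
    }
  }
  diag(out) <- 1
  out
}

# closed-form label-propagation fixed point
oracle_lp_fixed_point <- function(Wstar, Y, weight) {
  n <- nrow(Wstar)
  weight * solve(diag(n) - (1 - weight) * Wstar, Y)
}

# consistency projections by explicit scalar loops
oracle_project_mirna <- function(MMf, Fe) {
  out <- matrix(0, nrow(Fe), ncol(Fe))
  for (i in seq_len(nrow(Fe))) {
    for (j in seq_len(ncol(Fe))) {
      nrm <- sqrt(sum(Fe[, j]^2))
      if (nrm > 0) out[i, j] <- sum(MMf[i, ] * Fe[, j]) / nrm
    }
  }
  out
}

oracle_project_disease <- function(DDf, Fe) {
  out <- matrix(0, nrow(Fe), ncol(Fe))
  for (i in seq_len(nrow(Fe))) {
    for (j in seq_len(ncol(Fe))) {
      nrm <- sqrt(sum(Fe[i, ]^2))
      if (nrm > 0) out[i, j] <- sum(DDf[j, ] * Fe[i, ]) / nrm
    }
  }
  out
}
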