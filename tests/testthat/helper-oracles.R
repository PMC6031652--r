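# Independent brute-force oracles shared across test files. Each is a
# literal re-implementation of the published rule or textbook estimator,
# sharing no code with the package implementation it checks.

# Independent brute-force OLS for one variant: full normal equations via
# solve(), no shared code with the scan implementation.
brute_ols <- function(y, g, covars) {
  X <- cbind(1, covars, g)
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  V <- s2 * solve(XtX)
  k <- ncol(X)
  list(beta = b[k], se = sqrt(V[k, k]),
       p = 2 * pt(abs(b[k] / sqrt(V[k, k])), df, lower.tail = FALSE))
}

# Brute-force re-implementation of greedy sliding-window pruning used as an
# independent oracle: literal nested loops, no shared code with ld_prune.
brute_prune <- function(G, window = 50, step = 5, r2_max = 0.25) {
  alive <- colnames(G)
  start <- 1
  m <- ncol(G)
  repeat {
    end <- min(start + window - 1, m)
    win <- intersect(colnames(G)[start:end], alive)
    changed <- TRUE
    while (changed && length(win) >= 2) {
      changed <- FALSE
      for (i in seq_along(win)) {
        for (j in seq_along(win)) {
          if (j <= i) next
          a <- G[, win[i]]; b <- G[, win[j]]
          if (sd(a) == 0 || sd(b) == 0) next
          if (cor(a, b)^2 > r2_max) {
            alive <- setdiff(alive, win[j])   # positional rule: drop later
            win <- setdiff(win, win[j])
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
    }
    if (end >= m) break
    start <- start + step
  }
  alive
}

# Brute-force greedy clumping oracle: literal translation of the rule, no
# shared code with clump_results.
brute_clump <- function(res, G, kb = 500, p1 = 1, p2 = 1, r2 = 0.25) {
  res <- res[!is.na(res$p), ]
  res <- res[order(res$p, res$pos), ]
  clump_of <- setNames(rep(NA_character_, nrow(res)), res$variant_id)
  repeat {
    cand <- res$variant_id[is.na(clump_of[res$variant_id]) & res$p <= p1]
    if (length(cand) == 0) break
    idx <- cand[1]
    clump_of[idx] <- idx
    pos_i <- res$pos[res$variant_id == idx]
    for (v in res$variant_id) {
      if (!is.na(clump_of[v])) next
      pos_v <- res$pos[res$variant_id == v]
      p_v <- res$p[res$variant_id == v]
      if (abs(pos_v - pos_i) <= kb * 1000 && p_v <= p2 &&
          cor(G[, idx], G[, v])^2 > r2)
        clump_of[v] <- idx
    }
  }
  clump_of
}

# Brute-force Cox partial likelihood (Breslow ties) maximized by optimize():
# independent of survival::coxph.
brute_cox_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    d <- which(time == t & status == 1)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[d]) -
      length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}
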