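# Independent oracles and fixture builders. Everything here is deliberately
# brute-force and shares no code with the implementation it checks.

# random valid connectome: directed weights, zero diagonal
random_connectome <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(stats::runif(n * n), n, n)
  w[w > density] <- 0
  w[w > 0] <- w[w > 0] + 0.05
  diag(w) <- 0
  connectome(w, name = sprintf("rand-%d-%d", n, seed))
}

# exhaustive-subgraph coreness oracle: coreness(v) = max over all node
# subsets containing v of the minimum within-subset score of any member.
# score_fun(sub_matrix) returns the per-member score (degree or strength).
# Exponential in n; meant for n <= 10.
brute_force_coreness <- function(w, score_fun) {
  n <- nrow(w)
  best <- numeric(n)
  for (mask in 1:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sub <- w[members, members, drop = FALSE]
    level <- min(score_fun(sub))
    upd <- members[level > best[members]]
    best[upd] <- level
  }
  best
}

oracle_k_coreness <- function(conn) {
  a <- (conn$weights > 0 | t(conn$weights) > 0) * 1
  diag(a) <- 0
  brute_force_coreness(a, function(sub) rowSums(sub))
}

oracle_s_coreness <- function(conn) {
  brute_force_coreness(conn$weights,
                       function(sub) rowSums(sub) + colSums(sub))
}

# damped-Newton multivariate fixed-point solver for the coupled network,
# independent of the Euler path: solves F(S) = 0 with numerical Jacobian.
oracle_network_fixed_point <- function(conn, params, S_init,
                                       tol = 1e-12, max_iter = 200) {
  Ffun <- function(S) {
    chi <- params$w * params$J_N * S +
      params$J_N * params$G * drop(conn$weights %*% S) + params$I_0
    x <- params$a * chi - params$b
    R <- ifelse(abs(x) < 1e-9, 1 / params$d + x / 2,
                x / (1 - exp(-params$d * x)))
    -S / params$tau_S + (1 - S) * params$gamma_kin * R
  }
  S <- S_init
  n <- length(S)
  for (it in seq_len(max_iter)) {
    F0 <- Ffun(S)
    if (max(abs(F0)) < tol) break
    J <- matrix(0, n, n)
    h <- 1e-8
    for (j in seq_len(n)) {
      Sp <- S; Sp[j] <- Sp[j] + h
      J[, j] <- (Ffun(Sp) - F0) / h
    }
    step <- tryCatch(solve(J, -F0), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      S_new <- pmin(pmax(S + lam * step, 0), 1)
      if (max(abs(Ffun(S_new))) < max(abs(F0)) || lam < 1e-6) break
      lam <- lam / 2
    }
    S <- S_new
  }
  if (max(abs(Ffun(S))) > 1e-9) return(NULL)
  chi <- params$w * params$J_N * S +
    params$J_N * params$G * drop(conn$weights %*% S) + params$I_0
  list(S = S, R = firing_rate(chi, params))
}

# small, fast sweep configuration for desk tests
quick_cfg <- function(...) {
  sweep_config(g_min = 0.3, g_max = 1.2, g_step = 0.02, seed = 11, ...)
}
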