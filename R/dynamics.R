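#' Mean-field simulation parameters
#'
#' Constants of the reduced Wong-Wang neural mass and of the Euler
#' integration, all in SI-consistent units (seconds, Hz, nA). The defaults
#' are the whole-network values: `tau_S` = 0.1 s synaptic (NMDA) time
#' constant, `gamma_kin` = 0.641 kinetic rate factor, transfer-function gain
#' `a` = 270 (V nC)^-1, threshold `b` = 108 Hz, shape `d` = 0.154 s, local
#' recurrence `w` = 0.9, synaptic coupling `J_N` = 0.2609 nA, basal input
#' `I_0` = 0.3 nA, coupling gain `G`, step `dt` = 1 ms and horizon `T` =
#' 120 s. The isolated-node bistable regime uses `w` = 1, `I_0` = 0.322.
#'
#' @param G dimensionless coupling gain scaling all long-range inputs.
#' @param tau_S,gamma_kin,a,b,d,w,J_N,I_0,dt,T model and integration
#'   constants as above.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(G = 0, tau_S = 0.1, gamma_kin = 0.641,
                       a = 270, b = 108, d = 0.154,
                       w = 0.9, J_N = 0.2609, I_0 = 0.3,
                       dt = 0.001, T = 120) {
  p <- list(G = G, tau_S = tau_S, gamma_kin = gamma_kin, a = a, b = b, d = d,
            w = w, J_N = J_N, I_0 = I_0, dt = dt, T = T)
  consts <- p[setdiff(names(p), "G")]
  if (any(unlist(consts) <= 0)) stop("all constants must be strictly positive",
                                     call. = FALSE)
  if (dt > tau_S / 10) stop("dt must be <= tau_S / 10 for a stable Euler step",
                            call. = FALSE)
  structure(p, class = "sim_params")
}

#' Read simulation parameters from a key-value config file
#'
#' Plain-text `key = value` lines (one per line, `#` comments allowed);
#' unknown keys are an error, missing keys take the [sim_params()] defaults.
#'
#' @param path config file.
#' @return A `sim_params` list.
#' @export
read_sim_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  known <- names(formals(sim_params))
  if (length(keys) > 0 && !all(keys %in% known)) {
    stop("unknown parameter key: ", setdiff(keys, known)[1], call. = FALSE)
  }
  do.call(sim_params, stats::setNames(as.list(vals), keys))
}

#' Transfer function: synaptic input to population firing rate
#'
#' `R(chi) = (a*chi - b) / (1 - exp(-d*(a*chi - b)))`, the sigmoidal-to-
#' linear input-output curve of the reduced neural mass. Continuous and
#' strictly increasing; the removable singularity at `a*chi = b` (where
#' `R = 1/d`) is evaluated by series expansion when `|a*chi - b| < 1e-9`.
#'
#' @param chi total synaptic input (nA), any numeric vector.
#' @param params a [sim_params] list.
#' @return Firing rate(s) in Hz.
#' @export
firing_rate <- function(chi, params = sim_params()) {
  x <- params$a * chi - params$b
  d <- params$d
  out <- numeric(length(x))
  small <- abs(x) < 1e-9
  # x / (1 - exp(-d x)) = 1/d + x/2 + d x^2/12 + O(x^3)
  out[small] <- 1 / d + x[small] / 2 + d * x[small]^2 / 12
  xs <- x[!small]
  out[!small] <- xs / (1 - exp(-d * xs))
  out
}

#' Total synaptic input
#'
#' `chi_i = w*J_N*S_i + J_N*G*sum_j C_ij S_j + I_0`: local recurrence plus
#' gain-scaled long-range input plus basal drive.
#'
#' @param S gating vector (length n).
#' @param conn a [connectome] (n nodes).
#' @param params a [sim_params] list.
#' @return Input vector chi (nA), length n.
#' @export
synaptic_input <- function(S, conn, params = sim_params()) {
  if (length(S) != nrow(conn$weights)) {
    stop("S has length ", length(S), " but the connectome has ",
         nrow(conn$weights), " nodes", call. = FALSE)
  }
  unname(drop(params$w * params$J_N * S +
                params$J_N * params$G * (conn$weights %*% S) +
                params$I_0))
}

#' Simulate the coupled mean-field network
#'
#' Deterministic forward-Euler integration of
#' `dS_i/dt = -S_i/tau_S + (1 - S_i) * gamma_kin * R_i` with `R_i` given by
#' [firing_rate()] applied to [synaptic_input()]. `S` is clamped to `[0, 1]`
#' after every step (overshoot guard); no noise is injected anywhere.
#'
#' @param conn a [connectome].
#' @param params a [sim_params] list; `params$T` sets the duration.
#' @param S0 initial gating vector in `[0, 1]^n`.
#' @param keep_trajectory if `TRUE`, return the whole `S` trajectory
#'   (thinned by `thin`) rather than just the final state.
#' @param thin store every `thin`-th step of the trajectory.
#' @return A list with `S`, `R`, `chi` (final state), `t` (simulated time);
#'   with `keep_trajectory = TRUE` also `trajectory` (steps x n matrix) and
#'   `time` (vector of stored times).
#' @export
simulate_network <- function(conn, params = sim_params(), S0,
                             keep_trajectory = FALSE, thin = 10L) {
  check_S0(S0, conn)
  n_steps <- as.integer(round(params$T / params$dt))
  res <- euler_integrate(conn$weights, S0,
                         params$G, params$tau_S, params$gamma_kin,
                         params$a, params$b, params$d,
                         params$w, params$J_N, params$I_0,
                         params$dt, n_steps,
                         -1.0, 0L,   # no convergence exit
                         keep_trajectory, as.integer(thin))
  if (anyNA(res$S)) {
    stop("divergence (NaN) detected at step ", res$steps, call. = FALSE)
  }
  out <- list(S = drop(res$S),
              chi = synaptic_input(drop(res$S), conn, params),
              t = res$steps * params$dt)
  out$R <- firing_rate(out$chi, params)
  if (keep_trajectory) {
    out$trajectory <- res$trajectory
    out$time <- seq(0, by = params$dt * thin,
                    length.out = nrow(res$trajectory))
  }
  out
}

#' Integrate to a steady state
#'
#' Runs the Euler scheme until the per-node rate of change is negligible —
#' `max_i |dS_i/dt| < tol` sustained for 100 consecutive steps — or until
#' `max_T` of simulated time has elapsed, whichever comes first. Early exit
#' is an optimisation; the cap preserves the fixed-duration protocol.
#'
#' @param conn a [connectome].
#' @param params a [sim_params] list.
#' @param S0 initial gating vector in `[0, 1]^n`.
#' @param tol convergence threshold on `max|dS/dt|` (s^-1).
#' @param max_T time cap in seconds (defaults to `params$T`).
#' @return A list: `S`, `R` (steady state), `converged` (flag; `FALSE`
#'   means the cap was hit, reported via the flag rather than an error),
#'   `t` (elapsed simulated time, s).
#' @export
steady_state <- function(conn, params = sim_params(), S0,
                         tol = 1e-9, max_T = NULL) {
  check_S0(S0, conn)
  if (is.null(max_T)) max_T <- params$T
  if (is.infinite(tol)) {
    R0 <- firing_rate(synaptic_input(S0, conn, params), params)
    return(list(S = S0, R = R0, converged = TRUE, t = 0))
  }
  n_steps <- as.integer(round(max_T / params$dt))
  res <- euler_integrate(conn$weights, S0,
                         params$G, params$tau_S, params$gamma_kin,
                         params$a, params$b, params$d,
                         params$w, params$J_N, params$I_0,
                         params$dt, n_steps,
                         tol, 100L, FALSE, 1L)
  if (anyNA(res$S)) {
    stop("divergence (NaN) detected at step ", res$steps, call. = FALSE)
  }
  S <- drop(res$S)
  list(S = S,
       R = firing_rate(synaptic_input(S, conn, params), params),
       converged = res$converged,
       t = res$steps * params$dt)
}

check_S0 <- function(S0, conn) {
  if (length(S0) != nrow(conn$weights)) {
    stop("S0 has length ", length(S0), " but the connectome has ",
         nrow(conn$weights), " nodes", call. = FALSE)
  }
  if (any(S0 < 0 | S0 > 1)) stop("S0 must lie in [0, 1]", call. = FALSE)
  invisible(S0)
}

#' Fixed points of an isolated node
#'
#' Solves `0 = -S/tau_S + (1 - S) * gamma_kin * R(chi(S))` for a single
#' uncoupled node (`chi = w*J_N*S + I_0`) by dense sign-change bracketing on
#' `S` in `[0, 1]` followed by bisection; stability follows from the sign of
#' the derivative of the right-hand side at the root. Depending on `w` and
#' `I_0` the node is monostable (one stable point) or bistable (stable
#' baseline / unstable / stable ignited).
#'
#' @param params a [sim_params] list (`G` is irrelevant for a single node).
#' @param grid_n number of bracketing grid points on `[0, 1]`.
#' @return A data frame with columns `S`, `R` and `stability`
#'   (`"stable"`/`"unstable"`), ordered by `S`.
#' @export
isolated_fixed_points <- function(params = sim_params(), grid_n = 2000L) {
  rhs <- function(S) {
    chi <- params$w * params$J_N * S + params$I_0
    -S / params$tau_S + (1 - S) * params$gamma_kin * firing_rate(chi, params)
  }
  grid <- seq(0, 1, length.out = grid_n)
  f <- rhs(grid)
  roots <- grid[f == 0]
  flips <- which(f[-1] * f[-length(f)] < 0)
  for (k in flips) {
    roots <- c(roots, stats::uniroot(rhs, c(grid[k], grid[k + 1]),
                                     tol = 1e-12)$root)
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0) return(data.frame(S = numeric(0), R = numeric(0),
                                            stability = character(0)))
  h <- 1e-7
  dfdS <- (rhs(pmin(roots + h, 1)) - rhs(pmax(roots - h, 0))) /
    (pmin(roots + h, 1) - pmax(roots - h, 0))
  chi <- params$w * params$J_N * roots + params$I_0
  data.frame(S = roots,
             R = firing_rate(chi, params),
             stability = ifelse(dfdS < 0, "stable", "unstable"))
}
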