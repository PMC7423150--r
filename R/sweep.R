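#' Coupling-gain sweep configuration
#'
#' The reference protocol scans `G` from 0.5 to 5 in steps of 0.01, starting
#' every run either from Low initial conditions (uniform `S0` in `[0, 0.1]`)
#' or High initial conditions (uniform `S0` in `[0.3, 1]`), with 60
#' repetitions per cell to confirm branch consistency; the desk default is a
#' single repetition, which is sufficient because the dynamics are
#' deterministic and branch membership has always proven IC-draw-invariant.
#' A node counts as ignited when its steady rate exceeds
#' `ignition_threshold` (strictly greater than 5 Hz).
#'
#' @param g_min,g_max,g_step the `G` grid.
#' @param ic_low_range,ic_high_range the two disjoint `S0` sampling
#'   intervals.
#' @param reps repetitions per (G, condition) cell.
#' @param ignition_threshold rate cutoff in Hz.
#' @param seed integer seed for the IC draws.
#' @param paper_protocol if `TRUE`, use the full reference protocol
#'   (`reps = 60`).
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(g_min = 0.5, g_max = 5, g_step = 0.01,
                         ic_low_range = c(0, 0.1),
                         ic_high_range = c(0.3, 1),
                         reps = 1L, ignition_threshold = 5,
                         seed = 1L, paper_protocol = FALSE) {
  if (paper_protocol) reps <- 60L
  stopifnot(g_min < g_max, g_step > 0, reps >= 1,
            all(c(ic_low_range, ic_high_range) >= 0),
            all(c(ic_low_range, ic_high_range) <= 1),
            ic_low_range[2] <= ic_high_range[1])
  structure(list(g_min = g_min, g_max = g_max, g_step = g_step,
                 ic_low_range = ic_low_range, ic_high_range = ic_high_range,
                 reps = as.integer(reps),
                 ignition_threshold = ignition_threshold,
                 seed = as.integer(seed)),
            class = "sweep_config")
}

#' Run a coupling-gain sweep
#'
#' For every grid value of `G` and each initial-condition regime (low,
#' high), draws uniform `S0` from the regime's interval, integrates to a
#' steady state, and records the steady rate vector, its maximum `R_max`,
#' and the ignited mask under the configured threshold. With `reps > 1` the
#' ignited masks of all converged repetitions must agree; disagreeing cells
#' are counted in `inconsistent_cells` and the first repetition is stored as
#' the consensus. Non-converged runs are excluded from the consensus and
#' counted in `nonconverged`.
#'
#' @param conn a [connectome].
#' @param params a [sim_params] list (`G` is overridden by the grid).
#' @param cfg a [sweep_config] list.
#' @param tol,max_T forwarded to [steady_state()].
#' @return A `sweep_result`: list with `g_grid`, per-branch matrices
#'   `R_low`, `R_high` (grid x nodes), vectors `rmax_low`, `rmax_high`,
#'   logical mask matrices `ignited_low`, `ignited_high`, fraction vectors
#'   `f_low`, `f_high`, convergence counts and the config/params echo.
#' @export
run_sweep <- function(conn, params = sim_params(), cfg = sweep_config(),
                      tol = 1e-9, max_T = NULL) {
  g_grid <- seq(cfg$g_min, cfg$g_max, by = cfg$g_step)
  n <- nrow(conn$weights)
  ng <- length(g_grid)
  branches <- list(low = cfg$ic_low_range, high = cfg$ic_high_range)
  out <- list(g_grid = g_grid, config = cfg, params = params,
              labels = conn$labels, n = n,
              nonconverged = 0L, inconsistent_cells = 0L)
  set.seed(cfg$seed)
  for (br in names(branches)) {
    rng <- branches[[br]]
    R <- matrix(NA_real_, ng, n)
    conv <- logical(ng)
    for (k in seq_len(ng)) {
      params$G <- g_grid[k]
      masks <- NULL
      for (r in seq_len(cfg$reps)) {
        S0 <- stats::runif(n, rng[1], rng[2])
        st <- steady_state(conn, params, S0, tol = tol, max_T = max_T)
        if (!st$converged) {
          out$nonconverged <- out$nonconverged + 1L
          if (cfg$reps > 1L) next
        }
        if (is.null(masks)) {
          R[k, ] <- st$R
          conv[k] <- st$converged
          masks <- matrix(st$R > cfg$ignition_threshold, nrow = 1)
        } else {
          masks <- rbind(masks, st$R > cfg$ignition_threshold)
        }
      }
      if (!is.null(masks) && nrow(masks) > 1L &&
          any(apply(masks, 2, function(z) length(unique(z)) > 1))) {
        out$inconsistent_cells <- out$inconsistent_cells + 1L
        warning(sprintf("branch %s, G = %.3f: ignited mask differs across reps",
                        br, g_grid[k]), call. = FALSE)
      }
    }
    ign <- R > cfg$ignition_threshold
    out[[paste0("R_", br)]] <- R
    out[[paste0("rmax_", br)]] <- apply(R, 1, max)
    out[[paste0("ignited_", br)]] <- ign
    out[[paste0("f_", br)]] <- rowMeans(ign)
    out[[paste0("converged_", br)]] <- conv
  }
  structure(out, class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep result> %d nodes, G in [%.3g, %.3g] (%d points)\n",
              x$n, min(x$g_grid), max(x$g_grid), length(x$g_grid)))
  invisible(x)
}

#' Detect the bistable ignition range
#'
#' A grid point is bistable when the two branches disagree:
#' `|R_max(high) - R_max(low)| > branch_gap`. The ignition point `G-` and
#' the flaring point `G+` are the smallest and largest bistable grid
#' values; the ignition core is the set of nodes ignited on the high-IC
#' branch at `G-`. When no grid point is bistable, `exists = FALSE`.
#'
#' Because `R_max` is an indirect (scalar) proxy for the network state, it
#' can close before every individual node's hysteresis closes: near the
#' flaring point, sub-dominant attractors that differ in a single weak node
#' leave `R_max` almost unchanged. The result therefore also reports the
#' *node-wise* envelope — `g_minus_nodewise` / `g_plus_nodewise`, the
#' smallest/largest grid points at which any node's steady rate differs by
#' more than `branch_gap` between the branches. Outside that envelope the
#' two branches coincide node by node; outside `[g_minus, g_plus]` only
#' `R_max` is guaranteed to coincide.
#'
#' @param sweep a `sweep_result` from [run_sweep()].
#' @param branch_gap rate tolerance in Hz separating the branches (default
#'   1 Hz).
#' @return A list of class `bistability_range`: `exists`, `g_minus`,
#'   `g_plus`, `f_minus`, `f_plus`, `n_ignited_minus`, `n_ignited_plus`,
#'   `ignition_core` (node indices), `bistable_mask` over the grid, plus the
#'   node-wise envelope `g_minus_nodewise`, `g_plus_nodewise` and its
#'   `nodewise_mask`.
#' @export
detect_bistable_range <- function(sweep, branch_gap = 1) {
  bi <- abs(sweep$rmax_high - sweep$rmax_low) > branch_gap
  node_diff <- apply(abs(sweep$R_high - sweep$R_low), 1, max)
  nw <- node_diff > branch_gap
  if (!any(bi)) {
    return(structure(list(exists = FALSE, g_minus = NA_real_,
                          g_plus = NA_real_, f_minus = NA_real_,
                          f_plus = NA_real_, n_ignited_minus = NA_integer_,
                          n_ignited_plus = NA_integer_,
                          ignition_core = integer(0), bistable_mask = bi,
                          g_minus_nodewise = if (any(nw)) sweep$g_grid[which(nw)[1]] else NA_real_,
                          g_plus_nodewise = if (any(nw)) sweep$g_grid[which(nw)[sum(nw)]] else NA_real_,
                          nodewise_mask = nw),
                     class = "bistability_range"))
  }
  i_minus <- which(bi)[1]
  i_plus <- which(bi)[sum(bi)]
  structure(list(
    exists = TRUE,
    g_minus = sweep$g_grid[i_minus],
    g_plus = sweep$g_grid[i_plus],
    f_minus = sweep$f_high[i_minus],
    f_plus = sweep$f_high[i_plus],
    n_ignited_minus = sum(sweep$ignited_high[i_minus, ]),
    n_ignited_plus = sum(sweep$ignited_high[i_plus, ]),
    ignition_core = which(sweep$ignited_high[i_minus, ]),
    bistable_mask = bi,
    g_minus_nodewise = sweep$g_grid[which(nw)[1]],
    g_plus_nodewise = sweep$g_grid[which(nw)[sum(nw)]],
    nodewise_mask = nw
  ), class = "bistability_range")
}

#' @export
print.bistability_range <- function(x, ...) {
  if (!x$exists) {
    cat("<bistability range> none detected on the grid\n")
  } else {
    cat(sprintf(
      "<bistability range> G- = %.3f (%d ignited, F- = %.1f%%), G+ = %.3f (%d ignited, F+ = %.1f%%)\n",
      x$g_minus, x$n_ignited_minus, 100 * x$f_minus,
      x$g_plus, x$n_ignited_plus, 100 * x$f_plus))
  }
  invisible(x)
}

#' Per-node first-ignition profile
#'
#' For every node, the smallest grid `G` at which the high-IC branch shows
#' it ignited *and it stays ignited at every larger grid value* (isolated
#' non-monotone flickers are not first ignitions; any flicker is counted in
#' `n_flickers`). Nodes that never ignite within the grid are reported in
#' `never_ignited` with `first_ignition_g = NA`.
#'
#' @param sweep a `sweep_result`.
#' @return A list of class `ignition_profile`: `first_ignition_g` (named
#'   per-node vector, `NA` when never ignited), `never_ignited` (indices),
#'   `n_flickers`.
#' @export
first_ignition_profile <- function(sweep) {
  ign <- sweep$ignited_high
  ng <- nrow(ign)
  first_g <- rep(NA_real_, ncol(ign))
  flickers <- 0L
  for (i in seq_len(ncol(ign))) {
    v <- ign[, i]
    if (!any(v)) next
    # smallest grid index from which the node is ignited through the end
    suffix_all <- rev(cumprod(rev(v))) > 0
    if (any(suffix_all)) {
      k <- which(suffix_all)[1]
      first_g[i] <- sweep$g_grid[k]
      if (any(v[seq_len(k - 1)])) flickers <- flickers + 1L
    } else {
      flickers <- flickers + 1L   # ignited somewhere but not at the top end
    }
  }
  names(first_g) <- sweep$labels
  structure(list(first_ignition_g = first_g,
                 never_ignited = which(is.na(first_g)),
                 n_flickers = flickers),
            class = "ignition_profile")
}
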