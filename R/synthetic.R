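#' Generate a connectome with a planted strong core
#'
#' Builds a random weighted network whose statistics mimic an averaged
#' diffusion-imaging cortical connectome: a fixed number of connections,
#' a right-skewed (log-normal) weight distribution rescaled so the mean
#' nonzero weight hits an exact target, and, optionally, a compact subgraph of
#' exceptionally strong mutual weights (a planted maximal s-core). The planted
#' members are the first `core_size` node indices unless `permute_nodes` is
#' set, which keeps declared membership trivially comparable in tests.
#'
#' With `symmetric = TRUE` (the default) connections are laid out on
#' unordered pairs and each direction receives an independent small
#' multiplicative jitter, so the adjacency support is symmetric but in- and
#' out-strengths differ, as in volume-normalised empirical matrices.
#'
#' @param n node count.
#' @param connection_count target number of nonzero *directed* entries; with
#'   `symmetric = TRUE` it must be even (pairs contribute two entries).
#' @param core_size number of planted core nodes (0 disables the core).
#' @param core_density probability that a within-core pair is connected.
#' @param core_weight_boost multiplicative factor >= 1 applied to within-core
#'   weights before the global rescaling.
#' @param target_mean_weight exact mean of the nonzero weights after rescaling.
#' @param meanlog,sdlog log-normal weight parameters before rescaling; only
#'   `sdlog` (the shape) matters since the mean is rescaled away.
#' @param core_sdlog log-normal shape of the *within-core* weights (default
#'   `sdlog / 10`). The planted core emulates a compact set of strong mutual
#'   weights of comparable magnitude: near-homogeneous within-core weights
#'   make the clique fall in a single cascade of the s-core peeling, so the
#'   planted set is the realized maximal s-core. With the full off-core
#'   dispersion a single extreme pair out-ranks the clique instead, which is
#'   not the structure being planted.
#' @param jitter_sd standard deviation of the per-direction log-normal jitter
#'   (`symmetric = TRUE` only); 0 gives an exactly symmetric matrix.
#' @param symmetric lay connections on unordered pairs (see above) instead of
#'   independent directed entries.
#' @param permute_nodes shuffle node identities after planting, so the core
#'   occupies random indices (membership is still returned).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param labels,name passed to [connectome()].
#' @return A list with elements `connectome` (a validated [connectome]) and
#'   `core` (integer vector of planted member indices).
#' @examples
#' g <- planted_core_connectome(n = 20, connection_count = 120, core_size = 5,
#'                              seed = 1)
#' g$core
#' @export
planted_core_connectome <- function(n, connection_count,
                                    core_size = 0L,
                                    core_density = 1,
                                    core_weight_boost = 6,
                                    target_mean_weight = 1.332e-2,
                                    meanlog = 0, sdlog = 1,
                                    core_sdlog = sdlog / 10,
                                    jitter_sd = 0.1,
                                    symmetric = TRUE,
                                    permute_nodes = FALSE,
                                    seed = 1L,
                                    labels = NULL, name = "planted-core") {
  stopifnot(core_size >= 0, core_size <= n,
            core_density >= 0, core_density <= 1,
            core_weight_boost >= 1, sdlog >= 0,
            connection_count <= n * (n - 1L))
  if (symmetric && connection_count %% 2L != 0L) {
    stop("symmetric generation needs an even connection_count", call. = FALSE)
  }
  set.seed(as.integer(seed))
  core <- seq_len(core_size)

  if (symmetric) {
    pairs <- utils::combn(n, 2L)                     # 2 x n(n-1)/2
    in_core <- pairs[1, ] %in% core & pairs[2, ] %in% core
    budget <- connection_count %/% 2L
    core_pick <- which(in_core)[stats::runif(sum(in_core)) < core_density]
    if (length(core_pick) > budget) core_pick <- core_pick[seq_len(budget)]
    rest <- setdiff(seq_len(ncol(pairs)), core_pick)
    fill <- sample(rest, budget - length(core_pick))
    chosen <- c(core_pick, fill)
    is_core_link <- seq_along(chosen) <= length(core_pick)
    w <- matrix(0, n, n)
    base <- stats::rlnorm(length(chosen), meanlog,
                          ifelse(is_core_link, core_sdlog, sdlog))
    boost <- ifelse(is_core_link, core_weight_boost, 1)
    jit <- function(k) if (jitter_sd > 0) stats::rlnorm(k, 0, jitter_sd) else rep(1, k)
    i <- pairs[1, chosen]; j <- pairs[2, chosen]
    w[cbind(i, j)] <- base * boost * jit(length(chosen))
    w[cbind(j, i)] <- base * boost * jit(length(chosen))
  } else {
    all_idx <- which(upper.tri(matrix(0, n, n)) | lower.tri(matrix(0, n, n)))
    rc <- arrayInd(all_idx, c(n, n))
    in_core <- rc[, 1] %in% core & rc[, 2] %in% core
    core_pick <- which(in_core)[stats::runif(sum(in_core)) < core_density]
    if (length(core_pick) > connection_count)
      core_pick <- core_pick[seq_len(connection_count)]
    fill <- sample(setdiff(seq_along(all_idx), core_pick),
                   connection_count - length(core_pick))
    chosen <- c(core_pick, fill)
    is_core_link <- seq_along(chosen) <= length(core_pick)
    w <- matrix(0, n, n)
    base <- stats::rlnorm(length(chosen), meanlog,
                          ifelse(is_core_link, core_sdlog, sdlog))
    w[all_idx[chosen]] <- base * ifelse(is_core_link, core_weight_boost, 1)
  }

  if (permute_nodes) {
    perm <- sample.int(n)
    w <- w[perm, perm]
    core <- which(perm %in% core)
  }
  nz <- w > 0
  if (any(nz)) w[nz] <- w[nz] * target_mean_weight / mean(w[nz])
  list(connectome = connectome(w, labels = labels, name = name),
       core = sort(core))
}

#' Synthetic stand-in for the 66-region average human connectome
#'
#' Emulates the headline statistics of the averaged 66-area DSI connectome:
#' 66 nodes, 1148 nonzero directed entries, right-skewed weights with mean
#' exactly 1.332e-2, and a planted 11-node core of strongly boosted mutual
#' weights standing in for the empirical maximal s-core. Deterministic under
#' a fixed seed.
#'
#' @param seed integer seed.
#' @param core_weight_boost within-core weight multiplier (default 6).
#' @return A list with `connectome` and `core` as in
#'   [planted_core_connectome()].
#' @export
hagmann_like_connectome <- function(seed = 1L, core_weight_boost = 6) {
  planted_core_connectome(
    n = 66L, connection_count = 1148L,
    core_size = 11L, core_density = 1, core_weight_boost = core_weight_boost,
    target_mean_weight = 1.332e-2, sdlog = 1, jitter_sd = 0.1,
    symmetric = TRUE, seed = seed, name = sprintf("synthetic-66 (seed %d)", seed)
  )
}
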