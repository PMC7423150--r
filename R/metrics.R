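#' Node strengths
#'
#' Under the `C_ij = j -> i` orientation, the in-strength of node `i` is the
#' `i`-th row sum, the out-strength the `i`-th column sum, and the total
#' strength their sum — the weighted analogue of the degree used throughout
#' the core decomposition.
#'
#' @param conn a [connectome].
#' @param mode `"in"`, `"out"` or `"total"`.
#' @return Named numeric vector, one entry per node.
#' @export
node_strengths <- function(conn, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  w <- conn$weights
  s <- switch(mode,
              "in"    = rowSums(w),
              "out"   = colSums(w),
              "total" = rowSums(w) + colSums(w))
  stats::setNames(s, conn$labels)
}

#' Node degrees on the binarized undirected projection
#'
#' An edge exists between `i` and `j` iff either directed weight is nonzero.
#'
#' @param conn a [connectome].
#' @return Named integer vector of degrees.
#' @export
node_degrees <- function(conn) {
  a <- binarize_undirected(conn$weights)
  stats::setNames(rowSums(a), conn$labels)
}

# undirected 0/1 adjacency: edge iff either direction nonzero
binarize_undirected <- function(w) {
  a <- (w > 0 | t(w) > 0) * 1L
  diag(a) <- 0L
  a
}

# shared recursive-peeling engine. strength_fun(alive) returns the current
# within-subgraph score of every alive node. Returns per-node coreness: the
# largest level at which the node survives (running-max peeling rule; ties
# and cascades removed in whole passes, so the result is order-independent).
peel_coreness <- function(n, strength_fun) {
  alive <- rep(TRUE, n)
  coreness <- numeric(n)
  level <- 0
  while (any(alive)) {
    s <- strength_fun(alive)
    level <- max(level, min(s[alive]))
    repeat {
      drop <- alive & s <= level
      if (!any(drop)) break
      coreness[drop] <- level
      alive[drop] <- FALSE
      if (!any(alive)) break
      s <- strength_fun(alive)
    }
  }
  coreness
}

finish_decomposition <- function(coreness, labels, shell_width, integer_levels) {
  names(coreness) <- labels
  s_max <- max(coreness)
  members <- which(coreness == s_max)
  if (is.null(shell_width)) {
    shell_width <- if (integer_levels) 1 else if (s_max > 0) s_max / 100 else 1
  }
  breaks <- unique(c(seq(0, s_max, by = shell_width), s_max))
  bin <- findInterval(coreness, breaks, rightmost.closed = TRUE)
  shells <- split(seq_along(coreness), bin)
  structure(
    list(node_coreness = coreness,
         max_core_level = s_max,
         max_core_members = members,
         shell_width = shell_width,
         shells = shells),
    class = "core_decomposition"
  )
}

#' @export
print.core_decomposition <- function(x, ...) {
  cat(sprintf("<core decomposition> max level %.4g, %d member(s) in the maximal core\n",
              x$max_core_level, length(x$max_core_members)))
  invisible(x)
}

#' k-core decomposition (binarized, undirected)
#'
#' Recursively removes nodes of within-subgraph degree below the running
#' level on the binarized undirected projection. A node's coreness is the
#' largest `k` at which it survives; `k_max` is the deepest nonempty core.
#'
#' @param conn a [connectome].
#' @return A `core_decomposition` with integer levels: `node_coreness`,
#'   `max_core_level` (k_max), `max_core_members`, `shell_width`, `shells`.
#' @export
k_core_decomposition <- function(conn) {
  a <- binarize_undirected(conn$weights)
  n <- nrow(a)
  cn <- peel_coreness(n, function(alive) {
    d <- rep(0, n)
    if (sum(alive) > 0) d[alive] <- rowSums(a[alive, alive, drop = FALSE])
    d
  })
  finish_decomposition(cn, conn$labels, shell_width = 1, integer_levels = TRUE)
}

#' Weighted s-core decomposition
#'
#' The s-core at level `s` is the maximal subgraph in which every member's
#' within-subgraph *total* strength (in + out) is at least `s`; it is found
#' by recursive removal of the weakest node(s), recomputing strengths after
#' every pass. A node's s-coreness is the largest `s` at which it survives;
#' `s_max` is the strongest level with a nonempty core. Levels are located
#' exactly by scanning the attained strengths, never by fixed-step
#' increments; `shell_width` only bins the continuous coreness values into
#' shells for reporting.
#'
#' @param conn a [connectome].
#' @param shell_width bin width for the reported shells (default
#'   `s_max / 100`).
#' @return A `core_decomposition` with continuous levels.
#' @export
s_core_decomposition <- function(conn, shell_width = NULL) {
  w <- conn$weights
  n <- nrow(w)
  cn <- peel_coreness(n, function(alive) {
    s <- rep(0, n)
    if (sum(alive) > 0) {
      sub <- w[alive, alive, drop = FALSE]
      s[alive] <- rowSums(sub) + colSums(sub)
    }
    s
  })
  finish_decomposition(cn, conn$labels, shell_width, integer_levels = FALSE)
}

#' Small-world index
#'
#' `sigma = (gamma / gamma_random) / (lambda / lambda_random)` where `gamma`
#' is the mean local clustering coefficient and `lambda` the characteristic
#' path length of the binarized undirected projection, each normalised by
#' the mean over `n_random` uniform random reference graphs with the same
#' node and edge count (regenerated until connected). `sigma > 1` indicates
#' small-world organisation.
#'
#' @param conn a [connectome]; its binarized projection must be connected.
#' @param n_random number of reference graphs (>= 2).
#' @param seed integer seed for the reference ensemble.
#' @return A list: `sigma`, `gamma_ratio`, `lambda_ratio`, `n_random`,
#'   `dispersion` (standard error of the per-reference sigma estimates),
#'   `gamma`, `lambda`.
#' @export
small_world_sigma <- function(conn, n_random = 100, seed = 1L) {
  if (n_random < 2) stop("n_random must be >= 2", call. = FALSE)
  a <- binarize_undirected(conn$weights)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  if (!igraph::is_connected(g)) {
    stop("binarized graph is disconnected: characteristic path length undefined",
         call. = FALSE)
  }
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  gam <- mean_local_clustering(g)
  lam <- igraph::mean_distance(g)
  set.seed(as.integer(seed))
  gr <- numeric(n_random)
  lr <- numeric(n_random)
  for (k in seq_len(n_random)) {
    repeat {
      ref <- igraph::sample_gnm(n, m)
      if (igraph::is_connected(ref)) break
    }
    gr[k] <- mean_local_clustering(ref)
    lr[k] <- igraph::mean_distance(ref)
  }
  gamma_ratio <- gam / mean(gr)
  lambda_ratio <- lam / mean(lr)
  per_ref <- (gam / gr) / (lam / lr)
  list(sigma = gamma_ratio / lambda_ratio,
       gamma_ratio = gamma_ratio,
       lambda_ratio = lambda_ratio,
       n_random = n_random,
       dispersion = stats::sd(per_ref) / sqrt(n_random),
       gamma = gam,
       lambda = lam)
}

# mean local clustering with the convention that degree < 2 nodes count 0
mean_local_clustering <- function(g) {
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(cc)
}
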