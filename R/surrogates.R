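#' Homogenize connection weights
#'
#' Keeps the adjacency pattern and sets every existing link to a single
#' value, by default the mean nonzero weight of the input — so the mean
#' weight is preserved while all weight heterogeneity is removed. This is
#' the "homogeneous weight" (hw) operation behind the unweighted surrogate
#' ensembles.
#'
#' @param conn a [connectome].
#' @param value weight given to every existing link; defaults to the mean
#'   nonzero weight of `conn`.
#' @return A [connectome] with identical support and constant weights.
#' @export
homogenize_weights <- function(conn, value = NULL) {
  w <- conn$weights
  if (is.null(value)) {
    nz <- w[w > 0]
    value <- if (length(nz) > 0) mean(nz) else 0
  }
  w[w > 0] <- value
  connectome(w, labels = conn$labels,
             name = paste0(conn$name, "_hw"))
}

#' Degree-preserving randomization (Maslov-Sneppen rewiring)
#'
#' Repeated double-edge swaps on the binarized graph, rejecting self-loops
#' and duplicate edges, so the per-node degree sequence is preserved exactly
#' while the wiring is randomised. Symmetric inputs are rewired as
#' undirected and re-symmetrized; asymmetric inputs are rewired as directed
#' graphs (preserving both in- and out-degree sequences). The output is
#' homogeneous-weight: every surviving link carries the input's mean nonzero
#' weight (pass the result to [permute_weights()] for a weighted surrogate).
#'
#' @param conn a [connectome].
#' @param swaps_per_edge attempted swaps per edge (default 10, the standard
#'   burn-in).
#' @param seed integer seed.
#' @return A rewired homogeneous-weight [connectome].
#' @export
degree_preserving_randomize <- function(conn, swaps_per_edge = 10, seed = 1L) {
  w <- conn$weights
  sym <- isTRUE(all.equal((w > 0) * 1L, t(w > 0) * 1L))
  nz <- w[w > 0]
  value <- if (length(nz) > 0) mean(nz) else 0
  set.seed(as.integer(seed))
  if (sym) {
    a <- binarize_undirected(w)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    if (igraph::ecount(g) < 2) stop("too few edges to swap", call. = FALSE)
    g <- igraph::rewire(g, igraph::keeping_degseq(
      niter = swaps_per_edge * igraph::ecount(g)))
    out <- igraph::as_adjacency_matrix(g, sparse = FALSE) * value
  } else {
    g <- igraph::graph_from_adjacency_matrix((w > 0) * 1L, mode = "directed")
    if (igraph::ecount(g) < 2) stop("too few edges to swap", call. = FALSE)
    g <- igraph::rewire(g, igraph::keeping_degseq(
      niter = swaps_per_edge * igraph::ecount(g)))
    out <- igraph::as_adjacency_matrix(g, sparse = FALSE) * value
  }
  dimnames(out) <- NULL
  connectome(out, labels = conn$labels, name = paste0(conn$name, "_dpr"))
}

#' Small-world surrogate ensemble
#'
#' Generates `n_generate` Watts-Strogatz candidates (ring lattice of the
#' even degree whose edge count is closest to `edge_count`, rewiring
#' probability drawn log-uniformly in `[0.01, 0.5]` per candidate), scores
#' each with [small_world_sigma()], and keeps the `n_select` members whose
#' sigma is closest to `sigma_target`. Selection, not construction, matches
#' the target. Homogeneous weights `value` are applied to every member.
#'
#' @param n node count.
#' @param edge_count undirected edge count of the reference.
#' @param sigma_target small-world index to match.
#' @param n_generate,n_select candidate and kept ensemble sizes (the
#'   reference protocol is 1000 and 100).
#' @param value homogeneous weight applied to every link.
#' @param n_random reference-graph count per sigma evaluation (kept small by
#'   default here because sigma is evaluated `n_generate` times).
#' @param seed integer seed.
#' @return A `surrogate_ensemble` (see [build_ensemble()]) of kind `"sw_hw"`
#'   with per-member `sigma` values attached.
#' @export
small_world_ensemble <- function(n, edge_count, sigma_target,
                                 n_generate = 1000, n_select = 100,
                                 value = 1, n_random = 10, seed = 1L) {
  if (n_select > n_generate) stop("n_select must be <= n_generate", call. = FALSE)
  nei <- max(1L, round(edge_count / n))
  if (nei > (n - 1) %/% 2) stop("infeasible edge count for a ring lattice",
                                call. = FALSE)
  set.seed(as.integer(seed))
  p <- exp(stats::runif(n_generate, log(0.01), log(0.5)))
  cand_seeds <- sample.int(.Machine$integer.max, n_generate)
  cands <- vector("list", n_generate)
  sig <- numeric(n_generate)
  for (k in seq_len(n_generate)) {
    set.seed(cand_seeds[k])
    repeat {
      g <- igraph::sample_smallworld(1, n, nei, p[k])
      g <- igraph::simplify(g)
      if (igraph::is_connected(g)) break
    }
    a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    a[a > 0] <- 1
    dimnames(a) <- NULL
    conn <- connectome(a * value, name = sprintf("sw_cand_%d", k))
    sig[k] <- small_world_sigma(conn, n_random = n_random,
                                seed = cand_seeds[k])$sigma
    cands[[k]] <- conn
  }
  keep <- order(abs(sig - sigma_target))[seq_len(n_select)]
  structure(
    list(kind = "sw_hw",
         members = cands[keep],
         reference = NA_character_,
         seeds = cand_seeds[keep],
         sigma = sig[keep],
         sigma_target = sigma_target),
    class = "surrogate_ensemble"
  )
}

#' Permute connection weights onto a structure
#'
#' Keeps the adjacency of `structure` and assigns to its links a uniformly
#' random permutation of the nonzero weights of `weight_source` — the "rw"
#' (random weights) operation: the weight multiset is preserved exactly
#' while weight-to-topology correlations are destroyed.
#'
#' @param structure a [connectome] providing the adjacency.
#' @param weight_source a [connectome] providing the weight multiset; must
#'   have the same number of nonzero links as `structure`.
#' @param seed integer seed.
#' @return A [connectome].
#' @export
permute_weights <- function(structure, weight_source, seed = 1L) {
  ws <- structure$weights
  idx <- which(ws > 0)
  pool <- weight_source$weights[weight_source$weights > 0]
  if (length(idx) != length(pool)) {
    stop("link-count mismatch: structure has ", length(idx),
         " links, weight source has ", length(pool), call. = FALSE)
  }
  set.seed(as.integer(seed))
  ws[idx] <- sample(pool)
  connectome(ws, labels = structure$labels,
             name = paste0(structure$name, "_rw"))
}

#' Build a surrogate-connectome null ensemble
#'
#' Composes the surrogate operations into the six ensembles used to
#' benchmark a reference connectome: `human_hw` (same wiring, homogeneous
#' weights), `dpr_hw` (degree-preserving rewired, homogeneous weights),
#' `sw_hw` (Watts-Strogatz graphs selected to match the reference's
#' small-world sigma), and their weighted counterparts `human_rw`, `dpr_rw`,
#' `sw_rw` obtained by permuting the reference's weights onto the
#' corresponding hw structures. Default sizes follow the reference protocol:
#' 100 members for hw kinds, 60 for rw kinds; `human_hw` is a single
#' deterministic member. Per-member seeds are derived deterministically from
#' the master seed, so regeneration is bit-exact.
#'
#' @param kind one of `"human_hw"`, `"dpr_hw"`, `"sw_hw"`, `"human_rw"`,
#'   `"dpr_rw"`, `"sw_rw"`.
#' @param reference the reference [connectome].
#' @param size ensemble size (default 100 for hw kinds, 60 for rw kinds).
#' @param seed master integer seed.
#' @param sw_n_generate,sw_n_random Watts-Strogatz candidate pool and
#'   per-candidate sigma reference count (sw kinds only).
#' @param sigma_n_random reference count used to score the reference's own
#'   sigma target (sw kinds only).
#' @return A `surrogate_ensemble`: list with `kind`, `members` (list of
#'   [connectome]s), `reference` (name), `seeds`, and for sw kinds `sigma`
#'   and `sigma_target`.
#' @export
build_ensemble <- function(kind = c("human_hw", "dpr_hw", "sw_hw",
                                    "human_rw", "dpr_rw", "sw_rw"),
                           reference, size = NULL, seed = 1L,
                           sw_n_generate = NULL, sw_n_random = 10,
                           sigma_n_random = 100) {
  kind <- match.arg(kind)
  weighted <- grepl("_rw$", kind)
  if (is.null(size)) size <- if (weighted) 60L else 100L
  if (kind == "human_hw") size <- 1L
  set.seed(as.integer(seed))
  member_seeds <- sample.int(.Machine$integer.max, max(size, 1L))
  base_kind <- sub("_rw$", "_hw", kind)
  sigma_target <- NULL
  if (base_kind == "sw_hw") {
    sigma_target <- small_world_sigma(reference, n_random = sigma_n_random,
                                      seed = member_seeds[1])$sigma
  }

  structures <- switch(
    base_kind,
    human_hw = replicate(size, homogenize_weights(reference), simplify = FALSE),
    dpr_hw = lapply(seq_len(size), function(k) {
      degree_preserving_randomize(homogenize_weights(reference),
                                  seed = member_seeds[k])
    }),
    sw_hw = {
      ref_sum <- summary(reference)
      if (is.null(sw_n_generate)) sw_n_generate <- 10L * size
      ens <- small_world_ensemble(ref_sum$n, ref_sum$pair_count, sigma_target,
                                  n_generate = sw_n_generate, n_select = size,
                                  value = ref_sum$mean_weight,
                                  n_random = sw_n_random,
                                  seed = member_seeds[1])
      ens$members
    }
  )
  if (kind == "human_rw") {
    # same wiring as the reference; only the weights are permuted
    structures <- replicate(size, reference, simplify = FALSE)
  } else if (weighted) {
    structures <- structures[seq_len(size)]
  }
  members <- if (weighted) {
    lapply(seq_len(size), function(k) {
      permute_weights(structures[[k]], reference,
                      seed = member_seeds[k] %% 2147483587L + 1L)
    })
  } else {
    structures
  }
  out <- list(kind = kind, members = members, reference = reference$name,
              seeds = member_seeds[seq_len(size)])
  if (!is.null(sigma_target)) out$sigma_target <- sigma_target
  structure(out, class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate ensemble> kind %s, %d member(s), reference %s\n",
              x$kind, length(x$members), x$reference))
  invisible(x)
}
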