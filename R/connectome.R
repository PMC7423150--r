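#' Weighted connectome container
#'
#' A `connectome` wraps a dense n x n matrix of nonnegative coupling weights
#' together with region labels. The orientation convention follows the network
#' input term of the mean-field model: entry `weights[i, j]` is the weight of
#' the connection from node `j` *to* node `i`, so the input to node `i` is the
#' `i`-th row of `weights %*% S`. Consequently the in-strength of node `i` is
#' its row sum and the out-strength its column sum.
#'
#' @param weights square numeric matrix; finite, nonnegative, zero diagonal.
#' @param labels character vector of unique region identifiers, one per node.
#'   Defaults to `"n01"`, `"n02"`, ... when omitted.
#' @param name free-text provenance tag stored with the object.
#'
#' @return An object of class `connectome`: a list with elements `weights`
#'   (with `labels` as dimnames), `labels` and `name`.
#' @examples
#' w <- matrix(0, 3, 3)
#' w[2, 1] <- w[1, 2] <- 0.5
#' w[3, 2] <- 0.2
#' conn <- connectome(w, labels = c("A", "B", "C"))
#' summary(conn)
#' @export
connectome <- function(weights, labels = NULL, name = "connectome") {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  n <- nrow(weights)
  if (is.null(labels)) labels <- sprintf("n%02d", seq_len(n))
  labels <- as.character(labels)
  obj <- structure(
    list(weights = weights, labels = labels, name = as.character(name)[1]),
    class = "connectome"
  )
  validate_connectome(obj)
  dimnames(obj$weights) <- list(labels, labels)
  obj
}

#' Validate connectome invariants
#'
#' Checks squareness, finiteness, nonnegativity, a zero diagonal, and label
#' consistency. Violations are reported with row/column context.
#'
#' @param conn a `connectome` (or a bare list with the same fields).
#' @return `conn`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_connectome <- function(conn) {
  w <- conn$weights
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    stop("connectome weights must be a square matrix, got ",
         nrow(w), " x ", ncol(w), call. = FALSE)
  }
  bad <- which(!is.finite(w), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite weight at [%d, %d]", bad[1, 1], bad[1, 2]),
         call. = FALSE)
  }
  bad <- which(w < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("negative weight %.6g at [%d, %d]",
                 w[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  dg <- which(diag(w) != 0)
  if (length(dg) > 0L) {
    stop(sprintf("nonzero diagonal entry at node %d (self-coupling not allowed)",
                 dg[1]), call. = FALSE)
  }
  if (length(conn$labels) != nrow(w)) {
    stop("label count (", length(conn$labels), ") does not match node count (",
         nrow(w), ")", call. = FALSE)
  }
  if (anyDuplicated(conn$labels)) {
    stop("duplicate region label: ",
         conn$labels[anyDuplicated(conn$labels)], call. = FALSE)
  }
  invisible(conn)
}

#' @export
print.connectome <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<connectome> %s: %d nodes, %d directed connections (density %.3f)\n",
              x$name, s$n, s$connection_count, s$density))
  cat(sprintf("  mean nonzero weight %.4g\n", s$mean_weight))
  invisible(x)
}

#' Summarize a connectome
#'
#' @param object a `connectome`.
#' @param ... unused.
#' @return A list with `n`, `connection_count` (nonzero directed entries),
#'   `pair_count` (unordered connected pairs: the same quantity under the
#'   other counting convention), `density` (directed, out of n(n-1)),
#'   `mean_weight` (mean over nonzero entries; 0 for an empty graph) and
#'   `weight_quantiles` (0/25/50/75/100% of the nonzero weights).
#' @export
summary.connectome <- function(object, ...) {
  w <- object$weights
  n <- nrow(w)
  nz <- w[w > 0]
  m <- sum(w > 0)
  pairs <- sum((w > 0 | t(w) > 0)[upper.tri(w)])
  list(
    n = n,
    connection_count = m,
    pair_count = pairs,
    density = if (n > 1L) m / (n * (n - 1L)) else 0,
    mean_weight = if (m > 0L) mean(nz) else 0,
    weight_quantiles = if (m > 0L) stats::quantile(nz) else
      stats::setNames(rep(0, 5), c("0%", "25%", "50%", "75%", "100%"))
  )
}

#' Read a connectome from disk
#'
#' Two plain-text formats are supported. `"matrix"`: whitespace/tab-delimited
#' dense n x n matrix, lines starting with `#` ignored. `"edgelist"`:
#' 3-column tab-delimited `source target weight` with 0-based node indices,
#' one directed edge per line; absent pairs are materialized as 0.
#'
#' @param path file to read.
#' @param format `"matrix"` or `"edgelist"`.
#' @param labels_path optional plain-text label table: one label per line, or
#'   two whitespace-separated columns `index label` (0-based index).
#' @param n node count, required for `"edgelist"` input when it cannot be
#'   inferred (defaults to 1 + the largest index seen).
#' @param name provenance tag; defaults to the file name.
#' @return A validated [connectome].
#' @export
read_connectome <- function(path, format = c("matrix", "edgelist"),
                            labels_path = NULL, n = NULL, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- basename(path)
  if (format == "matrix") {
    w <- as.matrix(utils::read.table(path, comment.char = "#"))
    dimnames(w) <- NULL
  } else {
    e <- utils::read.table(path, comment.char = "#",
                           col.names = c("source", "target", "weight"))
    if (nrow(e) > 0 && (any(e$source != floor(e$source)) ||
                        any(e$target != floor(e$target)))) {
      stop("edge-list indices must be integers", call. = FALSE)
    }
    if (is.null(n)) n <- if (nrow(e) == 0) 0L else max(e$source, e$target) + 1L
    dup <- duplicated(e[, c("source", "target")])
    if (any(dup)) {
      stop(sprintf("duplicate edge %d -> %d at line %d",
                   e$source[dup][1], e$target[dup][1], which(dup)[1]),
           call. = FALSE)
    }
    w <- matrix(0, n, n)
    # stored as source -> target; C_ij = j -> i lands in row `target`
    w[cbind(e$target + 1L, e$source + 1L)] <- e$weight
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, comment.char = "#",
                             colClasses = "character")
    labels <- if (ncol(lab) >= 2) {
      lab[[2]][order(as.integer(lab[[1]]))]
    } else {
      lab[[1]]
    }
  }
  connectome(w, labels = labels, name = name)
}

#' Write a connectome to disk
#'
#' Inverse of [read_connectome()]: `load(write(conn))` reproduces the weights
#' to full stored precision and the labels exactly.
#'
#' @param conn a `connectome`.
#' @param path output file.
#' @param format `"matrix"` or `"edgelist"`.
#' @param labels_path optional path for a 2-column `index label` side-car.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(conn, path, format = c("matrix", "edgelist"),
                             labels_path = NULL) {
  format <- match.arg(format)
  validate_connectome(conn)
  w <- conn$weights
  if (format == "matrix") {
    lines <- apply(w, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(lines, path)
  } else {
    idx <- which(w > 0, arr.ind = TRUE)
    # row = target i, column = source j under the C_ij = j -> i convention
    lines <- sprintf("%d\t%d\t%.17g",
                     idx[, 2] - 1L, idx[, 1] - 1L, w[idx])
    writeLines(lines, path)
  }
  if (!is.null(labels_path)) {
    writeLines(sprintf("%d\t%s", seq_along(conn$labels) - 1L, conn$labels),
               labels_path)
  }
  invisible(path)
}
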