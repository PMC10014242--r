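#' Communication topology
#'
#' A `topology` object is an undirected, unweighted graph over `n` agents
#' (0-based indices in the edge list for interchange; 1-based internally, as
#' usual in R). It stores the adjacency matrix and, when the graph was
#' generated geometrically, the node positions in the unit square.
#'
#' @param n Number of agents (>= 1).
#' @param edges Two-column integer matrix of 1-based endpoint pairs, one row
#'   per undirected edge. Self-loops are rejected; duplicate rows collapse.
#' @param positions Optional `n x 2` matrix of node coordinates in the unit
#'   square (kept for reproducibility of geometric graphs).
#' @return An object of class `topology` with elements `n`, `edges`,
#'   `adjacency`, and `positions`.
#' @examples
#' tp <- topology(3, rbind(c(1, 2), c(2, 3)))
#' degrees(tp)
#' @export
topology <- function(n, edges, positions = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer")
  }
  n <- as.integer(n)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L | edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    # canonical order (i < j), drop duplicates
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
  }
  adj <- matrix(0, n, n)
  if (nrow(edges) > 0L) {
    adj[edges] <- 1
    adj[edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  if (!is.null(positions)) {
    positions <- matrix(as.numeric(positions), ncol = 2L)
    stopifnot(nrow(positions) == n)
  }
  structure(
    list(n = n, edges = edges, adjacency = adj, positions = positions),
    class = "topology"
  )
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf(
    "<topology> %d nodes, %d edges, mean degree %.2f%s\n",
    x$n, nrow(x$edges), mean_degree(x),
    if (!is.null(x$positions)) ", geometric" else ""
  ))
  invisible(x)
}

#' Degree sequence, mean degree and Laplacian
#'
#' @param tp A [topology()].
#' @return `degrees()` returns the integer degree of each node; `mean_degree()`
#'   the average degree 2|E|/n; `laplacian()` the combinatorial Laplacian
#'   L = D - A whose rows sum to zero.
#' @export
degrees <- function(tp) {
  stopifnot(inherits(tp, "topology"))
  as.integer(rowSums(tp$adjacency))
}

#' @rdname degrees
#' @export
mean_degree <- function(tp) {
  stopifnot(inherits(tp, "topology"))
  2 * nrow(tp$edges) / tp$n
}

#' @rdname degrees
#' @export
laplacian <- function(tp) {
  stopifnot(inherits(tp, "topology"))
  diag(rowSums(tp$adjacency), tp$n) - tp$adjacency
}

as_igraph <- function(tp) {
  igraph::graph_from_adjacency_matrix(tp$adjacency, mode = "undirected")
}

#' Connectivity test
#'
#' @param tp A [topology()].
#' @return `TRUE` iff a single connected component spans all nodes.
#' @export
is_connected_topology <- function(tp) {
  stopifnot(inherits(tp, "topology"))
  if (tp$n == 1L) return(TRUE)
  igraph::is_connected(as_igraph(tp))
}

#' Random geometric graph in the unit square
#'
#' Places `n` nodes uniformly at random in the unit square and connects every
#' pair at Euclidean distance strictly below `delta`. With
#' `connected = TRUE`, instances are rejection-sampled until a connected graph
#' is drawn; the number of rejected instances is attached as attribute
#' `"rejections"`.
#'
#' @param n Number of nodes (>= 1).
#' @param delta Connection radius (> 0).
#' @param seed Integer seed for the placement.
#' @param connected If `TRUE`, resample until connected.
#' @param max_tries Cap on rejection-sampling attempts.
#' @return A [topology()] with node positions retained.
#' @examples
#' tp <- generate_rgg(25, 0.4, seed = 1)
#' @export
generate_rgg <- function(n, delta, seed = NULL, connected = FALSE,
                         max_tries = 10000L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("`delta` must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  tries <- 0L
  repeat {
    pos <- cbind(stats::runif(n), stats::runif(n))
    d <- as.matrix(stats::dist(pos))
    adj <- (d < delta) * 1
    diag(adj) <- 0
    idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    tp <- topology(n, idx, positions = pos)
    if (!connected || is_connected_topology(tp)) {
      attr(tp, "rejections") <- tries
      return(tp)
    }
    tries <- tries + 1L
    if (tries >= max_tries) {
      stop("could not draw a connected RGG within `max_tries`; increase delta")
    }
  }
}

#' Erdos-Renyi and ring-lattice topologies
#'
#' Convenience generators behind the same `topology` interface, used to check
#' that results do not hinge on the geometric construction.
#'
#' @param n Number of nodes.
#' @param p Edge probability (Erdos-Renyi G(n, p)).
#' @param k Even neighbourhood size of the ring lattice (each node linked to
#'   the `k/2` nearest nodes on each side).
#' @param seed Integer seed.
#' @return A [topology()].
#' @export
generate_er <- function(n, p, seed = NULL) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  topology(n, igraph::as_edgelist(g))
}

#' @rdname generate_er
#' @export
generate_ring <- function(n, k) {
  stopifnot(n >= 3, k >= 2, k %% 2 == 0, k < n)
  half <- k / 2
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- ((i - 1 + seq_len(half)) %% n) + 1
    cbind(i, j)
  }))
  topology(n, edges)
}

#' Calibrate the connection radius to a target mean degree
#'
#' The analytic estimate `kappa = n * pi * delta^2` ignores the boundary of
#' the unit square and overstates the degree, so the radius is found by
#' bisection on the empirical mean degree over a fixed panel of uniformly
#' drawn point sets (common random numbers, so the objective is monotone and
#' deterministic given the seed).
#'
#' @param n Number of nodes.
#' @param kappa Target mean degree, in (0, n-1].
#' @param seed Integer seed for the calibration panel.
#' @param samples Number of point sets in the panel.
#' @param tol Tolerance on the panel mean degree.
#' @return The calibrated radius `delta`.
#' @examples
#' delta <- radius_for_target_degree(50, 10, seed = 1)
#' @export
radius_for_target_degree <- function(n, kappa, seed = NULL, samples = 200L,
                                     tol = 0.5) {
  stopifnot(n >= 2)
  if (!is.numeric(kappa) || kappa <= 0 || kappa > n - 1) {
    stop("`kappa` must lie in (0, n-1]")
  }
  if (kappa == n - 1) return(sqrt(2))
  if (!is.null(seed)) set.seed(seed)
  panel <- lapply(seq_len(samples), function(s) {
    as.matrix(stats::dist(cbind(stats::runif(n), stats::runif(n))))
  })
  mean_deg <- function(delta) {
    mean(vapply(panel, function(d) {
      (sum(d < delta) - n) / n  # subtract the zero diagonal
    }, numeric(1)))
  }
  lo <- 0
  hi <- sqrt(2)
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    m <- mean_deg(mid)
    if (abs(m - kappa) <= tol) return(mid)
    if (m < kappa) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Edge-list serialization
#'
#' Plain-text interchange format: a header line `n=<N>` followed by one
#' 0-based `i j` pair per line.
#'
#' @param tp A [topology()].
#' @param path File path.
#' @return `write_topology()` returns `path` invisibly; `read_topology()`
#'   returns a [topology()] (positions are not serialized).
#' @export
write_topology <- function(tp, path) {
  stopifnot(inherits(tp, "topology"))
  lines <- c(
    sprintf("n=%d", tp$n),
    if (nrow(tp$edges) > 0L) {
      sprintf("%d %d", tp$edges[, 1L] - 1L, tp$edges[, 2L] - 1L)
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  if (!grepl("^n=\\d+$", lines[1L])) stop("missing `n=<N>` header")
  n <- as.integer(sub("^n=", "", lines[1L]))
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  edges <- if (length(body) > 0L) {
    do.call(rbind, lapply(strsplit(body, "\\s+"), function(x) {
      as.integer(x[1:2]) + 1L
    }))
  } else {
    matrix(integer(0), ncol = 2L)
  }
  topology(n, edges)
}
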