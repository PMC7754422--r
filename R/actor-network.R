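#' Actor networks
#'
#' An `actor_network` represents the social system over which reserve and
#' development behaviors spread: one node per actor (each with exclusive
#' management rights over one species-bearing site), and undirected links
#' carrying two influence probabilities. `u_d` is the probability, per time
#' step, that a neighbor who has developed induces an available actor to
#' develop; `u_r` is the same for the reserve behavior (active only while an
#' intervention targets the actor).
#'
#' @param n_nodes Number of actors/sites (positive integer).
#' @param edges A data frame or two-column matrix of undirected links with
#'   columns `from` and `to` (1-based node indices) and optionally `u_r` and
#'   `u_d` per-link strengths. May have zero rows for an empty network.
#' @param u_r,u_d Global link strengths in `[0, 1]`, used for any edge that
#'   does not carry its own.
#' @param labels Optional character vector of node names.
#'
#' @return An object of class `actor_network`: a list with elements
#'   `n_nodes`, `edges` (tibble with `from`, `to`, `u_r`, `u_d`) and
#'   `labels`.
#' @export
#' @examples
#' net <- actor_network(3, data.frame(from = c(1, 2), to = c(2, 3)),
#'                      u_r = 0.3, u_d = 0.3)
#' network_density(net)
actor_network <- function(n_nodes, edges = NULL, u_r = 0, u_d = 0,
                          labels = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 1L) {
    stop("`n_nodes` must be a single positive integer.", call. = FALSE)
  }
  if (is.null(edges)) {
    edges <- tibble::tibble(from = integer(), to = integer())
  }
  edges <- tibble::as_tibble(as.data.frame(edges))
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges))) {
    names(edges)[1:2] <- c("from", "to")
  }
  if (!all(c("from", "to") %in% names(edges))) {
    edges$from <- integer(0)
    edges$to <- integer(0)
  }
  if (!"u_r" %in% names(edges)) edges$u_r <- rep(u_r, nrow(edges))
  if (!"u_d" %in% names(edges)) edges$u_d <- rep(u_d, nrow(edges))
  edges <- edges[, c("from", "to", "u_r", "u_d")]
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)

  if (nrow(edges) > 0) {
    if (any(edges$from == edges$to)) {
      stop("Self-links are not allowed.", call. = FALSE)
    }
    if (any(edges$from < 1L | edges$from > n_nodes |
            edges$to < 1L | edges$to > n_nodes)) {
      stop("Edge endpoints must reference nodes in 1..n_nodes.", call. = FALSE)
    }
    ## canonical unordered representation
    lo <- pmin(edges$from, edges$to)
    hi <- pmax(edges$from, edges$to)
    edges$from <- lo
    edges$to <- hi
    if (anyDuplicated(paste(lo, hi))) {
      stop("Duplicate undirected links.", call. = FALSE)
    }
  }
  if (any(edges$u_r < 0 | edges$u_r > 1 | edges$u_d < 0 | edges$u_d > 1)) {
    stop("Link strengths u_r and u_d must lie in [0, 1].", call. = FALSE)
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_nodes)
    labels <- as.character(labels)
  }
  structure(
    list(n_nodes = n_nodes, edges = edges, labels = labels),
    class = "actor_network"
  )
}

#' @export
print.actor_network <- function(x, ...) {
  cat("<actor_network> ", x$n_nodes, " nodes, ", nrow(x$edges), " links\n",
      sep = "")
  if (!is.null(x$labels)) cat("nodes:", paste(x$labels, collapse = ", "), "\n")
  if (nrow(x$edges) > 0) print(x$edges, n = 10)
  invisible(x)
}

#' @export
#' @method tidy actor_network
tidy.actor_network <- function(x, ...) {
  out <- x$edges
  if (!is.null(x$labels)) {
    out$from_label <- x$labels[out$from]
    out$to_label <- x$labels[out$to]
  }
  out
}

## Motif edge sets in one constants block so the topology of any motif can
## be corrected in a single place. All motifs use 1-based indices; node 1 is
## the hub for star and wheel, node n is the hub for ring_star.
motif_edge_table <- function(kind, n_nodes) {
  n <- n_nodes
  pairs <- switch(
    kind,
    ring = cbind(1:n, c(2:n, 1L)),
    line = cbind(1:(n - 1), 2:n),
    star = cbind(rep(1L, n - 1), 2:n),
    ## hub (node 1) joined to every rim node plus the rim cycle
    wheel = rbind(
      cbind(rep(1L, n - 1), 2:n),
      cbind(2:n, c(3:n, 2L))
    ),
    ## rim cycle over nodes 1..(n-1); hub node n pends from rim node 1,
    ## giving a density equal to the ring's and a closeness centralization
    ## between line and wheel
    ring_star = rbind(
      cbind(1:(n - 1), c(2:(n - 1), 1L)),
      c(1L, n)
    ),
    stop("Unknown motif kind: '", kind, "'.", call. = FALSE)
  )
  pairs
}

#' Build a named network motif
#'
#' Constructs one of the five 6-node motif topologies used to span a
#' gradient of closeness centralization: `ring` (cycle), `line` (path),
#' `ring_star` (cycle rim with a pendant hub), `wheel` (hub joined to every
#' rim node plus the rim cycle) and `star` (hub plus leaves). All links get
#' the same homogeneous strengths `u_r` and `u_d`.
#'
#' @param kind One of `"ring"`, `"line"`, `"ring_star"`, `"wheel"`,
#'   `"star"`.
#' @param n_nodes Number of nodes (default 6, minimum 3; `wheel` and
#'   `ring_star` need at least 4).
#' @inheritParams actor_network
#' @return An [actor_network()].
#' @export
#' @examples
#' motif_network("star", u_r = 0.5, u_d = 0.5)
motif_network <- function(kind = c("ring", "line", "ring_star", "wheel",
                                   "star"),
                          n_nodes = 6, u_r = 0, u_d = 0) {
  if (length(kind) != 1L || !kind %in% c("ring", "line", "ring_star",
                                         "wheel", "star")) {
    stop("`kind` must be one of ring, line, ring_star, wheel, star.",
         call. = FALSE)
  }
  n_nodes <- as.integer(n_nodes)
  min_n <- if (kind %in% c("wheel", "ring_star")) 4L else 3L
  if (n_nodes < min_n) {
    stop("Motif '", kind, "' needs at least ", min_n, " nodes.",
         call. = FALSE)
  }
  pairs <- motif_edge_table(kind, n_nodes)
  net <- actor_network(
    n_nodes,
    data.frame(from = pairs[, 1], to = pairs[, 2]),
    u_r = u_r, u_d = u_d
  )
  attr(net, "motif") <- kind
  net
}

## hop-count distance matrix (link strengths never enter distances)
distance_matrix <- function(net) {
  if (nrow(net$edges) == 0) {
    d <- matrix(Inf, net$n_nodes, net$n_nodes)
    diag(d) <- 0
    return(d)
  }
  g <- igraph::make_empty_graph(n = net$n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(as.matrix(
    net$edges[, c("from", "to")]))))
  igraph::distances(g)
}

#' Closeness centrality
#'
#' Normalized closeness \eqn{(n - 1) / \sum_j d(i, j)} with unweighted
#' hop-count distances. For a node in a smaller connected component the sum
#' runs over its reachable set only (still normalized by \eqn{n - 1}), and
#' an isolated node has closeness 0. Link strengths affect dynamics, not
#' distances.
#'
#' @param net An [actor_network()].
#' @param node Optional single node index; if omitted, a vector for all
#'   nodes is returned.
#' @return Nonnegative numeric closeness value(s) (values can exceed 1 for
#'   nodes in small components, since the normalization always uses
#'   `n - 1`).
#' @export
closeness_centrality <- function(net, node = NULL) {
  stopifnot(inherits(net, "actor_network"))
  d <- distance_matrix(net)
  n <- net$n_nodes
  cc <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0) 0 else (n - 1) / sum(di)
  }, numeric(1))
  if (is.null(node)) return(cc)
  if (node < 1 || node > n) stop("Invalid node index.", call. = FALSE)
  cc[node]
}

#' Freeman closeness centralization
#'
#' Whole-network statistic \eqn{\sum_i (c_{max} - c_i)} divided by the
#' maximum attainable sum for `n` nodes, which is attained by the star:
#' \eqn{(n - 1)(n - 2) / (2n - 3)}. Uses the closeness convention of
#' [closeness_centrality()], including its treatment of disconnected nodes.
#'
#' @inheritParams closeness_centrality
#' @return A value in `[0, 1]`.
#' @export
closeness_centralization <- function(net) {
  stopifnot(inherits(net, "actor_network"))
  n <- net$n_nodes
  if (n < 3) stop("Centralization needs at least 3 nodes.", call. = FALSE)
  cc <- closeness_centrality(net)
  sum(max(cc) - cc) / ((n - 1) * (n - 2) / (2 * n - 3))
}

#' Network density
#'
#' Number of links relative to the number of possible undirected links,
#' \eqn{|E| / \binom{n}{2}}.
#'
#' @inheritParams closeness_centrality
#' @return A value in `[0, 1]`.
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "actor_network"))
  n <- net$n_nodes
  if (n < 2) stop("Density needs at least 2 nodes.", call. = FALSE)
  nrow(net$edges) / (n * (n - 1) / 2)
}

## strength matrices (n x n symmetric, 0 where no link)
strength_matrices <- function(net) {
  n <- net$n_nodes
  Ur <- matrix(0, n, n)
  Ud <- matrix(0, n, n)
  if (nrow(net$edges) > 0) {
    idx <- cbind(net$edges$from, net$edges$to)
    Ur[idx] <- net$edges$u_r
    Ur[idx[, 2:1, drop = FALSE]] <- net$edges$u_r
    Ud[idx] <- net$edges$u_d
    Ud[idx[, 2:1, drop = FALSE]] <- net$edges$u_d
  }
  list(u_r = Ur, u_d = Ud)
}
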