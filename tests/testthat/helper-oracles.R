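# Independent brute-force oracles used to validate the package's
# implementations along a different computational path.

## ---- graph metrics: Floyd-Warshall on an adjacency matrix ----

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

adjacency_of <- function(net) {
  n <- net$n_nodes
  adj <- matrix(0, n, n)
  if (nrow(net$edges) > 0) {
    idx <- cbind(net$edges$from, net$edges$to)
    adj[idx] <- 1
    adj[idx[, 2:1, drop = FALSE]] <- 1
  }
  adj
}

oracle_closeness <- function(net) {
  d <- oracle_distances(adjacency_of(net))
  n <- net$n_nodes
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0) 0 else (n - 1) / sum(di)
  }, numeric(1))
}

oracle_centralization <- function(net) {
  cc <- oracle_closeness(net)
  n <- net$n_nodes
  sum(max(cc) - cc) / ((n - 1) * (n - 2) / (2 * n - 3))
}

## ---- discrepancy: explicit maximally packed matrix ----

oracle_discrepancy <- function(inc) {
  inc <- as.matrix(inc)
  ord <- order(colSums(inc), decreasing = TRUE)
  packed_cols <- function(r) if (r == 0) integer(0) else ord[seq_len(r)]
  mismatch <- 0L
  for (i in seq_len(nrow(inc))) {
    packed <- matrix(0L, 1, ncol(inc))
    packed[packed_cols(sum(inc[i, ]))] <- 1L
    mismatch <- mismatch + sum(inc[i, ] == 1L & packed[1, ] == 0L)
  }
  mismatch
}

## all binary matrices with the given row and column sums (tiny cases only)
oracle_fixed_marginal_matrices <- function(rs, cs) {
  nr <- length(rs)
  nc <- length(cs)
  out <- list()
  cells <- expand.grid(rep(list(0:1), nr * nc))
  for (i in seq_len(nrow(cells))) {
    m <- matrix(as.integer(cells[i, ]), nr, nc)
    if (all(rowSums(m) == rs) && all(colSums(m) == cs)) {
      out[[length(out) + 1]] <- m
    }
  }
  out
}

## ---- factored dynamics: scalar per-node kernel and explicit joint ----

oracle_node_probs <- function(digit, digits_all, i, Ud, Ur, p_d, p_r,
                              intervened) {
  if (digit == 1) return(c(0, 1, 0))
  if (digit == 2) return(c(0, 0, 1))
  stay_d <- prod(1 - Ud[i, digits_all == 1])
  stay_r <- prod(1 - Ur[i, digits_all == 2])
  q_d <- 1 - (1 - p_d) * stay_d
  if (!intervened) return(c(1 - q_d, q_d, 0))
  q_r <- 1 - (1 - p_r) * stay_r
  c((1 - q_r) * (1 - q_d), (1 - q_r) * q_d, q_r)
}

## explicit (3^n x 3^n) transition matrix by enumeration over all outcomes
oracle_transition_matrix <- function(model, action) {
  n <- model$network$n_nodes
  S <- 3^n
  str <- netreserve:::strength_matrices(model$network)
  P <- matrix(0, S, S)
  for (s in 0:(S - 1)) {
    digs <- decode_state(s, n)
    probs <- lapply(seq_len(n), function(i) {
      oracle_node_probs(digs[i], digs, i, str$u_d, str$u_r,
                        model$params$p_d, model$params$p_r,
                        intervened = action == i)
    })
    for (t in 0:(S - 1)) {
      td <- decode_state(t, n)
      p <- 1
      for (i in seq_len(n)) p <- p * probs[[i]][td[i] + 1]
      P[s + 1, t + 1] <- p
    }
  }
  P
}

## finite-horizon backward induction on oracle transition matrices
oracle_optimal_value <- function(model, horizon) {
  n <- model$network$n_nodes
  S <- 3^n
  P <- lapply(0:n, function(a) oracle_transition_matrix(model, a))
  R <- vapply(0:n, function(a) {
    vapply(0:(S - 1), function(s) reward(s, a, model), numeric(1))
  }, numeric(S))
  V <- numeric(S)
  for (t in seq_len(horizon)) {
    Q <- vapply(seq_len(n + 1), function(k) {
      R[, k] + model$discount * drop(P[[k]] %*% V)
    }, numeric(S))
    V <- do.call(pmax, lapply(seq_len(n + 1), function(k) Q[, k]))
  }
  V
}

## finite-horizon evaluation of a fixed policy on oracle matrices
oracle_policy_value <- function(model, actions, horizon) {
  n <- model$network$n_nodes
  S <- 3^n
  P <- lapply(0:n, function(a) oracle_transition_matrix(model, a))
  R <- vapply(0:n, function(a) {
    vapply(0:(S - 1), function(s) reward(s, a, model), numeric(1))
  }, numeric(S))
  V <- numeric(S)
  idx <- cbind(seq_len(S), actions + 1L)
  Ppi <- matrix(0, S, S)
  for (s in seq_len(S)) Ppi[s, ] <- P[[actions[s] + 1L]][s, ]
  Rpi <- R[idx]
  for (t in seq_len(horizon)) V <- Rpi + model$discount * drop(Ppi %*% V)
  V
}

## ---- small model builders ----

two_node_model <- function(p_d, p_r, u_d, u_r, discount = 0.9, cost = 0.1) {
  net <- actor_network(2, data.frame(from = 1, to = 2),
                       u_r = u_r, u_d = u_d)
  sp <- species_distribution(matrix(c(1, 0, 1, 1), 2, 2))
  decision_model(net, sp, behavior_params(p_d, p_r),
                 discount = discount, cost = cost)
}

three_node_model <- function(kind = "star", u = 0.8, seed = 11,
                             discount = 0.9, cost = 0.1) {
  net <- motif_network(kind, 3, u_r = u, u_d = u)
  sp <- netreserve:::with_seed(seed,
    generate_species_distribution(5, 3, 0.6))
  decision_model(net, sp, behavior_params(),
                 discount = discount, cost = cost)
}
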