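#' Encode and decode system states
#'
#' A joint state assigns each node one of available (0), developed (1) or
#' reserved (2). States are encoded canonically as base-3 integers with
#' node 1 the least significant digit, so the all-available state is 0 and
#' there are `3^n` codes `0..3^n - 1`.
#'
#' @param states Integer vector of per-node digits in `{0, 1, 2}`, or a
#'   character vector over `"A"`, `"D"`, `"R"`.
#' @return `encode_state()`: a single integer code. `decode_state()`: an
#'   integer vector of per-node digits.
#' @export
#' @examples
#' encode_state(c("D", "A", "A"))  # 1
#' decode_state(1, 3)
encode_state <- function(states) {
  if (is.character(states)) {
    states <- match(states, c("A", "D", "R")) - 1L
  }
  states <- as.integer(states)
  if (anyNA(states) || any(states < 0L | states > 2L)) {
    stop("States must be 0/1/2 or A/D/R.", call. = FALSE)
  }
  as.integer(sum(states * 3^(seq_along(states) - 1)))
}

#' @param code Integer state code in `0..3^n - 1`.
#' @param n Number of nodes.
#' @rdname encode_state
#' @export
decode_state <- function(code, n) {
  code <- as.integer(code)
  if (length(code) != 1L || is.na(code) || code < 0L || code >= 3^n) {
    stop("State code out of range for ", n, " nodes.", call. = FALSE)
  }
  as.integer(code %/% 3^(0:(n - 1)) %% 3)
}

#' @param digits Integer vector of per-node digits.
#' @rdname encode_state
#' @export
state_labels <- function(digits) {
  paste(c("A", "D", "R")[digits + 1L], collapse = "")
}

## S x n matrix of per-node digits for all 3^n codes (row s = code s - 1)
state_digits <- function(n) {
  S <- 3^n
  vapply(0:(n - 1), function(i) as.integer((0:(S - 1)) %/% 3^i %% 3),
         integer(S))
}

#' Decision model for sequencing interventions
#'
#' Couples an [actor_network()] with a [species_distribution()] over its
#' nodes and the behavioral parameters into a factored Markov decision
#' process. At each step the decision maker either does nothing (action 0)
#' or targets a single actor `i` for an intervention (action `i`), paying a
#' notional cost `cost` in species-representation units. The objective is
#' the expected discounted sum of the number of species represented in
#' reserved sites, with the reward accrued on the pre-transition state.
#'
#' The exact planner enumerates all `3^n` joint states, so models are
#' limited to `n <= 8` nodes; larger networks are refused.
#'
#' @param network An [actor_network()].
#' @param species A [species_distribution()] whose site count equals the
#'   node count.
#' @param params A [behavior_params()].
#' @param discount Discount factor in `(0, 1)`.
#' @param cost Per-intervention cost (nonnegative, species units).
#' @return An object of class `decision_model`.
#' @export
decision_model <- function(network, species, params = behavior_params(),
                           discount = 0.95, cost = 0.1) {
  stopifnot(inherits(network, "actor_network"),
            inherits(species, "species_distribution"),
            inherits(params, "behavior_params"))
  if (nrow(species$incidence) != network$n_nodes) {
    stop("Species distribution has ", nrow(species$incidence),
         " sites but the network has ", network$n_nodes, " nodes.",
         call. = FALSE)
  }
  if (discount <= 0 || discount >= 1) {
    stop("`discount` must lie strictly in (0, 1).", call. = FALSE)
  }
  if (cost < 0) stop("`cost` must be nonnegative.", call. = FALSE)
  if (network$n_nodes > 8) {
    stop("Exact planning enumerates 3^n states and is limited to 8 nodes; ",
         "got ", network$n_nodes, ". Approximate planning for larger ",
         "networks is out of scope.", call. = FALSE)
  }
  structure(
    list(network = network, species = species, params = params,
         discount = discount, cost = cost),
    class = "decision_model"
  )
}

#' @export
print.decision_model <- function(x, ...) {
  cat("<decision_model> ", x$network$n_nodes, " nodes, ",
      ncol(x$species$incidence), " species, gamma = ", x$discount,
      ", cost = ", x$cost, "\n", sep = "")
  invisible(x)
}

## vector over all states of the number of species covered by reserves
coverage_counts <- function(model) {
  digits <- state_digits(model$network$n_nodes)
  reserved <- (digits == 2) * 1
  rowSums((reserved %*% model$species$incidence) > 0)
}

## S x (n + 1) reward matrix, column a + 1 for action a
reward_matrix <- function(model) {
  cov <- coverage_counts(model)
  n <- model$network$n_nodes
  vapply(0:n, function(a) cov - model$cost * (a > 0), numeric(length(cov)))
}

#' Immediate reward
#'
#' The number of species with at least one presence at a reserved node in
#' `state` (each species counted once), minus the intervention cost when
#' `action != 0`.
#'
#' @param state Encoded state or per-node vector.
#' @param action `0` (no-op) or a node index.
#' @param model A [decision_model()].
#' @return Numeric scalar.
#' @export
reward <- function(state, action, model) {
  n <- model$network$n_nodes
  digs <- if (length(state) == 1 && is.numeric(state)) {
    decode_state(state, n)
  } else if (is.character(state)) {
    match(state, c("A", "D", "R")) - 1L
  } else {
    as.integer(state)
  }
  covered <- colSums(model$species$incidence[digs == 2L, , drop = FALSE]) > 0
  sum(covered) - model$cost * (action > 0)
}

new_value_function <- function(v, iterations, residual, converged) {
  structure(list(v = v, iterations = iterations, residual = residual,
                 converged = converged),
            class = "value_function")
}

#' @export
print.value_function <- function(x, ...) {
  cat("<value_function> ", length(x$v), " states; V(all-available) = ",
      signif(x$v[1], 6), "; ", x$iterations, " iterations, residual ",
      format(x$residual, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Value iteration
#'
#' Solves the infinite-horizon discounted criterion by successive Bellman
#' updates over all `3^n` states until the sup-norm residual drops below
#' `tol`. Because the Bellman operator is a `discount`-contraction, the
#' returned fixed-point approximation satisfies
#' `max |V - V*| <= tol * discount / (1 - discount)`.
#'
#' @param model A [decision_model()].
#' @param tol Sup-norm Bellman residual at convergence.
#' @param max_iter Iteration cap; exceeding it is an explicit error that
#'   reports the last residual.
#' @param P Optional precomputed transition matrices (internal reuse).
#' @return A `value_function` object.
#' @export
value_iteration <- function(model, tol = 1e-6, max_iter = 2000, P = NULL) {
  if (is.null(P)) P <- transition_matrices(model)
  R <- reward_matrix(model)
  gam <- model$discount
  V <- numeric(nrow(R))
  res <- Inf
  for (it in seq_len(max_iter)) {
    Q <- vapply(seq_along(P), function(k) R[, k] + gam * drop(P[[k]] %*% V),
                numeric(length(V)))
    Vn <- do.call(pmax, lapply(seq_len(ncol(Q)), function(k) Q[, k]))
    res <- max(abs(Vn - V))
    V <- Vn
    if (res <= tol) {
      return(new_value_function(V, it, res, TRUE))
    }
  }
  stop("Value iteration did not converge within ", max_iter,
       " iterations (residual ", format(res, digits = 4), ").",
       call. = FALSE)
}

new_policy <- function(actions, n_nodes) {
  structure(list(actions = as.integer(actions), n_nodes = n_nodes),
            class = "policy")
}

#' @export
print.policy <- function(x, ...) {
  cat("<policy> ", length(x$actions), " states, ", x$n_nodes,
      " nodes; action at all-available: ", x$actions[1], "\n", sep = "")
  invisible(x)
}

## normalize a policy specification to a function code -> action
policy_function <- function(policy) {
  if (inherits(policy, "policy")) {
    acts <- policy$actions
    function(code) acts[code + 1L]
  } else if (is.function(policy)) {
    policy
  } else if (is.numeric(policy)) {
    acts <- as.integer(policy)
    function(code) acts[code + 1L]
  } else {
    stop("Unsupported policy specification.", call. = FALSE)
  }
}

#' Greedy policy from a value function
#'
#' One-step lookahead: at each state pick the action maximizing the
#' expected backup `R(s, a) + discount * E[V(s')]`. Ties are broken toward
#' the no-op action, then toward the lowest node index.
#'
#' @param model A [decision_model()].
#' @param V A `value_function` or numeric value vector over states.
#' @param P Optional precomputed transition matrices.
#' @return A `policy` object mapping every state to an action.
#' @export
greedy_policy <- function(model, V, P = NULL) {
  if (inherits(V, "value_function")) V <- V$v
  if (is.null(P)) P <- transition_matrices(model)
  R <- reward_matrix(model)
  Q <- vapply(seq_along(P), function(k) R[, k] + model$discount *
                drop(P[[k]] %*% V), numeric(length(V)))
  new_policy(max.col(Q, ties.method = "first") - 1L, model$network$n_nodes)
}

#' Exact policy evaluation
#'
#' Solves the linear fixed point `V = R_pi + discount * P_pi V` by a direct
#' dense solve; for `discount < 1` the system is always nonsingular.
#'
#' @param model A [decision_model()].
#' @param policy A `policy` (or integer action vector over states).
#' @param P Optional precomputed transition matrices.
#' @return A `value_function` (with `iterations = 1`, direct solve).
#' @export
evaluate_policy_exact <- function(model, policy, P = NULL) {
  if (is.null(P)) P <- transition_matrices(model)
  acts <- if (inherits(policy, "policy")) policy$actions else
    as.integer(policy)
  S <- nrow(P[[1]])
  stopifnot(length(acts) == S)
  R <- reward_matrix(model)
  Pp <- matrix(0, S, S)
  Rp <- numeric(S)
  for (a in unique(acts)) {
    idx <- which(acts == a)
    Pp[idx, ] <- P[[a + 1L]][idx, , drop = FALSE]
    Rp[idx] <- R[idx, a + 1L]
  }
  V <- solve(diag(S) - model$discount * Pp, Rp)
  new_value_function(V, 1L, 0, TRUE)
}

#' Solve a decision model for the optimal policy
#'
#' `method = "policy_iteration"` (default) runs Howard policy iteration
#' with exact evaluation and a tie-aware improvement step (an action is
#' changed only when strictly better than the incumbent by `tie_tol`), which
#' terminates at an exactly optimal policy in finitely many steps.
#' `method = "value_iteration"` runs [value_iteration()] to `tol` and
#' extracts the greedy policy.
#'
#' @param model A [decision_model()].
#' @param method `"policy_iteration"` or `"value_iteration"`.
#' @param tol Residual tolerance for value iteration.
#' @param tie_tol Strict-improvement margin for policy iteration.
#' @param max_iter Iteration cap.
#' @param P Optional precomputed transition matrices.
#' @return An object of class `policy_solution` with elements `policy`,
#'   `value` (a `value_function`), `method`, `iterations` and `model`.
#' @export
solve_decision_model <- function(model,
                                 method = c("policy_iteration",
                                            "value_iteration"),
                                 tol = 1e-6, tie_tol = 1e-9, max_iter = 100,
                                 P = NULL) {
  method <- match.arg(method)
  if (is.null(P)) P <- transition_matrices(model)
  if (method == "value_iteration") {
    V <- value_iteration(model, tol = tol, max_iter = max(max_iter, 2000),
                         P = P)
    pol <- greedy_policy(model, V, P = P)
    Vexact <- evaluate_policy_exact(model, pol, P = P)
    out <- list(policy = pol, value = Vexact, method = method,
                iterations = V$iterations, model = model)
    class(out) <- "policy_solution"
    return(out)
  }
  R <- reward_matrix(model)
  gam <- model$discount
  S <- nrow(R)
  pol <- greedy_policy(model, numeric(S), P = P)$actions
  V <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    V <- evaluate_policy_exact(model, pol, P = P)$v
    Q <- vapply(seq_along(P), function(k) R[, k] + gam * drop(P[[k]] %*% V),
                numeric(S))
    best <- max.col(Q, ties.method = "first") - 1L
    improve <- Q[cbind(seq_len(S), best + 1L)] >
      Q[cbind(seq_len(S), pol + 1L)] + tie_tol
    if (!any(improve)) {
      converged <- TRUE
      break
    }
    pol[improve] <- best[improve]
  }
  if (!converged) {
    stop("Policy iteration did not converge within ", max_iter,
         " improvement sweeps.", call. = FALSE)
  }
  out <- list(policy = new_policy(pol, model$network$n_nodes),
              value = new_value_function(V, it, 0, TRUE),
              method = method, iterations = it, model = model)
  class(out) <- "policy_solution"
  out
}

#' @export
print.policy_solution <- function(x, ...) {
  cat("<policy_solution> via ", x$method, " (", x$iterations,
      " iterations)\n", sep = "")
  cat("  V(all-available) = ", signif(x$value$v[1], 6),
      "; first action: ",
      if (x$policy$actions[1] == 0) "no-op" else
        paste0("intervene at node ", x$policy$actions[1]), "\n", sep = "")
  invisible(x)
}

#' Tidy a solved policy into a state table
#'
#' @param x A `policy_solution`.
#' @param ... Unused.
#' @return Tibble with one row per state: `state` (encoded), `state_labels`
#'   (node 1 first), `target` (0-based targeted node id, `NA` for no-op)
#'   and `value`.
#' @method tidy policy_solution
#' @export
tidy.policy_solution <- function(x, ...) {
  n <- x$model$network$n_nodes
  digits <- state_digits(n)
  tibble::tibble(
    state = 0:(3^n - 1),
    state_labels = apply(digits, 1, state_labels),
    target = ifelse(x$policy$actions == 0L, NA_integer_,
                    x$policy$actions - 1L),
    value = x$value$v
  )
}

#' @rdname tidy.policy_solution
#' @return `glance()`: a one-row tibble with solver metadata and the value
#'   at the all-available state.
#' @method glance policy_solution
#' @export
glance.policy_solution <- function(x, ...) {
  tibble::tibble(
    method = x$method, iterations = x$iterations,
    n_states = length(x$value$v),
    v_initial = x$value$v[1],
    first_target = ifelse(x$policy$actions[1] == 0L, NA_integer_,
                          x$policy$actions[1] - 1L)
  )
}
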