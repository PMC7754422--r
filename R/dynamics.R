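#' Behavioral parameters
#'
#' `p_d` is the per-step probability that an available actor decides to
#' develop independently of the network; `p_r` is the per-step probability
#' that an available actor decides to reserve when (and only when) an
#' intervention targets them. Network influence enters separately through
#' per-link strengths `u_d`, `u_r` carried by the [actor_network()].
#'
#' @param p_d,p_r Probabilities in `[0, 1]`.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(p_d = 0.2, p_r = 0.2) {
  stopifnot(p_d >= 0, p_d <= 1, p_r >= 0, p_r <= 1)
  structure(list(p_d = p_d, p_r = p_r), class = "behavior_params")
}

#' Neighborhood context of an available actor
#'
#' Summarizes the influence an actor receives from its neighbors:
#' `developed_stay` is the product of `(1 - u_d_ij)` over developed
#' neighbors `j` (the probability that no developed neighbor transmits the
#' development behavior this step) and `reserved_stay` the analogous
#' product over reserved neighbors. With homogeneous strengths these
#' collapse to `(1 - u_d)^n_d` and `(1 - u_r)^n_r`.
#'
#' @param n_dev,n_res Neighbor counts in the developed/reserved state
#'   (used with the homogeneous strengths `u_d`, `u_r`).
#' @param u_d,u_r Homogeneous link strengths.
#' @param intervened Whether an intervention targets the actor this step.
#' @param developed_stay,reserved_stay Directly supplied stay-products,
#'   overriding the homogeneous form (for heterogeneous links).
#' @return An object of class `neighborhood_context`.
#' @export
neighborhood_context <- function(n_dev = 0, n_res = 0, u_d = 0, u_r = 0,
                                 intervened = FALSE,
                                 developed_stay = NULL,
                                 reserved_stay = NULL) {
  if (is.null(developed_stay)) developed_stay <- (1 - u_d)^n_dev
  if (is.null(reserved_stay)) reserved_stay <- (1 - u_r)^n_res
  stopifnot(developed_stay >= 0, developed_stay <= 1,
            reserved_stay >= 0, reserved_stay <= 1)
  structure(list(developed_stay = developed_stay,
                 reserved_stay = reserved_stay,
                 intervened = isTRUE(intervened)),
            class = "neighborhood_context")
}

#' Per-node transition distribution
#'
#' The stochastic kernel for a single actor/site over the states available
#' (`A`), developed (`D`) and reserved (`R`). `D` and `R` are absorbing.
#' From `A` the development hazard combines the intrinsic propensity and
#' neighbor influences as independent triggers,
#' \eqn{q_d = 1 - (1 - p_d)\prod_j(1 - u_{d,ij})}, and the reservation
#' hazard \eqn{q_r = 1 - (1 - p_r)\prod_j(1 - u_{r,ij})} is active only
#' under an intervention. When both latent events fire, reservation takes
#' precedence (the intervention actively facilitates it), so with an
#' intervention `P(A->R) = q_r`, `P(A->D) = (1 - q_r) q_d` and
#' `P(A->A) = (1 - q_r)(1 - q_d)`; without one, `P(A->R) = 0`.
#'
#' @param state `"A"`, `"D"` or `"R"`.
#' @param ctx A [neighborhood_context()].
#' @param params A [behavior_params()].
#' @return Named numeric vector `c(A=, D=, R=)` summing to 1.
#' @export
#' @examples
#' node_transition_distribution("A", neighborhood_context(), behavior_params())
node_transition_distribution <- function(state, ctx, params) {
  stopifnot(inherits(ctx, "neighborhood_context"),
            inherits(params, "behavior_params"))
  state <- match.arg(state, c("A", "D", "R"))
  if (state == "D") return(c(A = 0, D = 1, R = 0))
  if (state == "R") return(c(A = 0, D = 0, R = 1))
  q_d <- 1 - (1 - params$p_d) * ctx$developed_stay
  if (!ctx$intervened) {
    return(c(A = 1 - q_d, D = q_d, R = 0))
  }
  q_r <- 1 - (1 - params$p_r) * ctx$reserved_stay
  c(A = (1 - q_r) * (1 - q_d), D = (1 - q_r) * q_d, R = q_r)
}

## Vectorized per-node kernels over the whole state space.
## Returns S x n matrices PA/PD/PR for the no-intervention case and for the
## intervened case; digits is the S x n matrix of node states (0=A,1=D,2=R).
node_kernels <- function(digits, strengths, params) {
  Ud <- strengths$u_d
  Ur <- strengths$u_r
  Dev <- (digits == 1) * 1
  Res <- (digits == 2) * 1
  Ld <- ifelse(Ud < 1, log1p(-Ud), 0)
  Zd <- (Ud == 1) * 1
  Lr <- ifelse(Ur < 1, log1p(-Ur), 0)
  Zr <- (Ur == 1) * 1
  stayD <- exp(Dev %*% Ld) * ((Dev %*% Zd) == 0)
  stayR <- exp(Res %*% Lr) * ((Res %*% Zr) == 0)
  qd <- 1 - (1 - params$p_d) * stayD
  qr <- 1 - (1 - params$p_r) * stayR
  isA <- digits == 0
  isD <- digits == 1
  isR <- digits == 2
  list(
    no = list(PA = isA * (1 - qd),
              PD = isA * qd + isD,
              PR = isR * 1),
    int = list(PA = isA * (1 - qr) * (1 - qd),
               PD = isA * (1 - qr) * qd + isD,
               PR = isA * qr + isR)
  )
}

## Dense per-action transition matrices P[[a + 1]][s, s'] for a = 0..n.
## Built by elementwise products of per-node column gathers; prefix/suffix
## products avoid recomputing the shared no-intervention factors.
transition_matrices <- function(model) {
  n <- model$network$n_nodes
  digits <- state_digits(n)
  K <- node_kernels(digits, strength_matrices(model$network), model$params)
  gather <- function(k, i) {
    cbind(k$PA[, i], k$PD[, i], k$PR[, i])[, digits[, i] + 1L]
  }
  Mno <- lapply(seq_len(n), function(i) gather(K$no, i))
  pre <- vector("list", n)
  suf <- vector("list", n)
  pre[[1]] <- Mno[[1]]
  for (i in seq_len(n)[-1]) pre[[i]] <- pre[[i - 1]] * Mno[[i]]
  suf[[n]] <- Mno[[n]]
  for (i in rev(seq_len(n - 1))) suf[[i]] <- suf[[i + 1]] * Mno[[i]]
  P <- vector("list", n + 1)
  P[[1]] <- pre[[n]]
  for (a in seq_len(n)) {
    M <- gather(K$int, a)
    if (a > 1) M <- M * pre[[a - 1]]
    if (a < n) M <- M * suf[[a + 1]]
    P[[a + 1]] <- M
  }
  P
}

#' Joint transition distribution of the full system
#'
#' The factored system kernel: all nodes update synchronously, each from
#' its own [node_transition_distribution()] conditioned on the same
#' pre-transition joint state; only the targeted node (if any) has its
#' intervention flag set. The joint probability of a successor state is the
#' product of the per-node probabilities, so the support is limited to
#' states reachable by per-node moves.
#'
#' @param state Encoded system state (see [encode_state()]) or a per-node
#'   state vector.
#' @param action `0` for no intervention, or a node index `1..n`.
#' @param model A [decision_model()].
#' @return Tibble with columns `state` (successor codes) and `prob`,
#'   summing to 1.
#' @export
system_transition_distribution <- function(state, action, model) {
  n <- model$network$n_nodes
  digs <- if (length(state) == 1) decode_state(state, n) else as.integer(state)
  stopifnot(length(digs) == n, all(digs %in% 0:2))
  action <- as.integer(action)
  if (action < 0 || action > n) stop("Invalid action.", call. = FALSE)
  strengths <- strength_matrices(model$network)
  dev <- digs == 1L
  res <- digs == 2L
  per_node <- lapply(seq_len(n), function(i) {
    ctx <- neighborhood_context(
      developed_stay = prod(1 - strengths$u_d[i, dev]),
      reserved_stay = prod(1 - strengths$u_r[i, res]),
      intervened = action == i
    )
    node_transition_distribution(c("A", "D", "R")[digs[i] + 1L], ctx,
                                 model$params)
  })
  ## outer product over per-node supports
  acc <- data.frame(code = 0, prob = 1)
  for (i in seq_len(n)) {
    pr <- per_node[[i]]
    keep <- which(pr > 0)
    acc <- do.call(rbind, lapply(keep, function(k) {
      data.frame(code = acc$code + (k - 1L) * 3^(i - 1),
                 prob = acc$prob * pr[k])
    }))
  }
  out <- tibble::tibble(state = as.integer(acc$code), prob = acc$prob)
  dplyr::arrange(out, .data$state)
}

#' Simulate a trajectory under a policy
#'
#' Synchronous stochastic simulation of the network: at each step the
#' policy chooses an action from the current joint state, the per-step
#' reward is accrued on the pre-transition state, and every node draws its
#' next state from its own kernel conditioned on that same pre-step state.
#'
#' @param model A [decision_model()].
#' @param policy A `policy` object (see [greedy_policy()]), an integer
#'   vector of actions indexed by `state + 1`, or a function
#'   `(state_code) -> action`.
#' @param horizon Number of steps (at least 1).
#' @param init Initial state code (default: all available).
#' @return Tidy tibble with one row per step and node: columns `step`
#'   (0-based), `node`, `state` (`"A"/"D"/"R"` at the start of the step),
#'   `action` (the targeted node or `NA` for no-op) and `reward`.
#' @export
simulate_trajectory <- function(model, policy, horizon, init = 0L) {
  stopifnot(horizon >= 1)
  n <- model$network$n_nodes
  strengths <- strength_matrices(model$network)
  act_fun <- policy_function(policy)
  digs <- decode_state(init, n)
  labels <- c("A", "D", "R")
  rows <- vector("list", horizon)
  for (t in seq_len(horizon)) {
    code <- encode_state(digs)
    a <- act_fun(code)
    rew <- reward(code, a, model)
    nxt <- integer(n)
    dev <- digs == 1L
    res <- digs == 2L
    for (i in seq_len(n)) {
      ctx <- neighborhood_context(
        developed_stay = prod(1 - strengths$u_d[i, dev]),
        reserved_stay = prod(1 - strengths$u_r[i, res]),
        intervened = a == i
      )
      pr <- node_transition_distribution(labels[digs[i] + 1L], ctx,
                                         model$params)
      nxt[i] <- sample.int(3L, 1L, prob = pr) - 1L
    }
    rows[[t]] <- tibble::tibble(
      step = t - 1L, node = seq_len(n), state = labels[digs + 1L],
      action = if (a == 0) NA_integer_ else a, reward = rew
    )
    digs <- nxt
  }
  dplyr::bind_rows(rows)
}
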