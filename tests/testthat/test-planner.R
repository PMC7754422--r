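test_that("state encoding is a base-3 bijection with node 1 least significant", {
  expect_equal(encode_state(rep(0L, 6)), 0L)
  expect_equal(encode_state(c(1L, rep(0L, 5))), 1L)
  expect_equal(encode_state(c("D", "A", "A")), 1L)
  for (code in 0:728) {
    expect_identical(encode_state(decode_state(code, 6)), code)
  }
  expect_error(decode_state(729, 6), "out of range")
  expect_error(decode_state(-1, 6), "out of range")
  expect_error(encode_state(c(0, 3)), "0/1/2")
  expect_equal(state_labels(c(0L, 1L, 2L)), "ADR")
})

test_that("reward counts represented species once, minus intervention cost", {
  net <- motif_network("line", 4)
  inc <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 1, 1), c(0, 0, 1))
  m <- decision_model(net, species_distribution(inc), behavior_params(),
                      cost = 0.25)
  expect_equal(reward(0L, 0L, m), 0)
  ## nodes 1 and 3 reserved: species {1,2} u {2,3} counted once each
  expect_equal(reward(encode_state(c(2, 0, 2, 0)), 0L, m), 3)
  expect_equal(reward(encode_state(c(1, 1, 1, 1)), 2L, m), -0.25)
})

test_that("single-node closed form: certain reservation is worth gamma/(1-gamma)", {
  m <- decision_model(actor_network(1), species_distribution(matrix(1, 1, 1)),
                      behavior_params(p_d = 0.2, p_r = 1),
                      discount = 0.9, cost = 0)
  V <- value_iteration(m, tol = 1e-10)
  expect_equal(V$v[1], 9, tolerance = 1e-7)
  pol <- greedy_policy(m, V)
  expect_equal(pol$actions[1], 1L)  # intervene in state A
  sol <- solve_decision_model(m)
  expect_equal(sol$value$v[1], 9, tolerance = 1e-9)
})

test_that("with no species the planner does nothing and earns nothing", {
  m <- decision_model(motif_network("ring", 3, 0.5, 0.5),
                      species_distribution(matrix(integer(0), 3, 0)),
                      behavior_params(), cost = 0.1)
  sol <- solve_decision_model(m)
  expect_true(all(sol$value$v <= 1e-9))
  expect_true(all(sol$policy$actions == 0L))
})

test_that("value iteration matches the truncated-horizon oracle on 2 nodes", {
  corners <- expand.grid(p_d = c(0, 0.5), p_r = c(0, 0.5),
                         u_d = c(0, 0.5), u_r = c(0, 0.5))
  for (i in seq_len(nrow(corners))) {
    cr <- corners[i, ]
    m <- two_node_model(cr$p_d, cr$p_r, cr$u_d, cr$u_r, discount = 0.9)
    V <- value_iteration(m, tol = 1e-9)
    Voracle <- oracle_optimal_value(m, horizon = 300)
    expect_lt(max(abs(V$v - Voracle)), 1e-6)
  }
})

test_that("value iteration residuals contract and the cap is enforced", {
  m <- two_node_model(0.3, 0.3, 0.5, 0.5, discount = 0.95)
  expect_error(value_iteration(m, tol = 1e-12, max_iter = 3),
               "did not converge")
  V <- value_iteration(m, tol = 1e-8)
  expect_true(V$converged)
  expect_lte(V$residual, 1e-8)
})

test_that("greedy policy of the optimal value is Bellman-consistent", {
  m <- three_node_model("star", u = 0.6)
  sol <- solve_decision_model(m)
  V2 <- evaluate_policy_exact(m, greedy_policy(m, sol$value))
  expect_equal(V2$v, sol$value$v, tolerance = 1e-8)
  ## all-developed start: absorbing, nothing reserved, zero value at c = 0
  m0 <- decision_model(m$network, m$species, m$params, cost = 0)
  sol0 <- solve_decision_model(m0)
  expect_equal(sol0$value$v[encode_state(c(1, 1, 1)) + 1], 0,
               tolerance = 1e-10)
})

test_that("policy iteration and value iteration find the same solution", {
  m <- three_node_model("line", u = 0.7)
  s_pi <- solve_decision_model(m, method = "policy_iteration")
  s_vi <- solve_decision_model(m, method = "value_iteration", tol = 1e-9)
  expect_equal(s_pi$value$v, s_vi$value$v, tolerance = 1e-6)
})

test_that("optimal value dominates every stationary policy on 2 nodes", {
  m <- two_node_model(0.5, 0.5, 0.5, 0.5, discount = 0.9, cost = 0.1)
  P <- netreserve:::transition_matrices(m)
  sol <- solve_decision_model(m, P = P)
  ## exhaustive enumeration of all 3^9 stationary deterministic policies
  all_pols <- expand.grid(rep(list(0:2), 9))
  for (i in seq_len(nrow(all_pols))) {
    acts <- as.integer(all_pols[i, ])
    v <- evaluate_policy_exact(m, acts, P = P)$v
    expect_true(all(sol$value$v - v >= -1e-8))
  }
})

test_that("exact policy evaluation agrees with Monte-Carlo returns", {
  m <- three_node_model("ring", u = 0.5, discount = 0.9)
  sol <- solve_decision_model(m)
  v_exact <- sol$value$v[1]
  horizon <- 120  # 0.9^120 * V_max ~ 1e-4
  acts <- sol$policy$actions
  returns <- netreserve:::with_seed(31, {
    str <- netreserve:::strength_matrices(m$network)
    vapply(seq_len(2000), function(rep) {
      digs <- rep(0L, 3)
      total <- 0
      for (t in seq_len(horizon)) {
        code <- encode_state(digs)
        a <- acts[code + 1L]
        total <- total + m$discount^(t - 1) * reward(code, a, m)
        dev <- digs == 1L
        res <- digs == 2L
        digs <- vapply(1:3, function(i) {
          pr <- node_transition_distribution(
            c("A", "D", "R")[digs[i] + 1L],
            neighborhood_context(
              developed_stay = prod(1 - str$u_d[i, dev]),
              reserved_stay = prod(1 - str$u_r[i, res]),
              intervened = a == i),
            m$params)
          sample.int(3L, 1L, prob = pr) - 1L
        }, integer(1))
      }
      total
    }, numeric(1))
  })
  se <- stats::sd(returns) / sqrt(length(returns))
  expect_lt(abs(mean(returns) - v_exact), 3 * se + 1e-3)
})

test_that("optimal policy is invariant to species relabeling and padding", {
  m <- three_node_model("star", u = 0.8)
  sol <- solve_decision_model(m)
  ## permute species columns
  perm <- c(3, 1, 5, 2, 4)
  sp2 <- species_distribution(m$species$incidence[, perm])
  m2 <- decision_model(m$network, sp2, m$params, discount = m$discount,
                       cost = m$cost)
  sol2 <- solve_decision_model(m2)
  expect_identical(sol$policy$actions, sol2$policy$actions)
  expect_equal(sol$value$v, sol2$value$v, tolerance = 1e-9)
  ## duplicating a species column cannot decrease the optimal value
  sp3 <- species_distribution(cbind(m$species$incidence,
                                    m$species$incidence[, 1]))
  m3 <- decision_model(m$network, sp3, m$params, discount = m$discount,
                       cost = m$cost)
  sol3 <- solve_decision_model(m3)
  expect_true(all(sol3$value$v - sol$value$v >= -1e-8))
})

test_that("models beyond 8 nodes are refused", {
  net <- motif_network("ring", 9)
  sp <- species_distribution(matrix(1, 9, 2))
  expect_error(decision_model(net, sp, behavior_params()), "limited to 8")
})

test_that("tidy and glance expose the policy table and solver metadata", {
  m <- three_node_model("line", u = 0.4)
  sol <- solve_decision_model(m)
  td <- tidy(sol)
  expect_equal(nrow(td), 27)
  expect_equal(td$state, 0:26)
  expect_true(all(nchar(td$state_labels) == 3))
  expect_true(all(is.na(td$target) | td$target %in% 0:2))
  gl <- glance(sol)
  expect_equal(gl$n_states, 27)
  expect_equal(gl$v_initial, sol$value$v[1])
})
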