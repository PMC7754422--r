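test_that("node kernel reproduces the cascade formulas", {
  p <- behavior_params(0.2, 0.2)
  ## lone available actor, no intervention: develops with p_d
  expect_equal(node_transition_distribution("A", neighborhood_context(), p),
               c(A = 0.8, D = 0.2, R = 0))
  ## two developed neighbors at u_d = 0.5: q_d = 1 - 0.8 * 0.25
  tr <- node_transition_distribution(
    "A", neighborhood_context(n_dev = 2, u_d = 0.5), p)
  expect_equal(unname(tr["D"]), 0.8)
  ## intervened with one reserved neighbor at u_r = 0.5: q_r = 0.6,
  ## q_d = 0.2, reserve precedence
  tr <- node_transition_distribution(
    "A", neighborhood_context(n_res = 1, u_r = 0.5, intervened = TRUE), p)
  expect_equal(tr, c(A = 0.32, D = 0.08, R = 0.6))
  ## developed and reserved are absorbing
  expect_equal(node_transition_distribution("D", neighborhood_context(), p),
               c(A = 0, D = 1, R = 0))
  expect_equal(node_transition_distribution("R", neighborhood_context(), p),
               c(A = 0, D = 0, R = 1))
  ## no intervention means no route to R whatever the neighborhood
  tr <- node_transition_distribution(
    "A", neighborhood_context(n_res = 3, u_r = 1), p)
  expect_equal(unname(tr["R"]), 0)
})

test_that("kernel hazards are monotone in parameters", {
  grid <- seq(0, 1, by = 0.25)
  for (p_d in grid) {
    pad <- vapply(grid, function(u) {
      node_transition_distribution(
        "A", neighborhood_context(n_dev = 2, u_d = u),
        behavior_params(p_d, 0.2))["D"]
    }, numeric(1))
    expect_true(all(diff(pad) >= -1e-12))
  }
  for (u_r in grid) {
    par <- vapply(grid, function(p_r) {
      node_transition_distribution(
        "A", neighborhood_context(n_res = 1, u_r = u_r, intervened = TRUE),
        behavior_params(0.2, p_r))["R"]
    }, numeric(1))
    expect_true(all(diff(par) >= -1e-12))
  }
  pad_in_pd <- vapply(grid, function(p_d) {
    node_transition_distribution("A", neighborhood_context(),
                                 behavior_params(p_d, 0))["D"]
  }, numeric(1))
  expect_true(all(diff(pad_in_pd) >= -1e-12))
})

test_that("system distribution is a probability measure on a 3-node ring", {
  m <- three_node_model("ring", u = 0.5)
  for (s in 0:26) {
    for (a in 0:3) {
      dist <- system_transition_distribution(s, a, m)
      expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
      expect_true(all(dist$prob > 0))
      expect_false(anyDuplicated(dist$state) > 0)
    }
  }
  ## all-developed state is absorbing under any action
  all_dev <- encode_state(c(1, 1, 1))
  dist <- system_transition_distribution(all_dev, 2, m)
  expect_equal(dist, tibble::tibble(state = all_dev, prob = 1))
})

test_that("factored transition matrices equal exhaustive enumeration", {
  corners <- expand.grid(p_d = c(0, 0.5), p_r = c(0, 0.5),
                         u_d = c(0, 0.5), u_r = c(0, 0.5))
  for (i in seq_len(nrow(corners))) {
    cr <- corners[i, ]
    for (n in 2:3) {
      net <- if (n == 2) {
        actor_network(2, data.frame(from = 1, to = 2),
                      u_r = cr$u_r, u_d = cr$u_d)
      } else {
        motif_network("line", 3, u_r = cr$u_r, u_d = cr$u_d)
      }
      sp <- species_distribution(diag(n))
      m <- decision_model(net, sp, behavior_params(cr$p_d, cr$p_r))
      P <- netreserve:::transition_matrices(m)
      for (a in 0:n) {
        expect_equal(P[[a + 1]], oracle_transition_matrix(m, a),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("system distribution matches the matrix rows", {
  m <- three_node_model("star", u = 0.7)
  P <- netreserve:::transition_matrices(m)
  for (s in c(0, 5, 13, 26)) {
    for (a in c(0, 1, 3)) {
      dist <- system_transition_distribution(s, a, m)
      row <- P[[a + 1]][s + 1, ]
      expect_equal(dist$prob, unname(row[dist$state + 1]))
      expect_equal(sum(row), 1, tolerance = 1e-12)
      expect_equal(sort(which(row > 0) - 1L), dist$state)
    }
  }
})

test_that("reserved state is unreachable without interventions", {
  ## exhaustive 2-node check at parameter corners: the no-op column of the
  ## transition matrix puts zero mass on any state containing R
  for (p_d in c(0, 0.5, 1)) {
    for (u in c(0, 0.5, 1)) {
      m <- two_node_model(p_d, p_r = 1, u_d = u, u_r = 1)
      P0 <- netreserve:::transition_matrices(m)[[1]]
      has_R <- vapply(0:8, function(s) any(decode_state(s, 2) == 2L),
                      logical(1))
      from_no_R <- !has_R
      expect_true(all(P0[from_no_R, has_R] == 0))
    }
  }
  ## and along simulated trajectories under the no-op policy
  m <- two_node_model(0.5, 1, 0.5, 1)
  traj <- netreserve:::with_seed(4, simulate_trajectory(
    m, function(s) 0L, horizon = 50))
  expect_false(any(traj$state == "R"))
})

test_that("zero hazards freeze the system in the available state", {
  m <- two_node_model(p_d = 0, p_r = 0.5, u_d = 0, u_r = 0.5)
  traj <- netreserve:::with_seed(8, simulate_trajectory(
    m, function(s) 0L, horizon = 30))
  expect_true(all(traj$state == "A"))
})

test_that("one-step simulation frequencies match the kernel", {
  m <- three_node_model("ring", u = 0.6)
  s0 <- 0L
  a <- 1L
  dist <- system_transition_distribution(s0, a, m)
  n_rep <- 10000
  counts <- netreserve:::with_seed(99, {
    draws <- vapply(seq_len(n_rep), function(i) {
      tr <- simulate_trajectory(m, function(s) a, horizon = 2)
      encode_state(match(tr$state[tr$step == 1], c("A", "D", "R")) - 1L)
    }, numeric(1))
    table(factor(draws, levels = dist$state))
  })
  for (k in seq_len(nrow(dist))) {
    p <- dist$prob[k]
    se <- sqrt(p * (1 - p) / n_rep)
    expect_lt(abs(counts[k] / n_rep - p), max(3 * se, 1e-3))
  }
})
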