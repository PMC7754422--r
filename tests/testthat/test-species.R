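test_that("range sizes are uniform on {1..n_sites}", {
  set.seed(1)
  r <- sample_range_sizes(20, 6)
  expect_length(r, 20)
  expect_true(all(r >= 1 & r <= 6))
  expect_true(all(sample_range_sizes(50, 1) == 1))
  ## mean of uniform{1..6} is 3.5; se of the mean over 10,000 draws ~ 0.017
  big <- sample_range_sizes(10000, 6)
  expect_lt(abs(mean(big) - 3.5), 0.06)
})

test_that("species_distribution validates binarity and occupancy", {
  expect_error(species_distribution(matrix(c(0, 2), 1, 2)), "0 or 1")
  expect_error(species_distribution(cbind(c(1, 0), c(0, 0))),
               "at least one site")
  sp <- species_distribution(diag(3))
  expect_equal(sp$range_sizes, rep(1, 3), ignore_attr = TRUE)
})

test_that("discrepancy index matches spec examples and packing oracle", {
  nested <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))
  expect_equal(discrepancy_index(nested), 0)
  expect_equal(discrepancy_index(rbind(c(1, 1, 0), c(0, 0, 1))), 1)
  expect_equal(discrepancy_index(matrix(1, 4, 5)), 0)
})

test_that("discrepancy agrees with brute-force packing on all 3x3 matrices", {
  for (code in 0:511) {
    m <- matrix(as.integer(intToBits(code)[1:9]), 3, 3)
    d <- discrepancy_index(m)
    expect_identical(d, oracle_discrepancy(m))
    ## d = 0 iff every row's presences occupy the top-ranked columns
    ord <- order(colSums(m), decreasing = TRUE)
    nested <- all(vapply(1:3, function(i) {
      r <- sum(m[i, ])
      r == 0 || all(m[i, ord[seq_len(r)]] == 1)
    }, logical(1)))
    expect_identical(d == 0, nested)
  }
})

test_that("discrepancy matches vegan on matrices without column-sum ties", {
  set.seed(3)
  for (rep in 1:10) {
    ## distinct column sums make the packed matrix unique, so the
    ## deterministic tie-break and vegan's tie search must coincide
    repeat {
      m <- matrix(rbinom(35, 1, 0.5), 7, 5)
      if (all(colSums(m) > 0) && all(rowSums(m) > 0) &&
          !anyDuplicated(colSums(m))) break
    }
    expect_equal(discrepancy_index(m),
                 unname(vegan::nesteddisc(m)$statistic))
  }
})

test_that("generator hits phi = 1 exactly and preserves column sums", {
  set.seed(5)
  sp <- generate_species_distribution(20, 6, 1.0)
  expect_equal(discrepancy_index(sp), 0)
  expect_equal(attr(sp, "score"), 1)
  expect_true(attr(sp, "feasible"))
  for (phi in c(0.3, 0.6, 0.9)) {
    ranges <- sample_range_sizes(20, 6)
    sp <- generate_species_distribution(20, 6, phi, range_sizes = ranges)
    expect_equal(unname(colSums(sp$incidence)), ranges)
    expect_true(all(sp$incidence %in% 0:1))
    ## infeasible targets must be flagged, never silent
    expect_identical(attr(sp, "feasible"),
                     abs(attr(sp, "score") - phi) <= 0.02)
  }
})

test_that("achieved nestedness score is monotone in phi in expectation", {
  ## common random numbers: draw i uses the same seed at every phi, so the
  ## comparison is paired and the only difference is the target
  mean_scores <- vapply(c(0.1, 0.5, 1.0), function(phi) {
    mean(vapply(1:40, function(i) {
      netreserve:::with_seed(1700 + i, {
        attr(generate_species_distribution(20, 6, phi), "score")
      })
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_scores) >= 0))
  expect_lt(mean_scores[1], mean_scores[3])
})

test_that("null test p-values behave at the degenerate and nested extremes", {
  ## no swappable checkerboard: every null equals the observed matrix
  m <- rbind(c(1, 0), c(1, 1))
  res <- nestedness_null_test(m, n_perm = 99)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)

  ## a perfectly nested matrix has subset structure between every species
  ## pair, hence no checkerboard unit at all: its null is degenerate too
  nested <- matrix(0L, 6, 10)
  for (s in 1:10) nested[seq_len(max(1, 7 - s)), s] <- 1L
  res <- nestedness_null_test(nested, n_perm = 99)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)

  ## a nearly nested matrix does have checkerboards, and its discrepancy
  ## sits far below the swap-null distribution: small p
  set.seed(9)
  near <- nested
  near[6, 1] <- 0L
  near[6, 8] <- 1L
  near[5, 2] <- 0L
  near[5, 9] <- 1L
  res <- nestedness_null_test(near, n_perm = 199)
  expect_false(res$degenerate)
  expect_lte(res$p_value, 0.05)
  expect_gt(res$p_value, 0)

  expect_error(nestedness_null_test(near, n_perm = 10), "at least 99")
})

test_that("null permutations stay inside the fixed-marginal ensemble", {
  ## every null discrepancy must be attainable by some matrix with the
  ## observed row and column sums (exhaustive enumeration oracle)
  set.seed(21)
  m <- rbind(c(1, 1, 0, 0), c(0, 1, 1, 0), c(1, 0, 0, 1))
  ensemble <- oracle_fixed_marginal_matrices(rowSums(m), colSums(m))
  expect_gt(length(ensemble), 1)
  attainable <- sort(unique(vapply(ensemble, oracle_discrepancy, integer(1))))
  res <- nestedness_null_test(m, n_perm = 199)
  expect_true(all(res$null_discrepancy %in% attainable))
  expect_true(res$p_value > 0 && res$p_value <= 1)
})
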