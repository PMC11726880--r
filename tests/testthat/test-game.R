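test_that("control reference computes mean and n-1 standard deviation", {
  ds <- toy_dataset(rbind(c(5, 5, 1, 2, 3), c(9, 9, 5, 5, 5)), 2, 3)
  ref <- control_reference(ds)
  expect_equal(ref$mean, c(2, 5))
  expect_equal(ref$sd, c(1, 0))
})

test_that("discretization uses inclusive over / strict under boundaries", {
  # control stats: mean 2, sd 1 (controls are 1,2,3)
  vals <- rbind(c(3, 1, 0.99, 1, 2, 3))
  ds <- toy_dataset(vals, 3, 3, genes = "g1")
  ref <- control_reference(ds)
  over <- discretize(ds, ref, "over")
  under <- discretize(ds, ref, "under")
  expect_equal(unname(over$values[1, 1]), 1L)   # x = mean + sd flags (inclusive)
  expect_equal(unname(under$values[1, 2]), 0L)  # x = mean - sd does not (strict)
  expect_equal(unname(under$values[1, 3]), 1L)  # just below flags
  # controls themselves are coded too
  expect_equal(unname(over$values[1, 6]), 1L)
})

test_that("zero-variance genes are non-informative in both directions", {
  vals <- rbind(c(10, -10, 5, 5, 5), c(2, 0, 1, 1.5, 0.5))
  ds <- toy_dataset(vals, 2, 3)
  ref <- control_reference(ds)
  expect_true(all(discretize(ds, ref, "over")$values[1, ] == 0L))
  expect_true(all(discretize(ds, ref, "under")$values[1, ] == 0L))
  # mismatched reference is rejected
  ref2 <- control_reference(subset_genes(ds, "g02"))
  expect_error(discretize(ds, ref2, "over"), class = "cashr_validation_error")
})

test_that("group split is an order-preserving column partition", {
  set.seed(5)
  ds <- toy_dataset(matrix(rnorm(40), 4, 10), 6, 4)
  ref <- control_reference(ds)
  b <- discretize(ds, ref, "over")
  parts <- split_by_group(b, ds$groups)
  expect_equal(dim(parts$case$values), c(4L, 6L))
  expect_equal(dim(parts$control$values), c(4L, 4L))
  expect_identical(cbind(parts$case$values, parts$control$values), b$values)
})

test_that("games record supports and sizes per sample", {
  b <- matrix(c(1, 0, 1, 1), 2, 2, dimnames = list(c("g1", "g2"),
                                                   c("s1", "s2")))
  game <- build_game(b)
  expect_equal(game$supports, list(1L, c(1L, 2L)))
  expect_equal(game$k, c(1L, 2L))
  expect_equal(game$m, 2L)
  zero <- build_game(matrix(0L, 3, 2, dimnames = list(letters[1:3], c("a", "b"))))
  expect_true(all(lengths(zero$supports) == 0))
  one_col <- build_game(matrix(c(1, 0, 1), 3, 1,
                               dimnames = list(c("g1", "g2", "g3"), "s")))
  expect_equal(one_col$supports[[1]], c(1L, 3L))
  expect_error(build_game(matrix(2, 1, 1, dimnames = list("g", "s"))),
               class = "cashr_validation_error")
})

test_that("closed-form Shapley values match the worked examples", {
  b <- matrix(c(1, 0, 1, 1), 2, 2, dimnames = list(c("g1", "g2"),
                                                   c("s1", "s2")))
  expect_equal(shapley(build_game(b)), c(g1 = 0.75, g2 = 0.25))
  # one gene flagged in every sample captures all the worth
  solo <- matrix(1, 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  expect_equal(shapley(build_game(solo)), c(g1 = 1))
  # dummy gene: all-zero row
  dummy <- matrix(c(1, 0, 1, 0), 2, 2, dimnames = list(c("g1", "g2"),
                                                       c("s1", "s2")))
  expect_equal(shapley(build_game(dummy))[["g2"]], 0)
})

test_that("closed form agrees with the coalition-enumeration oracle", {
  # exhaustive on every 2x2 Boolean matrix, then random small games
  for (bits in 0:15) {
    b <- matrix(as.integer(intToBits(bits))[1:4], 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    game <- build_game(b)
    expect_lt(max(abs(shapley(game) - shapley_bruteforce(game))), 1e-12)
  }
  set.seed(99)
  for (i in 1:40) {
    b <- random_boolean_matrix(sample(1:6, 1), sample(1:6, 1))
    game <- build_game(b)
    expect_lt(max(abs(shapley(game) - shapley_bruteforce(game))), 1e-12)
  }
  # 1-gene game: phi = v({g})
  g1 <- build_game(matrix(c(1, 0, 1), 1, 3,
                          dimnames = list("g", paste0("s", 1:3))))
  expect_equal(unname(shapley_bruteforce(g1)), game_value_oracle(g1, 1))
  expect_error(shapley_bruteforce(build_game(random_boolean_matrix(11, 2))),
               class = "cashr_validation_error")
})

test_that("Shapley axioms hold on random games", {
  set.seed(7)
  for (i in 1:200) {
    b <- random_boolean_matrix(sample(2:12, 1), sample(1:8, 1),
                               prob = runif(1, 0.1, 0.9))
    game <- build_game(b)
    phi <- shapley(game)
    # efficiency
    expect_equal(sum(phi), sum(colSums(b) > 0) / ncol(b), tolerance = 1e-12)
    # dummy
    expect_true(all(phi[rowSums(b) == 0] == 0))
    # symmetry
    dup <- rbind(b, b[1, , drop = FALSE])
    rownames(dup) <- c(rownames(b), "twin")
    phi_dup <- shapley(build_game(dup))
    expect_equal(unname(phi_dup[1]), unname(phi_dup["twin"]))
    # monotonicity: turning on one extra bit never lowers that gene's value
    zeros <- which(b == 0)
    if (length(zeros)) {
      b2 <- b
      b2[zeros[sample.int(length(zeros), 1)]] <- 1L
      g <- arrayInd(which(b != b2), dim(b))[1]
      expect_gte(shapley(build_game(b2))[g], phi[g])
    }
  }
})
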