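test_that("kabsch_rotation recovers exact rotations and beats random sampling", {
  local_seed(41, {
    X <- matrix(runif(15, -2, 2), 5)
    X <- sweep(X, 2, colMeans(X))
    Q0 <- random_rotation_oracle()
    Y <- X %*% t(Q0)   # Y = X rotated by Q0, so X = Q0^T ... check recovery
    Q <- kabsch_rotation(X, Y)
    expect_lt(norm(X - Y %*% t(Q), "F"), 1e-10)
    expect_lt(max(abs(crossprod(Q) - diag(3))), 1e-8)
    expect_equal(det(Q), 1, tolerance = 1e-8)
    expect_lt(max(abs(kabsch_rotation(X, X) - diag(3))), 1e-10)
    # optimality: no random rotation does better
    Y2 <- matrix(runif(15, -2, 2), 5)
    Y2 <- sweep(Y2, 2, colMeans(Y2))
    Qbest <- kabsch_rotation(X, Y2)
    best <- norm(X - Y2 %*% t(Qbest), "F")
    for (i in 1:1000) {
      Qr <- random_rotation_oracle()
      expect_gte(norm(X - Y2 %*% t(Qr), "F"), best - 1e-12)
    }
  })
  expect_error(kabsch_rotation(matrix(0, 2, 3), matrix(0, 3, 3)), "matching")
})

test_that("optimal_assignment is exact, species-constrained and recovers permutations", {
  local_seed(43, {
    X <- matrix(runif(18, 0, 3), 6)
    sp <- c("H", "H", "H", "C", "C", "C")
    p0 <- c(2, 3, 1, 6, 4, 5)
    perm <- optimal_assignment(X, X[p0, ][order(p0), ], sp)  # sanity: identity map
    expect_equal(perm, 1:6)
    Y <- X[p0, ]
    perm2 <- optimal_assignment(X, Y, sp, sp[p0])
    expect_equal(Y[perm2, ], X, tolerance = 1e-12)
    # brute-force equality on a random two-species instance
    Y3 <- matrix(runif(18, 0, 3), 6)
    perm3 <- optimal_assignment(X, Y3, sp)
    cost <- function(p) sum((X - Y3[p, ])^2)
    best <- Inf
    for (p in all_permutations(1:6)) {
      if (any(sp != sp[p])) next
      best <- min(best, cost(p))
    }
    expect_equal(cost(perm3), best, tolerance = 1e-12)
    expect_true(all(sp[perm3] == sp))
  })
  expect_equal(optimal_assignment(matrix(1, 1, 3), matrix(1, 1, 3), "H"), 1L)
  expect_error(optimal_assignment(matrix(0, 2, 3), matrix(0, 2, 3),
                                  c("H", "C"), c("H", "H")),
               "inconsistent endpoint composition")
})

test_that("ira_align finds the global rotation-permutation optimum on small clusters", {
  local_seed(47, {
    for (trial in 1:8) {
      n <- sample(4:6, 1)
      sp <- sample(c("H", "C"), n, replace = TRUE)
      X <- matrix(runif(n * 3, 0, 2.5), n)
      Y <- matrix(runif(n * 3, 0, 2.5), n)
      res <- ira_align(configuration(sp, Y), configuration(sp, X))
      expect_lt(res$rmsd, brute_force_rmsd(X, Y, sp) + 1e-9)
      expect_lt(max(abs(crossprod(res$rotation) - diag(3))), 1e-8)
      expect_setequal(res$permutation, seq_len(n))
      expect_true(all(sp[res$permutation] == sp))
    }
  })
})

test_that("rigidly transformed, permuted copies align to zero RMSD", {
  fx <- make_fixture("random_cluster", seed = 7, size = 6)
  # product is jittered; build an exact rigid+permuted copy instead
  local_seed(49, {
    X <- fx$reactant$positions
    sp <- fx$reactant$species
    p0 <- c(3, 4, 5, 2, 1, 6)   # swaps within each species block
    stopifnot(all(sp == sp[p0]))
    Y <- sweep(X[p0, ] %*% t(random_rotation_oracle()), 2, c(3, -2, 1), `+`)
    res <- ira_align(configuration(sp[p0], Y), fx$reactant)
    expect_lt(res$rmsd, 1e-8)
    aligned <- apply_alignment(res, configuration(sp[p0], Y))
    expect_lt(max(abs(aligned$positions - X)), 1e-7)
    expect_identical(aligned$species, sp)
  })
  same <- ira_align(fx$reactant, fx$reactant)
  expect_equal(same$permutation, 1:6)
  expect_lt(same$rmsd, 1e-12)
})

test_that("permutation-invariant RMSD is symmetric, rigid-invariant and below naive", {
  local_seed(53, {
    fx <- make_fixture("random_cluster", seed = 12, size = 5)
    A <- fx$reactant; B <- fx$product
    d_ab <- permutation_invariant_rmsd(A, B)
    d_ba <- permutation_invariant_rmsd(B, A)
    expect_lt(abs(d_ab - d_ba), 1e-9)
    naive <- sqrt(sum((sweep(A$positions, 2, colMeans(A$positions)) -
                         sweep(B$positions, 2, colMeans(B$positions)))^2) / 5)
    expect_lte(d_ab, naive + 1e-12)
    # rigid motion of one argument leaves d unchanged
    Q <- random_rotation_oracle()
    B2 <- configuration(B$species, sweep(B$positions %*% t(Q), 2, c(1, 2, 3), `+`))
    expect_lt(abs(permutation_invariant_rmsd(A, B2) - d_ab), 1e-8)
    expect_lt(permutation_invariant_rmsd(A, A), 1e-12)
  })
})

test_that("alignment guards composition and system size", {
  a <- configuration(c("H", "C"), matrix(0:5, 2, 3))
  b <- configuration(c("H", "H"), matrix(0:5, 2, 3))
  expect_error(ira_align(a, b), "composition")
  big <- configuration(rep("H", 300), matrix(runif(900), 300))
  expect_error(ira_align(big, big), "cap")
})

test_that("two-stage preparation minimizes both endpoints and fixes atom order", {
  fx <- make_fixture("surrogate_triatomic")
  # scramble the product atom order; preparation must restore it
  scramble <- c(3, 1, 2)
  prod_scrambled <- configuration(fx$product$species[scramble],
                                  fx$product$positions[scramble, ])
  prep <- two_stage_prepare(fx$reactant, prod_scrambled,
                            align_params(), minimize_params(), fx$potential)
  expect_identical(prep$product$species, prep$reactant$species)
  for (cfg in list(prep$reactant, prep$product)) {
    out <- evaluate_potential(fx$potential, cfg)
    expect_lt(max(sqrt(rowSums(out$forces^2))), minimize_params()$force_tol)
  }
  # final RMSD is no worse than the naive minimized-endpoint RMSD
  naive <- sqrt(sum((sweep(prep$reactant$positions, 2, colMeans(prep$reactant$positions)) -
                       sweep(prep$product$positions, 2, colMeans(prep$product$positions)))^2) / 3)
  expect_lte(prep$rmsd, naive + 1e-9)
  # endpoints already prepared are a fixed point (up to re-centering)
  prep2 <- two_stage_prepare(prep$reactant, prep$product,
                             align_params(), minimize_params(), fx$potential)
  expect_lt(abs(prep2$rmsd - prep$rmsd), 1e-6)
})
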