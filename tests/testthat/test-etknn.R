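test_that("distances match their closed forms", {
  expect_equal(distance_angular(c(1, 1), c(2, 2)), 0)
  expect_equal(distance_angular(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(distance_angular(c(1, 1, 0), c(1, 0, 0)), 1 - 1 / sqrt(2))
  expect_equal(round(distance_angular(c(1, 1, 0), c(1, 0, 0)), 5), 0.29289)
  expect_error(distance_angular(c(0, 0), c(1, 0)), "zero vector")
  expect_error(distance_angular(c(1, 0), c(1, 0, 0)), "dimension")

  expect_equal(distance_euclidean(c(1, 2), c(1, 2)), 0)
  expect_equal(distance_euclidean(c(0, 0), c(3, 4)), 5)
  set.seed(1)
  u <- stats::rnorm(40)
  v <- stats::rnorm(40)
  oracle <- sqrt(sum(vapply(1:40, function(i) (u[i] - v[i])^2, numeric(1))))
  expect_equal(distance_euclidean(u, v), oracle)
  expect_error(distance_euclidean(1:3, 1:4), "dimension")
})

test_that("bba_from_neighbor follows the exponential evidence kernel", {
  frame <- c("A", "B", "C")
  p <- etknn_params(alpha = 0.95, gamma = c(A = 1, B = 2, C = 1))
  m0 <- bba_from_neighbor(0, "A", p, frame)
  expect_equal(m0[["A"]], 0.95)
  expect_equal(m0[["OMEGA"]], 0.05)
  expect_equal(sum(as.numeric(m0)), 1)

  far <- bba_from_neighbor(1e6, "B", p, frame)
  expect_equal(far[["OMEGA"]], 1) # vacuous in the limit

  m1 <- bba_from_neighbor(1, "A", p, frame)
  expect_equal(m1[["A"]], 0.95 * exp(-1))
  expect_equal(round(m1[["A"]], 5), 0.34949) # 0.95/e

})

test_that("dempster_combine matches hand-combined examples", {
  frame <- c("A", "B")
  mA <- mass_function(c(A = 0.5, B = 0), 0.5)
  mB <- mass_function(c(A = 0, B = 0.5), 0.5)
  vac <- mass_function(c(A = 0, B = 0), 1)

  same <- dempster_combine(mA, mA) # 1 - (1-a)(1-b) on {A}
  expect_equal(same[["A"]], 0.75)
  expect_equal(same[["OMEGA"]], 0.25)

  conflict <- dempster_combine(mA, mB) # conflict 0.25 renormalized
  expect_equal(conflict[["A"]], 1 / 3)
  expect_equal(conflict[["B"]], 1 / 3)
  expect_equal(conflict[["OMEGA"]], 1 / 3)

  expect_equal(as.numeric(dempster_combine(mA, vac)), as.numeric(mA))

  sure_A <- mass_function(c(A = 1, B = 0), 0)
  sure_B <- mass_function(c(A = 0, B = 1), 0)
  expect_error(dempster_combine(sure_A, sure_B), "conflict")
})

test_that("dempster_combine agrees with the power-set oracle", {
  set.seed(21)
  for (M in 2:4) {
    classes <- LETTERS[seq_len(M)]
    for (rep in 1:50) {
      m1 <- random_mass(classes)
      m2 <- random_mass(classes)
      got <- dempster_combine(m1, m2)
      expect_equal(as.numeric(got), unname(dempster_oracle(m1, m2, classes)),
        tolerance = 1e-9
      )
    }
  }
})

test_that("combination is commutative and associative", {
  set.seed(22)
  classes <- c("A", "B", "C")
  m <- replicate(4, random_mass(classes), simplify = FALSE)
  ab <- dempster_combine(m[[1]], m[[2]])
  ba <- dempster_combine(m[[2]], m[[1]])
  expect_equal(as.numeric(ab), as.numeric(ba), tolerance = 1e-12)
  left <- Reduce(dempster_combine, m)
  right <- dempster_combine(
    m[[1]],
    Reduce(dempster_combine, m[2:4])
  )
  expect_equal(as.numeric(left), as.numeric(right), tolerance = 1e-9)
})

test_that("belief_scores folds neighbor evidence and is order-invariant", {
  tr <- separable_training()
  params <- etknn_params(K = 1, alpha = 0.95, gamma = c(A = 1, B = 1))
  q <- c(0, 0)
  m <- belief_scores(q, tr, params)
  expect_equal(sum(as.numeric(m)), 1, tolerance = 1e-9)
  # K = 1 equals that single neighbor's BBA
  d <- apply(tr$x, 1, distance_euclidean, v = q)
  nearest <- which.min(d)
  expect_equal(
    as.numeric(m),
    as.numeric(bba_from_neighbor(d[nearest], tr$y[nearest], params, tr$frame))
  )

  # processing order must not matter (associativity/commutativity)
  params5 <- etknn_params(K = 5, alpha = 0.95, gamma = c(A = 1, B = 1))
  base <- belief_scores(q, tr, params5)
  set.seed(30)
  for (rep in 1:5) {
    perm <- sample(nrow(tr$x))
    tr2 <- etknn_training(tr$x[perm, ], tr$y[perm],
      frame = tr$frame,
      distance = "euclidean"
    )
    expect_equal(as.numeric(belief_scores(q, tr2, params5)),
      as.numeric(base),
      tolerance = 1e-12
    )
  }

  # matches the brute-force combination oracle on many queries
  set.seed(31)
  for (rep in 1:10) {
    q2 <- stats::rnorm(2, mean = 2.5, sd = 3)
    expect_equal(
      as.numeric(belief_scores(q2, tr, params5)),
      as.numeric(belief_oracle(q2, tr, params5)),
      tolerance = 1e-9
    )
  }
})

test_that("classify picks the maximal belief with seeded tie-breaks", {
  tr <- separable_training()
  params <- etknn_params(K = 3, alpha = 0.95, gamma = c(A = 1, B = 1))
  expect_identical(as.character(etknn_classify(c(0, 0), tr, params)), "A")
  expect_identical(as.character(etknn_classify(c(5, 5), tr, params)), "B")

  # two class-A neighbors at d ~ 0, one class-B far away -> A
  tr2 <- etknn_training(
    rbind(c(0, 0), c(0, 0), c(10, 10)), c("A", "A", "B"),
    distance = "euclidean"
  )
  m <- belief_scores(c(0, 0), tr2, params)
  expect_gt(m[["A"]], m[["B"]])

  # symmetric 2-class tie: either class, reproducible under a fixed seed
  sym <- etknn_training(
    rbind(c(-1, 0), c(1, 0)), c("A", "B"),
    distance = "euclidean"
  )
  p2 <- etknn_params(K = 2, alpha = 0.95, gamma = c(A = 1, B = 1))
  set.seed(99)
  first <- as.character(etknn_classify(c(0, 0), sym, p2))
  expect_true(first %in% c("A", "B"))
  set.seed(99)
  expect_identical(as.character(etknn_classify(c(0, 0), sym, p2)), first)
  expect_setequal(
    as.character(etknn_classify(c(0, 0), sym, p2, ties = "all")),
    c("A", "B")
  )

  # singleton training set -> its class
  single <- etknn_training(rbind(c(1, 1)), "A", distance = "euclidean")
  p1 <- etknn_params(K = 1, alpha = 0.95, gamma = c(A = 1))
  expect_identical(as.character(etknn_classify(c(3, 3), single, p1)), "A")

  # separable 2-class set: matches the exhaustive-combination oracle on
  # every query point
  set.seed(33)
  p5 <- etknn_params(K = 5, alpha = 0.95, gamma = c(A = 2, B = 0.5))
  for (rep in 1:20) {
    q <- stats::rnorm(2, mean = 2.5, sd = 4)
    oracle_m <- as.numeric(belief_oracle(q, tr, p5))[1:2]
    if (abs(diff(oracle_m)) < 1e-9) next # knife-edge query: argmax unstable
    oracle_cls <- tr$frame[which.max(oracle_m)]
    expect_identical(as.character(etknn_classify(q, tr, p5)), oracle_cls)
  }
})

test_that("evidence degenerates correctly in the alpha and gamma limits", {
  tr <- separable_training()
  # alpha -> 0: near-vacuous combined state
  weak <- etknn_params(K = 5, alpha = 1e-9, gamma = c(A = 1, B = 1))
  m <- belief_scores(c(0, 0), tr, weak)
  expect_gt(m[["OMEGA"]], 1 - 1e-6)
  # gamma -> large: only the d = 0 neighbor speaks (voting-KNN limit)
  tr2 <- etknn_training(
    rbind(c(0, 0), c(0.5, 0), c(0.6, 0)), c("B", "A", "A"),
    distance = "euclidean"
  )
  sharp <- etknn_params(K = 3, alpha = 0.95, gamma = c(A = 1e6, B = 1e6))
  expect_identical(as.character(etknn_classify(c(0, 0), tr2, sharp)), "B")
})

test_that("optimize_gammas descends the leave-one-out error", {
  tr <- separable_training(n_per = 8, seed = 2)
  fit <- optimize_gammas(tr, etknn_params(K = 3, alpha = 0.95))
  trace <- attr(fit, "error_trace")
  expect_true(all(diff(trace) <= 0)) # non-increasing across accepted steps
  expect_lte(trace[length(trace)], attr(fit, "initial_error"))
  expect_true(all(fit$gamma > 0))

  # perfectly separable fixture -> 100% LOO accuracy after fitting
  # (brute-force LOO evaluation)
  correct <- 0L
  for (i in seq_len(nrow(tr$x))) {
    sub <- etknn_training(tr$x[-i, ], tr$y[-i],
      frame = tr$frame,
      distance = "euclidean"
    )
    params_i <- etknn_params(K = 3, alpha = 0.95, gamma = fit$gamma)
    if (as.character(etknn_classify(tr$x[i, ], sub, params_i)) == tr$y[i]) {
      correct <- correct + 1L
    }
  }
  expect_identical(correct, nrow(tr$x))

  # determinism: same inputs -> identical gammas
  fit2 <- optimize_gammas(tr, etknn_params(K = 3, alpha = 0.95))
  expect_identical(fit$gamma, fit2$gamma)

  expect_error(
    optimize_gammas(
      etknn_training(rbind(c(0, 0), c(1, 1)), c("A", "A"),
        distance = "euclidean"
      )
    ),
    "two classes"
  )
})

test_that("fast combined-mass path equals folding dempster_combine", {
  # the internal product form used during optimization must agree with the
  # pairwise orthogonal sum it replaces
  set.seed(44)
  tr <- separable_training(n_per = 6, seed = 3)
  params <- etknn_params(K = 4, alpha = 0.9, gamma = c(A = 0.7, B = 1.3))
  for (rep in 1:10) {
    q <- stats::rnorm(2, 2.5, 3)
    expect_equal(
      as.numeric(belief_scores(q, tr, params)),
      as.numeric(belief_oracle(q, tr, params)),
      tolerance = 1e-9
    )
  }
})

test_that("mass_function enforces its invariants", {
  expect_error(mass_function(c(A = 0.5, B = 0.2), 0.2), "sum to 1")
  expect_error(mass_function(c(A = -0.1, B = 0.6), 0.5), "negative")
  m <- mass_function(c(A = 0.3, B = 0.3), 0.4)
  expect_equal(sum(as.numeric(m)), 1)
})
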