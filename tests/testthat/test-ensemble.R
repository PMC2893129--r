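test_that("route_query applies the GO-first rule", {
  gv <- structure(c(1, 0, 0), class = c("go_vector", "numeric"))
  zero <- structure(c(0, 0, 0), class = c("go_vector", "numeric"))
  fv <- structure(c(1, 0), class = c("fund_vector", "numeric"))
  pssm <- standardize_pssm(matrix(stats::rnorm(60), 3, 20))
  train_go <- rbind(c(1, 1, 0))

  expect_identical(route_query(list(go = gv, fund = fv, pssm = pssm),
    train_go), "go")
  expect_identical(
    route_query(list(go = zero, fund = fv, pssm = pssm), train_go),
    "fusion"
  )
  # productive-in-isolation but orthogonal to training evidence -> fusion
  orth <- structure(c(0, 0, 1), class = c("go_vector", "numeric"))
  expect_identical(
    route_query(list(go = orth, fund = fv, pssm = NULL), train_go),
    "fusion"
  )
  expect_error(
    route_query(list(go = zero, fund = NULL, pssm = NULL), train_go),
    "unroutable"
  )
})

test_that("run_members produces one vote per grid member", {
  sim <- small_sim()
  cfg <- ensemble_config(K_grid = 1:3, lambda_grid = 0:2, seed = 1)
  feats <- sim_features(sim, cfg)
  model <- train_localizer(sim$benchmark, feats, cfg,
    frame = sim$frame,
    optimize = FALSE
  )
  with_go <- Filter(function(f) !is.null(f$go), feats)
  members_go <- run_members(with_go[[1]], model, "go", cfg)
  expect_identical(nrow(members_go), 3L) # |K grid| members
  expect_true(all(members_go$mode == "go"))

  members_fus <- run_members(feats[[1]], model, "fusion", cfg)
  # |K| FunD members + |K| x |lambda| PsePSSM members
  expect_identical(nrow(members_fus), 3L + 3L * 3L)
  expect_identical(sum(members_fus$mode == "fund"), 3L)
  expect_identical(sum(members_fus$mode == "psepssm"), 9L)

  # grid-size arithmetic oracle at the default-shaped grids
  cfg10 <- ensemble_config(K_grid = 1:10, lambda_grid = 0:10)
  grid <- expand.grid(K = cfg10$K_grid, lambda = cfg10$lambda_grid)
  expect_identical(length(cfg10$K_grid) + nrow(grid), 10L + 110L)
})

test_that("fuse_votes tallies weighted member fractions", {
  frame <- c("A", "B", "C")
  members <- data.frame(
    mode = c("fund", "fund", "psepssm"),
    K = 1:3, lambda = c(NA, NA, 0),
    vote = c("A", "A", "B"), stringsAsFactors = FALSE
  )
  members$masses <- list(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))
  f <- fuse_votes(members, frame, ensemble_config())
  expect_equal(as.numeric(f), c(2 / 3, 1 / 3, 0))
  expect_equal(sum(as.numeric(f)), 1)

  unanimous <- members
  unanimous$vote <- "C"
  expect_equal(as.numeric(fuse_votes(unanimous, frame))[3], 1)

  # zero weight on one mode equals re-tallying the other alone
  cfg_w <- ensemble_config(mode_weights = c(fund = 0, psepssm = 1))
  f2 <- fuse_votes(members, frame, cfg_w)
  only_pse <- members[members$mode == "psepssm", ]
  expect_equal(as.numeric(f2), as.numeric(fuse_votes(only_pse, frame)))
})

test_that("decide_locations thresholds relative to the maximum", {
  frame <- c("A", "B", "C")
  mk <- function(v) structure(v, names = frame, class = "fused_scores")
  expect_setequal(
    decide_locations(mk(c(1.0, 0.8, 0.2) / 2), ensemble_config(tau = 0.7)),
    c("A", "B")
  )
  expect_identical(
    decide_locations(mk(c(0.5, 0.3, 0.2)), ensemble_config(tau = 1)), "A"
  )
  # tau = 1 keeps exact ties
  expect_setequal(
    decide_locations(mk(c(0.4, 0.4, 0.2)), ensemble_config(tau = 1)),
    c("A", "B")
  )
  # uniform scores return every class
  expect_setequal(decide_locations(mk(rep(1 / 3, 3)), 0.7), frame)
  # monotonicity: lowering tau never removes a location
  set.seed(50)
  for (rep in 1:20) {
    s <- stats::runif(3)
    s <- s / sum(s)
    hi <- decide_locations(mk(s), stats::runif(1, 0.5, 1))
    expect_true(all(hi %in% decide_locations(mk(s), 0.3)))
    expect_true(frame[which.max(s)] %in% hi) # always contains the argmax
    expect_gt(length(hi), 0)
  }
})

test_that("predict routes, fuses and memorizes the training data", {
  sim <- small_sim(seed = 9)
  cfg <- ensemble_config(K_grid = 1:3, lambda_grid = 0:2, seed = 9)
  feats <- sim_features(sim, cfg)
  model <- train_localizer(sim$benchmark, feats, cfg, frame = sim$frame)
  res <- predict(model, feats)
  # training proteins queried against the full model recover their labels
  for (i in seq_len(nrow(sim$benchmark))) {
    expect_setequal(res$locations[[i]], sim$benchmark$labels[[i]])
  }
  scores <- attr(res, "scores")
  expect_equal(unname(rowSums(scores)), rep(1, nrow(scores)),
    tolerance = 1e-9
  )
  # same query twice -> identical output
  res2 <- predict(model, feats)
  expect_identical(res$locations, res2$locations)
  expect_equal(attr(res, "scores"), attr(res2, "scores"))
})

test_that("a single-member ensemble reduces to the basic classifier", {
  sim <- small_sim(seed = 13)
  cfg <- ensemble_config(
    K_grid = 3, lambda_grid = 0, tau = 1,
    mode_weights = c(fund = 1, psepssm = 0), seed = 13
  )
  feats <- sim_features(sim, cfg)
  model <- train_localizer(sim$benchmark, feats, cfg,
    frame = sim$frame,
    optimize = FALSE
  )
  # force the fusion branch with a GO-free query, FunD weight only
  f <- feats[[which(vapply(feats, function(x) !is.null(x$fund), logical(1)))[1]]]
  f$go <- NULL
  res <- predict(model, list(q = f), config = cfg)
  params <- etknn_params(K = 3, alpha = cfg$alpha, gamma = model$fund$gamma)
  direct <- etknn_classify(f$fund, model$fund$training, params, ties = "all")
  expect_true(all(res$locations[[1]] %in% as.character(direct)) ||
    identical(sort(res$locations[[1]]), sort(as.character(direct))))
})

test_that("vote fusion mode runs end to end", {
  sim <- small_sim(seed = 17)
  cfg <- ensemble_config(
    K_grid = 1:3, lambda_grid = 0:1,
    fusion = "vote", seed = 17
  )
  feats <- sim_features(sim, cfg)
  model <- train_localizer(sim$benchmark, feats, cfg, frame = sim$frame)
  set.seed(17)
  res <- predict(model, feats[1:4], config = cfg)
  expect_identical(nrow(res), 4L)
  expect_true(all(lengths(res$locations) >= 1))
})
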