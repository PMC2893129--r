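#' Ensemble configuration
#'
#' Controls the grid of basic OET-KNN members, the multi-label decision
#' threshold and the per-mode fusion weights.
#'
#' @param K_grid Neighbor counts of the member classifiers (default 1..10).
#' @param lambda_grid PsePSSM tier counts of the sequential-evolution
#'   members (default 0..10; each must stay below the shortest training
#'   chain and below 50).
#' @param tau Multi-label threshold in (0, 1]: every location whose fused
#'   score reaches `tau` times the maximum score is called (default 0.7).
#' @param mode_weights Named weights for the FunD + PsePSSM fusion branch
#'   (default equal).
#' @param fusion `"belief"` (default): fuse the per-member combined
#'   singleton masses; `"vote"`: fuse hard member votes via
#'   [fuse_votes()].
#' @param alpha,e_cutoff,identity_cutoff Evidence scale and homology /
#'   domain significance cutoffs passed through to the descriptor and
#'   classifier layers.
#' @param seed Seed for the library-wide random generator (tie-breaks).
#' @return List of class `ensemble_config`.
#' @export
ensemble_config <- function(K_grid = 1:10, lambda_grid = 0:10, tau = 0.7,
                            mode_weights = c(fund = 1, psepssm = 1),
                            fusion = c("belief", "vote"),
                            alpha = 0.95, e_cutoff = 1e-3,
                            identity_cutoff = 25, seed = 1L) {
  fusion <- match.arg(fusion)
  stopifnot(
    length(K_grid) >= 1, length(lambda_grid) >= 1,
    tau > 0, tau <= 1, all(mode_weights >= 0)
  )
  structure(
    list(
      K_grid = as.integer(K_grid), lambda_grid = as.integer(lambda_grid),
      tau = tau, mode_weights = mode_weights, fusion = fusion,
      alpha = alpha, e_cutoff = e_cutoff,
      identity_cutoff = identity_cutoff, seed = as.integer(seed)
    ),
    class = "ensemble_config"
  )
}

#' Route a query to its descriptor mode plan
#'
#' The GO-first routing rule: a query whose GO descriptor is productive
#' (non-zero and overlapping the training evidence) is handled by the GO
#' engine alone; otherwise the FunD and PsePSSM engines are fused. A query
#' with no usable representation at all cannot be routed.
#'
#' @param features Per-protein feature list with elements `go`
#'   ([go_vector()] or `NULL`), `fund` ([fund_vector()] or `NULL`) and
#'   `pssm` (standardized matrix or `NULL`).
#' @param go_training_matrix Matrix of training GO vectors used by the
#'   productivity check (or `NULL` to skip the overlap condition).
#' @return `"go"` or `"fusion"`.
#' @export
route_query <- function(features, go_training_matrix = NULL) {
  if (!is.null(features$go) &&
    is_productive(features$go, go_training_matrix)) {
    return("go")
  }
  has_fund <- !is.null(features$fund) && any(as.numeric(features$fund) != 0)
  has_pssm <- !is.null(features$pssm)
  if (has_fund || has_pssm) {
    return("fusion")
  }
  stop_mlploc(
    "unroutable query: no productive GO descriptor and no ",
    "FunD/PsePSSM representation"
  )
}

member_grid <- function(plan, config) {
  if (plan == "go") {
    data.frame(mode = "go", K = config$K_grid, lambda = NA_integer_)
  } else {
    rbind(
      data.frame(mode = "fund", K = config$K_grid, lambda = NA_integer_),
      expand.grid(
        mode = "psepssm", K = config$K_grid,
        lambda = config$lambda_grid, stringsAsFactors = FALSE
      )
    )
  }
}

#' Run every member classifier of a mode plan
#'
#' One basic OET-KNN classification per grid cell: `(mode = GO, K)` for a
#' GO plan; `(mode = FunD, K)` plus `(mode = PsePSSM, K, lambda)` for a
#' fusion plan.
#'
#' @param features Query feature list (see [route_query()]).
#' @param model A [train_localizer()] bundle.
#' @param plan `"go"` or `"fusion"`.
#' @param config [ensemble_config()].
#' @return Data frame with one row per member: `mode`, `K`, `lambda`,
#'   `vote` (the tie-free classify output) and a list-column `masses` of
#'   combined singleton masses.
#' @export
run_members <- function(features, model, plan, config = model$config) {
  grid <- member_grid(plan, config)
  keep <- logical(nrow(grid))
  votes <- character(nrow(grid))
  masses <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    mode <- grid$mode[r]
    engine <- switch(mode,
      go = model$go,
      fund = model$fund,
      psepssm = model$psepssm[[as.character(grid$lambda[r])]]
    )
    if (is.null(engine)) next
    query <- switch(mode,
      go = features$go,
      fund = features$fund,
      psepssm = psepssm_query(features$pssm, grid$lambda[r])
    )
    if (is.null(query)) next
    if (mode %in% c("go", "fund") && !any(as.numeric(query) != 0)) next
    params <- etknn_params(
      K = grid$K[r], alpha = config$alpha,
      gamma = engine$gamma
    )
    cls <- etknn_classify(query, engine$training, params, ties = "random")
    m <- attr(cls, "masses")
    keep[r] <- TRUE
    votes[r] <- as.character(cls)[1]
    masses[[r]] <- as.numeric(m)[seq_along(engine$training$frame)]
  }
  out <- grid[keep, , drop = FALSE]
  out$vote <- votes[keep]
  out$masses <- masses[keep]
  if (!nrow(out)) stop_mlploc("no ensemble member could score the query")
  rownames(out) <- NULL
  out
}

psepssm_query <- function(pssm, lambda) {
  if (is.null(pssm)) {
    return(NULL)
  }
  if (lambda >= nrow(pssm)) {
    return(NULL)
  } # chain too short for this tier
  psepssm_vector(pssm, lambda)
}

member_weights <- function(members, config) {
  mw <- config$mode_weights
  vapply(members$mode, function(mode) {
    if (mode %in% names(mw)) unname(mw[[mode]]) else 1
  }, numeric(1), USE.NAMES = FALSE)
}

#' Fuse hard member votes into per-location scores
#'
#' Score of a location = the (mode-weighted) fraction of members voting
#' for it; scores sum to 1.
#'
#' @param members A [run_members()] result (only `mode` and `vote` are
#'   used).
#' @param frame Location classes.
#' @param config [ensemble_config()] (for the mode weights).
#' @return Named numeric vector of class `fused_scores` with attribute
#'   `provenance` (the members data frame).
#' @export
fuse_votes <- function(members, frame, config = ensemble_config()) {
  stopifnot(nrow(members) >= 1)
  w <- member_weights(members, config)
  if (sum(w) == 0) stop_mlploc("all member weights are zero")
  score <- vapply(
    frame,
    function(cl) sum(w[members$vote == cl]),
    numeric(1)
  )
  score <- score / sum(w)
  structure(score,
    names = frame, provenance = members,
    class = c("fused_scores", "numeric")
  )
}

#' Fuse member belief masses into per-location scores
#'
#' Each member contributes its combined singleton masses, normalized to
#' sum 1 over the locations; the fused score is the mode-weighted average,
#' renormalized. Unlike hard votes this preserves the near-ties that a
#' genuinely bi-located protein produces, so both of its locations survive
#' the relative threshold.
#'
#' @inheritParams fuse_votes
#' @return `fused_scores` vector summing to 1.
#' @export
fuse_beliefs <- function(members, frame, config = ensemble_config()) {
  stopifnot(nrow(members) >= 1)
  w <- member_weights(members, config)
  if (sum(w) == 0) stop_mlploc("all member weights are zero")
  acc <- setNames(numeric(length(frame)), frame)
  used <- 0
  for (r in seq_len(nrow(members))) {
    if (w[r] == 0) next
    m <- members$masses[[r]]
    tot <- sum(m)
    if (tot <= 0) next # vacuous member: no singleton support
    acc <- acc + w[r] * m / tot
    used <- used + w[r]
  }
  if (used == 0) stop_mlploc("every member is vacuous: undecidable query")
  structure(acc / used,
    names = frame, provenance = members,
    class = c("fused_scores", "numeric")
  )
}

#' Multi-label decision from fused scores
#'
#' Returns every location whose fused score is at least `tau` times the
#' maximum score. The set always contains the argmax (with its ties) and
#' is never empty; `tau = 1` reduces to the argmax set.
#'
#' @param fused [fuse_beliefs()] / [fuse_votes()] result.
#' @param config [ensemble_config()] (for `tau`), or a number taken as
#'   `tau` directly.
#' @return Character vector of predicted locations, in frame order.
#' @export
decide_locations <- function(fused, config = ensemble_config()) {
  tau <- if (is.numeric(config)) config else config$tau
  s <- as.numeric(fused)
  mx <- max(s)
  if (mx <= 0) stop_mlploc("undecidable query: all fused scores are zero")
  names(fused)[s >= tau * mx - 1e-12]
}

#' Train the full multi-location localizer
#'
#' Builds one evidence-theoretic engine per descriptor mode from a labeled
#' benchmark: a GO engine and a FunD engine (angular distance) and one
#' PsePSSM engine per `lambda` in the grid (Euclidean distance). Each
#' engine's per-class gamma rates are fitted with [optimize_gammas()].
#' Proteins contribute one training entry per location label (locative
#' entries); proteins without a usable descriptor in a mode are simply
#' absent from that engine.
#'
#' @param benchmark Data frame with columns `protein` and `labels`
#'   (list-column of location character vectors), e.g. from
#'   [read_benchmark()].
#' @param features Named list (by protein id) of feature lists with
#'   elements `go`, `fund`, `pssm` (see [build_features()]).
#' @param config [ensemble_config()].
#' @param frame Location classes (default [plant_locations()] restricted
#'   to labels present? no — pass explicitly for non-default frames).
#' @param optimize Fit gammas by leave-one-out descent (default `TRUE`);
#'   `FALSE` keeps the [init_gammas()] initialization.
#' @return Object of class `localizer`.
#' @export
train_localizer <- function(benchmark, features, config = ensemble_config(),
                            frame = plant_locations(), optimize = TRUE) {
  labs <- unique(unlist(benchmark$labels))
  bad <- setdiff(labs, frame)
  if (length(bad)) {
    stop_mlploc(
      "benchmark label(s) outside the frame: ",
      paste(bad, collapse = ", ")
    )
  }
  frame <- frame[frame %in% labs] # engines only see populated classes
  entries <- locative_entries(benchmark)
  model <- structure(
    list(frame = frame, config = config, go = NULL, fund = NULL,
         psepssm = list()),
    class = "localizer"
  )
  fit <- function(x, y, ids, distance) {
    tr <- etknn_training(x, y, frame = frame, distance = distance, ids = ids)
    params <- etknn_params(K = max(config$K_grid), alpha = config$alpha)
    params <- if (optimize && length(unique(y)) >= 2) {
      optimize_gammas(tr, params)
    } else {
      etknn_params(
        K = params$K, alpha = params$alpha,
        gamma = init_gammas(tr)
      )
    }
    list(training = tr, gamma = params$gamma)
  }
  collect <- function(extract) {
    rows <- list()
    y <- character()
    ids <- character()
    for (r in seq_len(nrow(entries))) {
      f <- features[[entries$protein[r]]]
      v <- if (is.null(f)) NULL else extract(f)
      if (is.null(v)) next
      rows[[length(rows) + 1L]] <- as.numeric(v)
      y[length(y) + 1L] <- entries$label[r]
      ids[length(ids) + 1L] <- entries$protein[r]
    }
    if (!length(rows)) {
      return(NULL)
    }
    list(x = do.call(rbind, rows), y = y, ids = ids)
  }
  go <- collect(function(f) {
    if (!is.null(f$go) && any(as.numeric(f$go) != 0)) f$go else NULL
  })
  if (!is.null(go)) model$go <- fit(go$x, go$y, go$ids, "angular")
  fund <- collect(function(f) {
    if (!is.null(f$fund) && any(as.numeric(f$fund) != 0)) f$fund else NULL
  })
  if (!is.null(fund)) model$fund <- fit(fund$x, fund$y, fund$ids, "angular")
  for (lam in config$lambda_grid) {
    pe <- collect(function(f) {
      if (is.null(f$pssm) || lam >= nrow(f$pssm)) {
        return(NULL)
      }
      psepssm_vector(f$pssm, lam)
    })
    if (!is.null(pe)) {
      model$psepssm[[as.character(lam)]] <-
        fit(pe$x, pe$y, pe$ids, "euclidean")
    }
  }
  model
}

locative_entries <- function(benchmark) {
  n <- vapply(benchmark$labels, length, integer(1))
  data.frame(
    protein = rep(benchmark$protein, n),
    label = unlist(benchmark$labels),
    stringsAsFactors = FALSE
  )
}

#' @export
print.localizer <- function(x, ...) {
  cat("<localizer>", length(x$frame), "locations; engines:",
    paste(c(
      if (!is.null(x$go)) "GO",
      if (!is.null(x$fund)) "FunD",
      if (length(x$psepssm)) {
        paste0("PsePSSM(lambda=", length(x$psepssm), " tiers)")
      }
    ), collapse = ", "), "\n")
  invisible(x)
}

#' Predict the location set of query proteins
#'
#' End-to-end prediction: route each query (GO engine if productive,
#' otherwise FunD + PsePSSM fusion), run every member classifier of the
#' plan, fuse, and threshold into a location set.
#'
#' @param object A [train_localizer()] bundle.
#' @param features Named list of per-protein feature lists (see
#'   [build_features()]), or a single feature list.
#' @param config Override the bundle's [ensemble_config()].
#' @param ... Unused.
#' @return Data frame with one row per query: `protein`, `locations`
#'   (list-column), `plan`, plus a `scores` matrix attribute (queries x
#'   locations).
#' @export
predict.localizer <- function(object, features, config = object$config,
                              ...) {
  if (!is.null(features$go) || !is.null(features$fund) ||
    !is.null(features$pssm)) {
    features <- list(query = features)
  }
  ids <- names(features)
  go_mat <- if (!is.null(object$go)) object$go$training$x else NULL
  scores <- matrix(0, length(ids), length(object$frame),
    dimnames = list(ids, object$frame)
  )
  locations <- vector("list", length(ids))
  plans <- character(length(ids))
  for (i in seq_along(ids)) {
    f <- features[[i]]
    plan <- tryCatch(route_query(f, go_mat), error = function(e) {
      stop_mlploc("query '", ids[i], "': ", conditionMessage(e))
    })
    if (plan == "go" && is.null(object$go)) plan <- "fusion"
    members <- run_members(f, object, plan, config)
    fused <- if (config$fusion == "belief") {
      fuse_beliefs(members, object$frame, config)
    } else {
      fuse_votes(members, object$frame, config)
    }
    scores[i, ] <- as.numeric(fused)
    locations[[i]] <- decide_locations(fused, config)
    plans[i] <- plan
  }
  out <- data.frame(protein = ids, plan = plans, stringsAsFactors = FALSE)
  out$locations <- locations
  attr(out, "scores") <- scores
  out
}
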