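#' Locative breakdown of a multi-location benchmark
#'
#' Tabulates how many different proteins carry exactly k location labels.
#' A protein located at two sites counts as two "locative proteins", one
#' per site; the breakdown is the bridge between different-protein and
#' locative-protein accounting.
#'
#' @param x Either a benchmark data frame (`protein`, list-column
#'   `labels`) or a named integer vector/`c(n1, n2, ...)` of counts of
#'   proteins with exactly 1, 2, ... locations.
#' @param M Number of location sites (default: inferred).
#' @return List of class `dataset_breakdown`: `n_dif`, `counts` (length
#'   M), `M`.
#' @export
dataset_breakdown <- function(x, M = NULL) {
  if (is.data.frame(x)) {
    k <- vapply(x$labels, function(l) length(unique(l)), integer(1))
    if (any(k < 1)) stop_mlploc("protein(s) with no location label")
    M <- M %||% max(length(unique(unlist(x$labels))), max(k))
    counts <- vapply(seq_len(M), function(i) sum(k == i), integer(1))
  } else {
    counts <- as.integer(x)
    if (any(counts < 0)) stop_mlploc("negative count")
    M <- M %||% length(counts)
    counts <- c(counts, integer(max(0, M - length(counts))))
  }
  structure(
    list(n_dif = sum(counts), counts = counts, M = M),
    class = "dataset_breakdown"
  )
}

#' Number of locative proteins
#'
#' `N_loc = sum_k k * n(k)`: each different protein counts once per
#' location it occupies.
#'
#' @param breakdown A [dataset_breakdown()] (or anything it accepts).
#' @return Integer count.
#' @export
#' @examples
#' count_locative(c(904, 71, 3)) # the 12-site benchmark: 1055
count_locative <- function(breakdown) {
  if (!inherits(breakdown, "dataset_breakdown")) {
    breakdown <- dataset_breakdown(breakdown)
  }
  sum(seq_along(breakdown$counts) * breakdown$counts)
}

#' Percentage of multi-location proteins
#'
#' `100 * (number of proteins with >= 2 locations) / n_dif`.
#'
#' @inheritParams count_locative
#' @return Percentage (0-100).
#' @export
#' @examples
#' multi_location_fraction(c(904, 71, 3)) # ~7.57, "about 8%"
multi_location_fraction <- function(breakdown) {
  if (!inherits(breakdown, "dataset_breakdown")) {
    breakdown <- dataset_breakdown(breakdown)
  }
  if (breakdown$n_dif == 0) stop_mlploc("empty dataset")
  100 * sum(breakdown$counts[-1]) / breakdown$n_dif
}

#' Score multi-label predictions with locative accounting
#'
#' Each locative pair (protein, true location) is correct when the
#' location is in the predicted set. Per-location success = correct /
#' members of that location; overall success = total correct / N_loc.
#' Predicted labels missing from the truth count as over-predictions
#' (false positives), true labels missing from the prediction as
#' under-predictions (false negatives); neither voids the hits that were
#' made.
#'
#' @param truth_sets Named list: protein id -> character vector of true
#'   locations.
#' @param predicted_sets Named list with the same ids -> predicted
#'   locations.
#' @return List of class `eval_report`: `per_location` data frame
#'   (`location`, `correct`, `total`, `rate`), `overall_correct`,
#'   `n_locative`, `overall_rate` (percent), `over_predictions`,
#'   `under_predictions`.
#' @export
score_predictions <- function(truth_sets, predicted_sets) {
  ids <- names(truth_sets)
  if (!setequal(ids, names(predicted_sets))) {
    stop_mlploc("truth and prediction protein ids differ")
  }
  locs <- sort(unique(unlist(truth_sets)))
  correct <- setNames(integer(length(locs)), locs)
  total <- setNames(integer(length(locs)), locs)
  over <- 0L
  under <- 0L
  for (id in ids) {
    tr <- unique(truth_sets[[id]])
    pr <- unique(predicted_sets[[id]])
    for (l in tr) {
      total[l] <- total[l] + 1L
      if (l %in% pr) correct[l] <- correct[l] + 1L
    }
    over <- over + length(setdiff(pr, tr))
    under <- under + length(setdiff(tr, pr))
  }
  n_loc <- sum(total)
  structure(
    list(
      per_location = data.frame(
        location = locs,
        correct = as.integer(correct),
        total = as.integer(total),
        rate = 100 * as.numeric(correct) / pmax(total, 1L),
        stringsAsFactors = FALSE
      ),
      overall_correct = sum(correct),
      n_locative = n_loc,
      overall_rate = 100 * sum(correct) / n_loc,
      over_predictions = over,
      under_predictions = under
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Jackknife / prediction success by location\n")
  with(x$per_location, {
    for (i in seq_along(location)) {
      cat(sprintf(
        "  %-22s %d/%d = %.1f%%\n", location[i], correct[i],
        total[i], rate[i]
      ))
    }
  })
  cat(sprintf(
    "  %-22s %d/%d = %.1f%%\n", "Total", x$overall_correct,
    x$n_locative, x$overall_rate
  ))
  cat(sprintf(
    "  over-predictions: %d  under-predictions: %d\n",
    x$over_predictions, x$under_predictions
  ))
  invisible(x)
}

#' Jackknife (leave-one-out) evaluation of the localizer
#'
#' Withholds each different protein in turn (all of its locative entries
#' together — a bi-located protein never leaks its twin entry into its own
#' training set), retrains the localizer on the remainder, predicts the
#' withheld protein's location set and aggregates the locative scores.
#'
#' @param benchmark Benchmark data frame (`protein`, list-column
#'   `labels`).
#' @param features Named list of per-protein feature lists.
#' @param config [ensemble_config()].
#' @param frame Location classes.
#' @param seed Seed for the whole run (tie-breaks are drawn from one
#'   generator, so identical seeds give identical reports).
#' @param optimize Refit gammas in every fold (default `TRUE`).
#' @return An `eval_report` (see [score_predictions()]) with the per-fold
#'   predictions attached as attribute `predictions`.
#' @export
jackknife <- function(benchmark, features, config = ensemble_config(),
                      frame = plant_locations(), seed = config$seed,
                      optimize = TRUE) {
  loc_members <- table(unlist(benchmark$labels))
  lonely <- names(loc_members)[loc_members < 2]
  if (length(lonely)) {
    warning(
      "location(s) with a single member protein: ",
      paste(lonely, collapse = ", "), call. = FALSE
    )
  }
  set.seed(seed)
  preds <- vector("list", nrow(benchmark))
  names(preds) <- benchmark$protein
  for (i in seq_len(nrow(benchmark))) {
    id <- benchmark$protein[i]
    train_bm <- benchmark[-i, , drop = FALSE]
    model <- train_localizer(
      train_bm, features[train_bm$protein],
      config = config, frame = frame, optimize = optimize
    )
    for (eng in c(
      list(model$go, model$fund),
      unname(model$psepssm)
    )) {
      if (!is.null(eng) && id %in% eng$training$ids) {
        stop_mlploc("leakage: withheld protein ", id, " found in training")
      }
    }
    res <- predict(model, features[id], config = config)
    preds[[id]] <- res$locations[[1]]
  }
  truth <- setNames(benchmark$labels, benchmark$protein)
  report <- score_predictions(truth, preds)
  attr(report, "predictions") <- preds
  report
}
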