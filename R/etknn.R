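#' Angular (cosine) distance
#'
#' `1 - cos(u, v)`; the distance used for the binary GO and FunD
#' descriptor modes. Range `[0, 2]`; 0 for parallel vectors, 1 for
#' orthogonal ones.
#'
#' @param u,v Equal-length numeric vectors, each with a non-zero norm.
#' @return Scalar distance.
#' @export
distance_angular <- function(u, v) {
  u <- as.numeric(u)
  v <- as.numeric(v)
  if (length(u) != length(v)) stop_mlploc("vectors differ in dimension")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop_mlploc(
      "angular distance undefined for a zero vector; ",
      "filter non-productive descriptors before classification"
    )
  }
  max(1 - sum(u * v) / (nu * nv), 0)
}

#' Euclidean distance
#'
#' The distance used for the PsePSSM descriptor mode.
#'
#' @param u,v Equal-length numeric vectors.
#' @return Scalar distance.
#' @export
distance_euclidean <- function(u, v) {
  u <- as.numeric(u)
  v <- as.numeric(v)
  if (length(u) != length(v)) stop_mlploc("vectors differ in dimension")
  sqrt(sum((u - v)^2))
}

#' ET-KNN parameters
#'
#' @param alpha Fixed evidence scale in (0, 1); 0.95 is the value
#'   conventional for this classifier family.
#' @param gamma Per-class positive rate parameters (named by class), or
#'   `NULL` to initialize from the training data at fit time.
#' @param K Neighbor count (>= 1).
#' @return List of class `etknn_params`.
#' @export
etknn_params <- function(K = 5, alpha = 0.95, gamma = NULL) {
  stopifnot(K >= 1, alpha > 0, alpha < 1, is.null(gamma) || all(gamma > 0))
  structure(list(K = as.integer(K), alpha = alpha, gamma = gamma),
    class = "etknn_params"
  )
}

#' Mass function over singleton classes plus the whole frame
#'
#' Basic belief assignment in which only the singleton classes and the
#' frame of discernment Omega can carry mass — the evidence structure that
#' arises from neighbor-based evidence and that is closed under Dempster
#' combination.
#'
#' @param singletons Named non-negative numeric vector, one entry per
#'   class.
#' @param omega Mass on the whole frame.
#' @return Object of class `mass_function`: numeric vector
#'   `c(singletons, OMEGA = omega)`, summing to 1.
#' @export
mass_function <- function(singletons, omega) {
  m <- c(singletons, OMEGA = omega)
  if (any(m < -1e-12)) stop_mlploc("negative mass")
  total <- sum(m)
  if (abs(total - 1) > 1e-9) {
    stop_mlploc("masses must sum to 1 (got ", format(total), ")")
  }
  structure(as.numeric(m),
    names = names(m),
    class = c("mass_function", "numeric")
  )
}

#' @export
print.mass_function <- function(x, digits = 4, ...) {
  cat("<mass_function>\n")
  print(round(setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}

mass_classes <- function(m) setdiff(names(m), "OMEGA")

#' Neighbor evidence as a basic belief assignment
#'
#' A neighbor of class `q` at distance `d` contributes mass
#' `alpha * exp(-gamma_q * d^2)` to the singleton `{q}` and the remainder
#' to the whole frame Omega: strong support close by, vacuous evidence far
#' away.
#'
#' @param d Non-negative distance to the neighbor.
#' @param class_q Neighbor's class label.
#' @param params [etknn_params()] with `gamma` set (named by class).
#' @param frame Character vector of all classes.
#' @return A [mass_function()].
#' @export
bba_from_neighbor <- function(d, class_q, params, frame) {
  stopifnot(d >= 0, class_q %in% frame)
  gamma_q <- params$gamma[[class_q]]
  if (is.null(gamma_q)) stop_mlploc("no gamma for class ", class_q)
  s <- setNames(numeric(length(frame)), frame)
  s[class_q] <- params$alpha * exp(-gamma_q * d^2)
  mass_function(s, omega = 1 - s[[class_q]])
}

#' Combine two mass functions with Dempster's rule
#'
#' Normalized orthogonal sum for the singleton-plus-Omega evidence
#' structure: the unnormalized combined mass on `{q}` is
#' `m1(q) m2(q) + m1(q) m2(Omega) + m1(Omega) m2(q)`, on Omega it is
#' `m1(Omega) m2(Omega)`, and the conflict (mass on empty intersections of
#' distinct singletons) is renormalized away. Commutative and associative.
#'
#' @param m1,m2 [mass_function()] objects over the same frame.
#' @return Combined [mass_function()].
#' @export
dempster_combine <- function(m1, m2) {
  cls <- mass_classes(m1)
  if (!identical(cls, mass_classes(m2))) {
    stop_mlploc("mass functions are over different frames")
  }
  s1 <- as.numeric(m1)[seq_along(cls)]
  s2 <- as.numeric(m2)[seq_along(cls)]
  o1 <- as.numeric(m1)[[length(cls) + 1L]]
  o2 <- as.numeric(m2)[[length(cls) + 1L]]
  s <- s1 * s2 + s1 * o2 + o1 * s2
  o <- o1 * o2
  total <- sum(s) + o
  if (total <= 1e-300) {
    stop_mlploc("total conflict: evidence cannot be combined")
  }
  mass_function(setNames(s / total, cls), omega = o / total)
}

vacuous_mass <- function(frame) {
  mass_function(setNames(numeric(length(frame)), frame), omega = 1)
}

#' Training set for the evidence-theoretic K-nearest-neighbor rule
#'
#' One row per locative training pair: a protein located at two sites
#' contributes two rows with the same descriptor and different labels.
#'
#' @param x Numeric matrix of descriptor vectors (rows = entries).
#' @param y Class labels (character or factor), one per row.
#' @param frame Class universe; defaults to the sorted unique labels.
#' @param distance `"angular"` (GO/FunD modes) or `"euclidean"` (PsePSSM
#'   mode).
#' @param ids Optional protein identifiers per row (used by the jackknife
#'   leakage check).
#' @return Object of class `etknn_training`.
#' @export
etknn_training <- function(x, y, frame = NULL,
                           distance = c("angular", "euclidean"),
                           ids = NULL) {
  distance <- match.arg(distance)
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop_mlploc("x and y sizes differ")
  if (nrow(x) == 0) stop_mlploc("empty training set")
  frame <- frame %||% sort(unique(y))
  if (!all(y %in% frame)) {
    stop_mlploc(
      "label(s) outside the frame: ",
      paste(setdiff(unique(y), frame), collapse = ", ")
    )
  }
  structure(
    list(x = x, y = y, frame = frame, distance = distance, ids = ids),
    class = "etknn_training"
  )
}

#' @export
print.etknn_training <- function(x, ...) {
  cat(
    "<etknn_training>", nrow(x$x), "entries,", length(x$frame),
    "classes,", x$distance, "distance\n"
  )
  invisible(x)
}

distances_to <- function(training, query) {
  q <- as.numeric(query)
  x <- training$x
  if (length(q) != ncol(x)) stop_mlploc("query dimension mismatch")
  if (training$distance == "euclidean") {
    sqrt(pmax(rowSums(x^2) - 2 * as.numeric(x %*% q) + sum(q^2), 0))
  } else {
    nq <- sqrt(sum(q^2))
    nx <- sqrt(rowSums(x^2))
    if (nq == 0 || any(nx == 0)) {
      stop_mlploc("angular distance undefined for a zero vector")
    }
    pmax(1 - as.numeric(x %*% q) / (nx * nq), 0)
  }
}

# indices of the K nearest entries, inclusive of every entry tied with the
# K-th smallest distance (keeps classification permutation-invariant)
k_nearest <- function(d, K) {
  K <- min(K, length(d))
  kth <- sort(d, partial = K)[K]
  which(d <= kth + 1e-12)
}

# combined singleton + Omega masses from neighbor classes/distances via the
# closed-form complement products; equals folding bba_from_neighbor with
# dempster_combine (property-tested)
combine_neighbors <- function(d, cls, params, frame) {
  gamma <- params$gamma[frame]
  m <- params$alpha * exp(-gamma[match(cls, frame)] * d^2)
  logP <- vapply(
    frame,
    function(q) sum(log1p(-m[cls == q])),
    numeric(1)
  )
  logPsum <- sum(logP)
  mu <- (1 - exp(logP)) * exp(logPsum - logP)
  omega <- exp(logPsum)
  total <- sum(mu) + omega
  if (total <= 1e-300) stop_mlploc("total conflict in neighbor evidence")
  mass_function(setNames(mu / total, frame), omega = omega / total)
}

#' Combined belief over classes from the K nearest neighbors
#'
#' Finds the K nearest training entries under the mode's distance (ties at
#' the K-th distance are all included), turns each into a basic belief
#' assignment with [bba_from_neighbor()], and folds them with Dempster's
#' rule. The combined singleton mass of a class equals its belief under
#' this evidence structure.
#'
#' @param query Descriptor vector.
#' @param training [etknn_training()] object.
#' @param params [etknn_params()]; `gamma` must be set (see
#'   [optimize_gammas()] / [init_gammas()]).
#' @return [mass_function()] of combined masses.
#' @export
belief_scores <- function(query, training, params) {
  d <- distances_to(training, query)
  nn <- k_nearest(d, params$K)
  bbas <- lapply(nn, function(i) {
    bba_from_neighbor(d[i], training$y[i], params, training$frame)
  })
  Reduce(dempster_combine, bbas, accumulate = FALSE)
}

#' Classify a query with the evidence-theoretic K-nearest-neighbor rule
#'
#' Assigns the class whose combined belief (singleton mass) is maximal.
#' Exact ties are broken by a uniform random draw from the tied set using
#' the session random number generator (seed it for reproducibility), or
#' returned whole with `ties = "all"`.
#'
#' @inheritParams belief_scores
#' @param ties `"random"` (default, the single-class contract) or `"all"`
#'   (return every argmax class; used by the ensemble's fractional votes).
#' @return Character class label (or vector of tied labels when
#'   `ties = "all"`), with the [mass_function()] attached as attribute
#'   `masses`.
#' @export
etknn_classify <- function(query, training, params,
                           ties = c("random", "all")) {
  ties <- match.arg(ties)
  m <- belief_scores(query, training, params)
  s <- as.numeric(m)[seq_along(training$frame)]
  top <- which(s >= max(s) - 1e-12)
  cls <- training$frame[top]
  out <- if (length(cls) > 1 && ties == "random") {
    cls[sample.int(length(cls), 1)]
  } else {
    cls
  }
  attr(out, "masses") <- m
  out
}

#' Initialize the gamma rates from training dispersion
#'
#' The inverse mean squared within-class pairwise distance sets the scale
#' of the evidence kernel. With `pooled = TRUE` (default) all classes
#' start from the dispersion pooled over classes; the leave-one-out
#' optimization then differentiates them only where the data demand it.
#' With `pooled = FALSE` each class uses its own dispersion,
#' `gamma_q = 1 / msd_q`. The pooled start is the safer default: per-class
#' dispersions of near-degenerate classes reflect how many boundary
#' (multi-location) members a class happens to have rather than its
#' tightness, and the resulting gamma heterogeneity skews the combined
#' evidence between the true locations of a bi-located query. Degenerate
#' scales fall back from pooled within-class dispersion to the overall
#' mean squared pairwise distance, then to 1.
#'
#' @param training [etknn_training()] object.
#' @param pooled Start every class from the pooled within-class scale.
#' @return Named numeric vector of gamma values.
#' @export
init_gammas <- function(training, pooled = TRUE) {
  D2 <- pairwise_sqdist(training)
  n <- nrow(D2)
  within <- lapply(training$frame, function(q) {
    idx <- which(training$y == q)
    if (length(idx) < 2) {
      return(numeric())
    }
    sub <- D2[idx, idx, drop = FALSE]
    sub[upper.tri(sub)]
  })
  all_within <- unlist(within)
  pooled_msd <- if (length(all_within)) mean(all_within) else 0
  pos <- D2[upper.tri(D2)]
  pos <- pos[pos > 1e-9]
  fallback <- if (is.finite(pooled_msd) && pooled_msd > 1e-9) {
    1 / pooled_msd
  } else if (length(pos)) {
    # every class is a point cluster: approach the voting-KNN limit by
    # making evidence at the smallest observed separation numerically
    # negligible (exp(-27.6) ~ 1e-12), yet finite so nearer unseen
    # queries still combine smoothly
    -log(1e-12) / min(pos)
  } else {
    1
  }
  out <- if (pooled) {
    rep(fallback, length(training$frame))
  } else {
    vapply(within, function(d2) {
      msd <- if (length(d2)) mean(d2) else 0
      if (is.finite(msd) && msd > 1e-9) 1 / msd else fallback
    }, numeric(1))
  }
  setNames(out, training$frame)
}

pairwise_sqdist <- function(training) {
  x <- training$x
  if (training$distance == "euclidean") {
    g <- tcrossprod(x)
    sq <- diag(g)
    pmax(outer(sq, sq, "+") - 2 * g, 0)
  } else {
    nx <- sqrt(rowSums(x^2))
    if (any(nx == 0)) {
      stop_mlploc("angular distance undefined for a zero vector")
    }
    pmax(1 - tcrossprod(x / nx), 0)^2
  }
}

# leave-one-out squared error between combined singleton masses and one-hot
# targets, vectorized over the query entries for fixed neighbor lists
loo_error <- function(gamma, flat, n, frame, alpha, y_int, qset) {
  m <- alpha * exp(-gamma[flat$cls] * flat$d2)
  m <- pmin(m, 1 - 1e-12)
  logP <- matrix(0, n, length(frame))
  acc <- rowsum(log1p(-m), group = flat$grp, reorder = FALSE)
  logP[as.integer(rownames(acc))] <- acc
  logPsum <- rowSums(logP)
  mu <- (1 - exp(logP)) * exp(logPsum - logP)
  total <- rowSums(mu) + exp(logPsum)
  mu <- mu / total
  target <- matrix(0, n, length(frame))
  target[cbind(seq_len(n), y_int)] <- 1
  sum((mu[qset, , drop = FALSE] - target[qset, , drop = FALSE])^2)
}

#' Fit the per-class gamma rates by minimizing a leave-one-out error
#'
#' The "optimized" step of the OET-KNN rule: gradient descent (finite
#' central differences on `log(gamma)`, backtracking halving line search)
#' on the leave-one-out squared error between each training entry's
#' combined singleton masses and its one-hot class target. Neighbor sets
#' are distance-determined and thus fixed throughout, so the objective is
#' smooth in gamma. Accepted steps never increase the error.
#'
#' When entry ids are available, two refinements follow from treating the
#' protein, not the locative entry, as the statistical unit: (1) an
#' entry's leave-one-out neighborhood excludes every entry of the same
#' protein (a bi-located protein must not act as its own evidence), and
#' (2) only entries of single-location proteins contribute error terms —
#' a one-hot target is undefined for a protein that genuinely belongs to
#' two classes, and forcing one drives the fit toward degenerate rate
#' configurations. Multi-location entries still serve as neighbors.
#'
#' @param training [etknn_training()] object with at least two classes.
#' @param params [etknn_params()]; a `NULL` `gamma` starts from
#'   [init_gammas()].
#' @param max_iter Maximum accepted descent steps.
#' @param tol Stop when the error improvement falls below `tol`.
#' @param step Initial step size on the log scale.
#' @param converged Mean per-entry squared-error floor: when the current
#'   error divided by the number of scored entries is already below this,
#'   the masses are essentially exact and further descent would only chase
#'   floating-point residue (and can distort the per-class rates doing
#'   so).
#' @return `etknn_params` with fitted `gamma` and attributes `error_trace`
#'   (error after each accepted step, starting at the initial error) and
#'   `initial_error`.
#' @export
optimize_gammas <- function(training, params = etknn_params(),
                            max_iter = 20, tol = 1e-6, step = 0.5,
                            converged = 1e-4) {
  frame <- training$frame
  if (length(unique(training$y)) < 2) {
    stop_mlploc("gamma optimization needs at least two classes")
  }
  n <- nrow(training$x)
  D2 <- pairwise_sqdist(training)
  diag(D2) <- Inf # leave-one-out: never one's own neighbor
  if (!is.null(training$ids)) {
    # a multi-location protein's twin entries share an id; leave the whole
    # protein out, as the jackknife does, so its own copies are never its
    # evidence
    same <- outer(training$ids, training$ids, "==")
    D2[same] <- Inf
    diag(D2) <- Inf
  }
  K <- min(params$K, n - 1L)
  y_int <- match(training$y, frame)
  nn <- lapply(seq_len(n), function(i) k_nearest(D2[i, ], K))
  flat <- list(
    grp = unlist(lapply(seq_len(n), function(i) {
      (match(training$y[nn[[i]]], frame) - 1L) * n + i
    })),
    cls = unlist(lapply(nn, function(ix) match(training$y[ix], frame))),
    d2 = unlist(lapply(seq_len(n), function(i) D2[i, nn[[i]]]))
  )
  qset <- seq_len(n)
  if (!is.null(training$ids)) {
    multi <- training$ids %in% training$ids[duplicated(training$ids)]
    if (!all(multi)) qset <- which(!multi)
  }
  gamma <- params$gamma %||% init_gammas(training)
  gamma <- unname(gamma[frame])
  f <- function(g) {
    loo_error(g, flat, n, frame, params$alpha, y_int, qset)
  }
  err <- f(gamma)
  trace <- err
  h <- 1e-4
  for (iter in seq_len(max_iter)) {
    if (err / length(qset) < converged) break
    lg <- log(gamma)
    grad <- vapply(seq_along(gamma), function(q) {
      up <- lg
      dn <- lg
      up[q] <- up[q] + h
      dn[q] <- dn[q] - h
      (f(exp(up)) - f(exp(dn))) / (2 * h)
    }, numeric(1))
    gnorm <- sqrt(sum(grad^2))
    if (!is.finite(gnorm)) stop_mlploc("non-finite error gradient")
    if (gnorm < 1e-12) break
    s <- step
    improved <- FALSE
    for (bt in 1:20) {
      cand <- exp(lg - s * grad / gnorm)
      e2 <- f(cand)
      if (is.finite(e2) && e2 <= err - 1e-15) {
        gamma <- cand
        err <- e2
        improved <- TRUE
        break
      }
      s <- s / 2
    }
    if (!improved) break
    trace <- c(trace, err)
    if (length(trace) > 1 &&
      trace[length(trace) - 1] - err < tol) {
      break
    }
  }
  out <- etknn_params(
    K = params$K, alpha = params$alpha,
    gamma = setNames(gamma, frame)
  )
  attr(out, "error_trace") <- trace
  attr(out, "initial_error") <- trace[1]
  out
}
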