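# shared fixtures and independent oracles

toy_homology <- function() {
  data.frame(
    query = c("Q1", "Q1", "Q2", "Q2", "Q2"),
    accession = c("A", "B", "C", "D", "E"),
    identity = c(40, 10, 60, 30, 28),
    evalue = c(1e-50, 1e-3, 1e-20, 1e-8, 1e-30),
    stringsAsFactors = FALSE
  )
}

toy_annotations <- function() {
  list(
    A = c("GO:0000001"),
    B = c("GO:0000001", "GO:0000003"),
    C = c("GO:0000002"),
    D = c("GO:0000003"),
    E = c("GO:0000001", "GO:0000002")
  )
}

toy_go_index <- function() sprintf("GO:%07d", 1:3)

# exhaustive power-set implementation of Dempster's rule for focal sets that
# are singletons or the whole frame; the independent oracle for
# dempster_combine (enumerates every focal pair, intersects, renormalizes)
dempster_oracle <- function(m1, m2, classes) {
  focal <- c(as.list(classes), list(classes)) # singletons then Omega
  v1 <- as.numeric(m1)
  v2 <- as.numeric(m2)
  out <- setNames(numeric(length(focal)), c(classes, "OMEGA"))
  conflict <- 0
  for (i in seq_along(focal)) {
    for (j in seq_along(focal)) {
      inter <- intersect(focal[[i]], focal[[j]])
      p <- v1[i] * v2[j]
      if (length(inter) == 0) {
        conflict <- conflict + p
      } else if (setequal(inter, classes)) {
        out["OMEGA"] <- out["OMEGA"] + p
      } else {
        stopifnot(length(inter) == 1)
        out[inter] <- out[inter] + p
      }
    }
  }
  out / (1 - conflict)
}

random_mass <- function(classes) {
  w <- stats::runif(length(classes) + 1)
  w <- w / sum(w)
  mass_function(setNames(w[seq_along(classes)], classes),
    omega = w[length(w)]
  )
}

# tiny well-separated 2-class training set in 2 dimensions
separable_training <- function(n_per = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(
    cbind(stats::rnorm(n_per, 0, 0.1), stats::rnorm(n_per, 0, 0.1)),
    cbind(stats::rnorm(n_per, 5, 0.1), stats::rnorm(n_per, 5, 0.1))
  )
  etknn_training(x, rep(c("A", "B"), each = n_per),
    distance = "euclidean",
    ids = sprintf("P%02d", seq_len(2 * n_per))
  )
}

# brute-force belief combination: fold bba_from_neighbor over an explicit
# exhaustive K-nearest search done with plain loops
belief_oracle <- function(query, training, params) {
  d <- apply(training$x, 1, function(row) {
    if (training$distance == "euclidean") {
      distance_euclidean(row, query)
    } else {
      distance_angular(row, query)
    }
  })
  kth <- sort(d)[min(params$K, length(d))]
  idx <- which(d <= kth + 1e-12)
  m <- NULL
  for (i in idx) {
    b <- bba_from_neighbor(d[i], training$y[i], params, training$frame)
    m <- if (is.null(m)) b else dempster_combine(m, b)
  }
  m
}

small_sim <- function(seed = 5, ...) {
  generate_benchmark(sim_config(
    M = 3, per_location = 6, multi_fraction = 0.15, seed = seed, ...
  ))
}

sim_features <- function(sim, config = ensemble_config()) {
  build_features(
    sim$benchmark$protein, sim$homology, sim$annotations, sim$go_index,
    sim$domains, sim$domain_index, sim$pssms,
    config = config, quiet = TRUE
  )
}
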