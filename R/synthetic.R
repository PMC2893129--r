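#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates the full input world of the pipeline — labeled
#' multi-location benchmark, homology and annotation tables, domain hits,
#' per-protein scoring matrices, FASTA sequences — with controllable class
#' separation, so that classifier behavior can be verified against an
#' analytic ground truth no real database can provide at desk scale.
#'
#' Each location gets a disjoint GO-term signature, domain signature and
#' scoring-matrix profile. At separation `s = 1` and `noise = 0` every
#' protein of a location carries exactly its signatures (descriptors
#' within a location are identical); as `s` falls, signature terms drop
#' out and background terms mix in, and profiles shrink toward a shared
#' background, eroding separability. Multi-location proteins blend the
#' signatures of two locations and carry both labels.
#'
#' @param M Number of location sites (default 4; up to 12, named from
#'   [plant_locations()]).
#' @param per_location Proteins whose primary site is each location
#'   (default 20).
#' @param length_range Sequence length range (default 60..400; chains
#'   under 50 residues are fragments and are never generated).
#' @param separation Class separation `s` in `[0, 1]`.
#' @param multi_fraction Probability that a protein carries a second
#'   location (default 0.08, the observed multi-location rate).
#' @param go_coverage Fraction of proteins with a homology set, i.e. with
#'   GO information (annotation informativeness; default 0.85 so both
#'   routing branches are exercised).
#' @param noise Noise rate in `[0, 1]`: scoring-matrix jitter scale and
#'   random annotation flips.
#' @param go_sig_size,domain_sig_size Signature terms/domains per location.
#' @param go_background,domain_background Extra non-diagnostic index
#'   entries.
#' @param seed Generator seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(M = 4, per_location = 20, length_range = c(60, 400),
                       separation = 1, multi_fraction = 0.08,
                       go_coverage = 0.85, noise = 0,
                       go_sig_size = 8, domain_sig_size = 6,
                       go_background = 20, domain_background = 12,
                       seed = 1L) {
  stopifnot(
    M >= 2, M <= 12, per_location >= 2,
    length_range[1] >= 50, length_range[2] >= length_range[1],
    separation >= 0, separation <= 1,
    multi_fraction >= 0, multi_fraction <= 1,
    go_coverage >= 0, go_coverage <= 1, noise >= 0, noise <= 1
  )
  structure(
    list(
      M = as.integer(M), per_location = as.integer(per_location),
      length_range = as.integer(length_range), separation = separation,
      multi_fraction = multi_fraction, go_coverage = go_coverage,
      noise = noise, go_sig_size = as.integer(go_sig_size),
      domain_sig_size = as.integer(domain_sig_size),
      go_background = as.integer(go_background),
      domain_background = as.integer(domain_background),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate a synthetic scoring matrix
#'
#' L rows of a 20-component profile plus integer-rounded Gaussian jitter,
#' in the raw (unstandardized) integer form a PSI-BLAST ASCII file
#' carries.
#'
#' @param profile Numeric 20-vector (the class profile).
#' @param length Number of positions L.
#' @param noise Jitter rate; the per-entry standard deviation is
#'   `4 * noise` score units.
#' @param seed Seed (`NULL` to use the current generator state).
#' @return Integer L x 20 matrix in alphabetical column order.
#' @export
generate_pssm <- function(profile, length, noise = 0, seed = NULL) {
  stopifnot(length(profile) == 20, length >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rep(profile, each = length), nrow = length)
  if (noise > 0) {
    m <- m + matrix(rnorm(length * 20, sd = 4 * noise), nrow = length)
  }
  m <- round(m)
  storage.mode(m) <- "integer"
  colnames(m) <- AA_ALPHABET
  m
}

sim_indices <- function(config) {
  M <- config$M
  go_terms <- sprintf(
    "GO:%07d",
    seq_len(M * config$go_sig_size + config$go_background)
  )
  domains <- sprintf(
    "pfam%05d",
    seq_len(M * config$domain_sig_size + config$domain_background)
  )
  go_sig <- lapply(seq_len(M), function(q) {
    go_terms[(q - 1) * config$go_sig_size + seq_len(config$go_sig_size)]
  })
  dom_sig <- lapply(seq_len(M), function(q) {
    domains[(q - 1) * config$domain_sig_size +
      seq_len(config$domain_sig_size)]
  })
  # disjoint 5-position score blocks per class, on a mild negative floor
  prof <- lapply(seq_len(M), function(q) {
    v <- rep(-2, 20)
    v[((q - 1) * 5) %% 20 + seq_len(5)] <- 6
    v
  })
  bg_prof <- rep(0, 20)
  list(
    go_terms = go_terms, domains = domains, go_sig = go_sig,
    dom_sig = dom_sig, prof = prof, bg_prof = bg_prof
  )
}

# keep each signature term w.p. 1 - 0.5(1-s); admix terms from the global
# background — which includes the other classes' signatures, so low s
# genuinely confuses classes — w.p. 0.3(1-s) + 0.1 noise each
sample_terms <- function(signature, all_terms, s, noise) {
  keep <- signature[runif(length(signature)) < 1 - 0.5 * (1 - s)]
  pool <- setdiff(all_terms, signature)
  bg_p <- 0.3 * (1 - s) + 0.1 * noise
  extra <- pool[runif(length(pool)) < bg_p]
  unique(c(keep, extra))
}

#' Generate a complete synthetic benchmark
#'
#' Draws the labeled protein set and every input table/file the
#' descriptor layer reads. All randomness flows from `config$seed`, so
#' identical configurations give byte-identical output trees.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory: when given, the full file tree (TSV
#'   tables, index files, FASTA, per-protein ASCII PSSM files and a JSON
#'   manifest) is written there.
#' @return List of class `sim_benchmark` with elements `benchmark` (data
#'   frame `protein`, list-column `labels`), `homology`, `annotations`,
#'   `go_index`, `domains`, `domain_index`, `sequences`, `pssms` (named
#'   list of raw integer matrices), `frame`, `config`, and `dir` (when
#'   written).
#' @export
generate_benchmark <- function(config = sim_config(), dir = NULL) {
  set.seed(config$seed)
  M <- config$M
  frame <- plant_locations()[seq_len(M)]
  ix <- sim_indices(config)
  s <- config$separation
  noise <- config$noise

  n <- M * config$per_location
  primary <- rep(seq_len(M), each = config$per_location)
  ids <- sprintf("SYN%04d", seq_len(n))
  second <- rep(NA_integer_, n)
  is_multi <- runif(n) < config$multi_fraction
  second[is_multi] <- vapply(primary[is_multi], function(q) {
    sample(setdiff(seq_len(M), q), 1)
  }, integer(1))

  labels <- lapply(seq_len(n), function(i) {
    frame[sort(c(primary[i], second[i]), na.last = NA)]
  })
  benchmark <- data.frame(protein = ids, stringsAsFactors = FALSE)
  benchmark$labels <- labels

  lens <- sample(
    seq(config$length_range[1], config$length_range[2]), n,
    replace = TRUE
  )
  sequences <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  }, character(1))
  names(sequences) <- ids

  # annotation coverage is stratified by primary location: every class
  # loses the same number of proteins to the no-homology branch, so class
  # evidence is not confounded by annotation availability
  has_go <- logical(n)
  n_cov <- round(config$go_coverage * config$per_location)
  for (q in seq_len(M)) {
    block <- which(primary == q)
    has_go[sample(block, n_cov)] <- TRUE
  }

  hom_rows <- list()
  ann <- list()
  dom_rows <- list()
  pssms <- vector("list", n)
  names(pssms) <- ids

  for (i in seq_len(n)) {
    sites <- c(primary[i], second[i])
    sites <- sites[!is.na(sites)]
    # GO: one reference accession per protein carrying its sampled terms
    if (has_go[i]) {
      terms <- unique(unlist(lapply(sites, function(q) {
        sample_terms(ix$go_sig[[q]], ix$go_terms, s, noise)
      })))
      if (length(terms)) {
        acc <- paste0("REF_", ids[i])
        ann[[acc]] <- terms
        hom_rows[[length(hom_rows) + 1L]] <- data.frame(
          query = ids[i], accession = acc,
          identity = round(runif(1, 30, 90), 1),
          evalue = 10^runif(1, -80, -10), stringsAsFactors = FALSE
        )
        if (noise > 0 && runif(1) < noise) { # decoy failing the cutoffs
          hom_rows[[length(hom_rows) + 1L]] <- data.frame(
            query = ids[i], accession = paste0("DECOY_", ids[i]),
            identity = round(runif(1, 5, 20), 1),
            evalue = 10^runif(1, -2, 1), stringsAsFactors = FALSE
          )
        }
      }
    }
    # domains: significant hits to sampled signature domains
    doms <- unique(unlist(lapply(sites, function(q) {
      sample_terms(ix$dom_sig[[q]], ix$domains, s, noise)
    })))
    if (length(doms)) {
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        protein = ids[i], domain_id = doms,
        evalue = 10^runif(length(doms), -30, -6), stringsAsFactors = FALSE
      )
    }
    # scoring matrix: blended class profile shrunk toward the shared
    # background plus a per-protein idiosyncratic component that grows as
    # separation falls
    prof <- Reduce(`+`, ix$prof[sites]) / length(sites)
    prof <- s * prof + (1 - s) * (ix$bg_prof + rnorm(20, sd = 3))
    pssms[[i]] <- generate_pssm(prof, lens[i], noise = noise, seed = NULL)
  }

  out <- structure(
    list(
      benchmark = benchmark,
      homology = if (length(hom_rows)) {
        do.call(rbind, hom_rows)
      } else {
        data.frame(
          query = character(), accession = character(),
          identity = numeric(), evalue = numeric()
        )
      },
      annotations = ann,
      go_index = ix$go_terms,
      domains = do.call(rbind, dom_rows),
      domain_index = ix$domains,
      sequences = sequences,
      pssms = pssms,
      frame = frame,
      config = config
    ),
    class = "sim_benchmark"
  )
  if (!is.null(dir)) {
    write_benchmark_tree(out, dir)
    out$dir <- dir
  }
  out
}

#' @export
print.sim_benchmark <- function(x, ...) {
  bd <- dataset_breakdown(x$benchmark, M = x$config$M)
  cat(
    "<sim_benchmark>", bd$n_dif, "proteins /", count_locative(bd),
    "locative entries over", x$config$M, "locations (",
    sprintf("%.1f%%", multi_location_fraction(bd)), "multi-location)\n"
  )
  invisible(x)
}
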