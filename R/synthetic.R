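#' Specification of a synthetic incidence community
#'
#' Describes a site-by-species community with controlled assembly
#' structure, sized by default to the scale of the vent-system matrices
#' the package targets (8 sites, 40 species, per-site richness around
#' half the pool, a right-skewed geometric occupancy-frequency law with
#' many single-site species and a few ubiquitous ones).
#'
#' Regimes: `random` draws each site under the fixed-richness,
#' frequency-weighted null model of [simulate_null_matrix()]; `nested`
#' ranks the species pool and gives site *i* the top `richness[i]`
#' species, making every pair strictly nested; `turnover` slides equal-
#' richness windows along the ranked pool with a fixed offset, producing
#' pure replacement (no richness differences); `mixed` gives every site a
#' shared nested core of `mix_weight * richness` top-ranked species plus
#' a sliding-window complement drawn from the remaining pool.
#'
#' @param n_sites,n_species community dimensions.
#' @param regime one of `"random"`, `"nested"`, `"turnover"`, `"mixed"`.
#' @param richness per-site richness targets; defaults to
#'   `round(n_species / 2)` everywhere, except a spread
#'   `n_species/4 .. 3*n_species/4` for the nested regime (strict nesting
#'   needs unequal richness to be visible).
#' @param freq_law `"geometric"` (weight `q^rank`) or `"uniform"`.
#' @param q geometric ratio in (0, 1); default 0.8.
#' @param offset window offset for turnover/mixed; default spreads the
#'   windows across the available pool.
#' @param mix_weight nested-core fraction in \[0, 1\] for `mixed`.
#' @param seed integer seed; generation is bit-reproducible given the
#'   spec.
#' @return object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_sites = 8, n_species = 40,
                           regime = c("random", "nested", "turnover",
                                      "mixed"),
                           richness = NULL,
                           freq_law = c("geometric", "uniform"),
                           q = 0.8, offset = NULL, mix_weight = 0.5,
                           seed = 1) {
  regime <- match.arg(regime)
  freq_law <- match.arg(freq_law)
  if (n_sites < 2 || n_species < 2) {
    stop("need at least 2 sites and 2 species", call. = FALSE)
  }
  if (is.null(richness)) {
    richness <- if (regime == "nested") {
      round(seq(n_species / 4, 3 * n_species / 4,
                length.out = n_sites))
    } else {
      rep(round(n_species / 2), n_sites)
    }
  }
  richness <- as.integer(richness)
  if (length(richness) == 1L) richness <- rep(richness, n_sites)
  if (length(richness) != n_sites || any(richness < 1) ||
      any(richness > n_species)) {
    stop("richness must give one value in [1, n_species] per site",
         call. = FALSE)
  }
  if (regime == "turnover" && length(unique(richness)) != 1L) {
    stop("turnover regime requires equal per-site richness",
         call. = FALSE)
  }
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  if (mix_weight < 0 || mix_weight > 1) {
    stop("mix_weight must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_sites = as.integer(n_sites),
                 n_species = as.integer(n_species), regime = regime,
                 richness = richness, freq_law = freq_law, q = q,
                 offset = offset, mix_weight = mix_weight,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

species_weights <- function(spec) {
  if (spec$freq_law == "uniform") {
    rep(1, spec$n_species)
  } else {
    spec$q^(seq_len(spec$n_species) - 1)
  }
}

#' Generate a synthetic incidence matrix
#'
#' @param spec a [synthetic_spec()].
#' @return an [incidence_matrix()] with `spec$n_sites` rows and
#'   `spec$n_species` columns.
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  S <- spec$n_species
  n <- spec$n_sites
  r <- spec$richness
  occ <- matrix(0L, n, S,
                dimnames = list(paste0("site", seq_len(n)),
                                paste0("sp", seq_len(S))))
  if (spec$regime == "random") {
    w <- species_weights(spec)
    with_seed(spec$seed, {
      for (s in seq_len(n)) {
        occ[s, sample.int(S, r[s], prob = w)] <- 1L
      }
    })
  } else if (spec$regime == "nested") {
    for (s in seq_len(n)) occ[s, seq_len(r[s])] <- 1L
  } else if (spec$regime == "turnover") {
    r1 <- r[1L]
    off <- spec$offset
    if (is.null(off)) off <- max(1L, (S - r1) %/% max(1L, n - 1L))
    if (off < 1L || r1 + (n - 1L) * off > S) {
      stop("species pool too small for the turnover windows",
           call. = FALSE)
    }
    for (s in seq_len(n)) {
      start <- 1L + (s - 1L) * off
      occ[s, seq.int(start, start + r1 - 1L)] <- 1L
    }
  } else {                                   # mixed
    core <- pmin(round(spec$mix_weight * r), r)
    core_max <- max(core)
    tail_pool <- seq.int(core_max + 1L, S)
    need <- r - core
    if (max(need) > length(tail_pool)) {
      stop("species pool too small for the mixed regime", call. = FALSE)
    }
    # densely overlapping tail windows (offset 1) keep the replacement
    # signal strictly below the maximally separated turnover regime
    off <- spec$offset
    if (is.null(off)) off <- 1L
    for (s in seq_len(n)) {
      if (core[s] > 0) occ[s, seq_len(core[s])] <- 1L
      if (need[s] > 0) {
        # circular window over the tail pool so every site fits
        pos <- ((s - 1L) * off + seq_len(need[s]) - 1L) %%
          length(tail_pool) + 1L
        occ[s, tail_pool[pos]] <- 1L
      }
    }
  }
  incidence_matrix(occ)
}

#' Type-I calibration of the Raup-Crick classifier under its own null
#'
#' Generates `n_datasets` communities from the random (null-model) regime
#' and runs [raup_crick()] on each, supplying the generator's true
#' species weights so the tested null coincides exactly with the
#' generating process; the fraction of pairs classified significant
#' should then sit near the nominal `1 - ci_level`. (Re-estimating the
#' weights from each realized matrix instead — the default behaviour of
#' [raup_crick()] on field data, where the true law is unknown — flattens
#' the weight profile and shifts pairs toward the "similar" tail; see the
#' package vignette.)
#'
#' @param spec a [synthetic_spec()] with `regime = "random"`.
#' @param n_datasets number of generated communities.
#' @param n_sim null replicates per [raup_crick()] run.
#' @param ci_level significance level passed through.
#' @param seed integer seed governing both generation and testing.
#' @return list with `fraction_significant` (pooled over all pairs),
#'   `mc_se` (binomial Monte-Carlo standard error at the pooled pair
#'   count), `per_dataset` fractions, `n_pairs_total`.
#' @export
calibration_suite <- function(spec, n_datasets = 20, n_sim = 999,
                              ci_level = 0.95, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$regime != "random") {
    stop("calibration is defined under the random (null) regime only",
         call. = FALSE)
  }
  per <- numeric(n_datasets)
  n_pairs <- choose(spec$n_sites, 2)
  for (d in seq_len(n_datasets)) {
    spec_d <- spec
    spec_d$seed <- (seed * 1000L + d) %% .Machine$integer.max
    m <- generate_community(spec_d)
    rc <- raup_crick(m, n_sim = n_sim, ci_level = ci_level,
                     seed = spec_d$seed + 1L,
                     weights = species_weights(spec))
    per[d] <- mean(rc$sig_class != "ns")
  }
  frac <- mean(per)
  n_tot <- n_datasets * n_pairs
  list(fraction_significant = frac,
       mc_se = sqrt(frac * (1 - frac) / n_tot),
       per_dataset = per, n_pairs_total = n_tot)
}
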