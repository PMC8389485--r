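#' Minimum set of sites covering all species
#'
#' Finds the smallest combination of sites whose union of species equals
#' the regional richness (every species covered), enumerating subset
#' sizes in ascending order so that all minimal solutions are reported.
#' Exact search is used up to `exact_limit` sites; beyond that a greedy
#' heuristic (largest marginal species gain, ties broken by lowest site
#' index) returns a single non-exact solution.
#'
#' Species occurring at no site cannot be covered and are dropped with a
#' warning before the search.
#'
#' @param m an [incidence_matrix()].
#' @param method `"auto"` (exact within `exact_limit`, else greedy),
#'   `"exact"` or `"greedy"`.
#' @param exact_limit maximum number of sites for exhaustive search.
#' @return list with `min_size`, `solutions` (list of character vectors of
#'   site labels; a single element for the greedy method),
#'   `coverage_fraction` (`min_size / n_sites`), `gamma`, `exact`.
#' @export
minimum_set <- function(m, method = c("auto", "exact", "greedy"),
                        exact_limit = 25L) {
  method <- match.arg(method)
  m <- as_incidence(m)
  occ <- unclass(m)
  empty <- colSums(occ) == 0
  if (any(empty)) {
    warning(sum(empty), " species occupy no site and are excluded from ",
            "coverage", call. = FALSE)
    occ <- occ[, !empty, drop = FALSE]
  }
  if (ncol(occ) == 0L) stop("no species to cover", call. = FALSE)
  n <- nrow(occ)
  use_exact <- method == "exact" ||
    (method == "auto" && n <= exact_limit)
  if (method == "exact" && n > exact_limit) {
    stop("exact search limited to ", exact_limit, " sites", call. = FALSE)
  }
  if (use_exact) {
    for (k in seq_len(n)) {
      combos <- utils::combn(n, k)
      hit <- apply(combos, 2L, function(set) {
        all(colSums(occ[set, , drop = FALSE]) > 0)
      })
      if (any(hit)) {
        sols <- lapply(which(hit), function(ci) {
          site_ids(m)[combos[, ci]]
        })
        return(list(min_size = k, solutions = sols,
                    coverage_fraction = k / n, gamma = ncol(occ),
                    exact = TRUE))
      }
    }
  }
  # greedy complement: repeatedly add the site covering the most
  # still-uncovered species
  chosen <- integer(0)
  uncovered <- rep(TRUE, ncol(occ))
  while (any(uncovered)) {
    gain <- occ[, uncovered, drop = FALSE]
    best <- which.max(rowSums(gain))   # which.max: lowest index on ties
    chosen <- c(chosen, best)
    uncovered <- uncovered & colSums(occ[chosen, , drop = FALSE]) == 0
  }
  list(min_size = length(chosen),
       solutions = list(site_ids(m)[chosen]),
       coverage_fraction = length(chosen) / n, gamma = ncol(occ),
       exact = FALSE)
}

#' Species sharing between two groups of sites
#'
#' @param m an [incidence_matrix()].
#' @param groups named character vector or factor mapping every site label
#'   to one of exactly two group labels.
#' @return list with `groups` (per-group gamma), `shared_species`,
#'   `n_shared`, `gamma_combined`, `shared_fraction`
#'   (`n_shared / gamma_combined`).
#' @export
group_overlap <- function(m, groups) {
  m <- as_incidence(m)
  g <- resolve_groups(m, groups)
  lv <- unique(g)
  if (length(lv) != 2L) {
    stop("exactly two groups required, got ", length(lv), call. = FALSE)
  }
  occ <- unclass(m)
  pool <- lapply(lv, function(l) {
    species_ids(m)[colSums(occ[g == l, , drop = FALSE]) > 0]
  })
  names(pool) <- lv
  shared <- intersect(pool[[1L]], pool[[2L]])
  gamma_combined <- length(union(pool[[1L]], pool[[2L]]))
  list(groups = stats::setNames(lengths(pool), lv),
       shared_species = shared,
       n_shared = length(shared),
       gamma_combined = gamma_combined,
       shared_fraction = length(shared) / gamma_combined)
}

#' Filter pairwise results to within- or between-group pairs
#'
#' Works on any pairwise result table carrying `site_i`/`site_j` columns
#' ([decompose_all()], [raup_crick()]). `within` and `between` partition
#' the pair set: two groups of 8 sites yield 28 + 28 within pairs and
#' 8 x 8 = 64 between pairs.
#'
#' @param pairs data.frame with `site_i` and `site_j` columns.
#' @param groups named vector mapping site labels to group labels.
#' @param mode `"within"` or `"between"`.
#' @return the filtered data.frame.
#' @export
subset_pairs <- function(pairs, groups, mode = c("within", "between")) {
  mode <- match.arg(mode)
  groups <- stats::setNames(as.character(groups), names(groups))
  sites <- unique(c(pairs$site_i, pairs$site_j))
  miss <- setdiff(sites, names(groups))
  if (length(miss)) {
    stop("unlabeled site(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  same <- groups[pairs$site_i] == groups[pairs$site_j]
  pairs[if (mode == "within") same else !same, , drop = FALSE]
}

resolve_groups <- function(m, groups) {
  groups <- stats::setNames(as.character(groups), names(groups))
  ids <- site_ids(m)
  if (is.null(names(groups))) {
    if (length(groups) != length(ids)) {
      stop("unnamed group vector must match the site count",
           call. = FALSE)
    }
    names(groups) <- ids
  }
  miss <- setdiff(ids, names(groups))
  if (length(miss)) {
    stop("site(s) without group label: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  unname(groups[ids])
}
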