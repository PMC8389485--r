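#' Local contributions to beta diversity (LCBD)
#'
#' Decomposes the total community variance of an incidence matrix into
#' per-site contributions. Pairwise Jaccard dissimilarities `beta_J` are
#' square-root transformed (which makes them Euclidean-embeddable, so all
#' contributions are non-negative), the matrix `A = -0.5 * d^2` is
#' Gower-centred to `G`, and `ss_total = trace(G)` is the total sum of
#' squares; `lcbd_i = G_ii / ss_total` sums to 1 across sites.
#'
#' @param m an [incidence_matrix()] with at least two sites and at least
#'   one non-identical pair.
#' @return object of class `"lcbd"`: list with `site_ids`, `lcbd`,
#'   `ss_total`, `bd_total` (= `ss_total / (n - 1)`), `p_values`
#'   (`NULL` until [lcbd_permutation_test()] is run), `n_perm`, `seed`.
#' @export
lcbd_from_matrix <- function(m) {
  m <- as_incidence(m)
  if (nrow(m) < 2L) stop("LCBD needs at least two sites", call. = FALSE)
  d2 <- jaccard_matrix(m)           # squared distances: d^2 = beta_J
  n <- nrow(d2)
  A <- -0.5 * d2
  G <- A - rowMeans(A) - rep(colMeans(A), each = n) + mean(A)
  ss_total <- sum(diag(G))
  if (ss_total <= .Machine$double.eps * n) {
    stop("no beta diversity: all sites identical", call. = FALSE)
  }
  structure(list(site_ids = site_ids(m),
                 lcbd = stats::setNames(diag(G) / ss_total, site_ids(m)),
                 ss_total = ss_total,
                 bd_total = ss_total / (n - 1),
                 p_values = NULL, n_perm = 0L, seed = NULL),
            class = "lcbd")
}

# beta_J for every pair as a full symmetric matrix (zero diagonal); used
# as squared sqrt-Jaccard distances.
jaccard_matrix <- function(m) {
  occ <- unclass(as_incidence(m))
  shared <- tcrossprod(occ)
  alpha <- rowSums(occ)
  tot <- outer(alpha, alpha, "+") - shared
  beta <- ifelse(tot > 0, 1 - shared / tot, 0)
  diag(beta) <- 0
  beta
}

#' Permutation test of LCBD values
#'
#' Significance of each site's contribution under a null model that
#' permutes every species column independently across sites, preserving
#' each species' occupancy frequency while breaking site structure.
#' P-values use the add-one correction
#' `p_i = (1 + #\{lcbd_null_i >= lcbd_obs_i\}) / (1 + n_perm)`.
#'
#' @param m an [incidence_matrix()].
#' @param n_perm number of permutations (0 returns point estimates only).
#' @param seed integer seed.
#' @return an `"lcbd"` object with `p_values` filled in.
#' @export
lcbd_permutation_test <- function(m, n_perm = 9999, seed = 1) {
  res <- lcbd_from_matrix(m)
  if (n_perm == 0) return(res)
  m <- as_incidence(m)
  occ <- unclass(m)
  n <- nrow(occ)
  obs <- res$lcbd
  count <- rep(0L, n)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      perm <- apply(occ, 2L, function(col) col[sample.int(n)])
      lc_null <- lcbd_values(perm)
      count <- count + (lc_null >= obs - 1e-12)
    }
  })
  res$p_values <- stats::setNames((1 + count) / (1 + n_perm), res$site_ids)
  res$n_perm <- as.integer(n_perm)
  res$seed <- as.integer(seed)
  res
}

# bare LCBD vector from a plain 0/1 matrix; NA-free fast path for the
# permutation loop (returns zeros if the permuted matrix is degenerate).
lcbd_values <- function(occ) {
  shared <- tcrossprod(occ)
  alpha <- rowSums(occ)
  tot <- outer(alpha, alpha, "+") - shared
  d2 <- ifelse(tot > 0, 1 - shared / tot, 0)
  diag(d2) <- 0
  n <- nrow(d2)
  A <- -0.5 * d2
  G <- A - rowMeans(A) - rep(colMeans(A), each = n) + mean(A)
  ss <- sum(diag(G))
  if (ss <= 0) rep(0, n) else diag(G) / ss
}

#' @export
print.lcbd <- function(x, ...) {
  cat(sprintf("LCBD over %d sites (SS_total = %.4f, BD_total = %.4f)\n",
              length(x$lcbd), x$ss_total, x$bd_total))
  df <- data.frame(site = x$site_ids, lcbd = round(unname(x$lcbd), 4))
  if (!is.null(x$p_values)) df$p_value <- round(unname(x$p_values), 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.lcbd <- function(x, ...) {
  df <- data.frame(site = x$site_ids, lcbd = unname(x$lcbd),
                   stringsAsFactors = FALSE)
  if (!is.null(x$p_values)) df$p_value <- unname(x$p_values)
  df
}
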