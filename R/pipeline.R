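#' Configure an end-to-end analysis run
#'
#' Bundles inputs and tuning parameters for [run_pipeline()]. The seed is
#' mandatory: every stochastic stage (Raup-Crick nulls, LCBD and
#' group-comparison permutations) derives its stream from it, so a run is
#' a pure function of (inputs, config).
#'
#' @param input an [incidence_matrix()] or a CSV path.
#' @param layout CSV layout when `input` is a path.
#' @param groups optional named vector mapping site labels to system
#'   labels; enables within/between splits and permutation tests.
#' @param n_sim Raup-Crick null replicates.
#' @param n_perm permutations for LCBD and group tests.
#' @param ci_level Raup-Crick confidence level in (0, 1).
#' @param alpha significance threshold for reporting, in (0, 1).
#' @param seed integer seed (required).
#' @param outdir output directory; created if missing.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input, layout = "wide", groups = NULL,
                            n_sim = 9999, n_perm = 9999,
                            ci_level = 0.95, alpha = 0.05, seed,
                            outdir = tempfile("ventbeta_run_")) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1 || alpha <= 0 || alpha >= 1) {
    stop("ci_level and alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(list(input = input, layout = layout, groups = groups,
                 n_sim = n_sim, n_perm = n_perm, ci_level = ci_level,
                 alpha = alpha, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the full incidence-based beta-diversity pipeline
#'
#' Executes every analytical stage on one incidence matrix and writes a
#' report bundle to `config$outdir`: per-pair decomposition
#' (`pairs.csv`), component summary (`summary.csv`), per-site/system
#' richness (`richness.csv`), LCBD table (`lcbd.csv`), Raup-Crick table
#' (`raupcrick.csv`), minimum-set solutions (`minimum_set.json`), UPGMA
#' dendrogram (`dendrogram.nwk`), simplex coordinates (`ternary.csv`)
#' and a run log (`run_log.txt`). When `groups` are supplied it adds the
#' within/between pair split (`pairs_between.csv`), group species overlap
#' (`group_overlap.json`) and permutation ANOVA/t-test results
#' (`group_tests.csv`).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all computed results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  m <- if (inherits(config$input, "incidence")) {
    config$input
  } else if (is.character(config$input)) {
    read_incidence(config$input, layout = config$layout)
  } else {
    as_incidence(config$input)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  pairs <- decompose_all(m)
  utils::write.csv(pairs, out("pairs.csv"), row.names = FALSE)
  summary_df <- summarize_decomposition(pairs)
  occ_sum <- occupancy_summary(m)
  rich <- data.frame(site = site_ids(m), alpha = unname(occ_sum$alpha))
  utils::write.csv(rich, out("richness.csv"), row.names = FALSE)
  lcbd_res <- lcbd_permutation_test(m, n_perm = config$n_perm,
                                    seed = config$seed)
  utils::write.csv(as.data.frame(lcbd_res), out("lcbd.csv"),
                   row.names = FALSE)
  rc <- raup_crick(m, n_sim = config$n_sim, ci_level = config$ci_level,
                   seed = config$seed)
  utils::write.csv(rc, out("raupcrick.csv"), row.names = FALSE)
  summary_df <- rbind(summary_df, data.frame(
    component = "beta_rc", mean = mean(rc$beta_rc),
    median = stats::median(rc$beta_rc), min = min(rc$beta_rc),
    max = max(rc$beta_rc), n = nrow(rc)))
  summary_extra <- data.frame(
    quantity = c("gamma", "mean_alpha", "sd_alpha", "whittaker_ratio",
                 "pct_significant_beta_rc"),
    value = c(occ_sum$gamma, mean(occ_sum$alpha),
              stats::sd(occ_sum$alpha), whittaker_ratio(m),
              percent_significant(rc)))
  utils::write.csv(summary_df, out("summary.csv"), row.names = FALSE)
  utils::write.csv(summary_extra, out("diversity.csv"),
                   row.names = FALSE)
  ms <- minimum_set(m)
  jsonlite::write_json(
    list(min_size = ms$min_size, n_sites = nrow(m),
         coverage_fraction = ms$coverage_fraction, exact = ms$exact,
         solutions = ms$solutions),
    out("minimum_set.json"), auto_unbox = TRUE, digits = NA)
  tern <- ternary_coordinates(pairs)
  utils::write.csv(tern, out("ternary.csv"), row.names = FALSE)
  h <- upgma(dissimilarity_matrix(pairs))
  dendrogram_newick(h, out("dendrogram.nwk"))

  groups_out <- NULL
  if (!is.null(config$groups)) {
    g <- resolve_groups_any(m, config$groups)
    between <- subset_pairs(pairs, g, "between")
    within <- subset_pairs(pairs, g, "within")
    utils::write.csv(between, out("pairs_between.csv"),
                     row.names = FALSE)
    gw <- split(within$beta_j, g[within$site_i])
    tests <- list()
    if (length(gw) >= 2L && all(lengths(gw) >= 2L)) {
      an <- perm_anova(gw, n_perm = config$n_perm, seed = config$seed)
      tests$anova_beta_j <- c(statistic = an$statistic,
                              p_value = an$p_value)
      if (length(gw) == 2L) {
        tt <- perm_t_test(gw[[1L]], gw[[2L]], n_perm = config$n_perm,
                          seed = config$seed)
        tests$t_beta_j <- c(statistic = tt$statistic,
                            p_value = tt$p_value)
      }
    }
    ov <- if (length(unique(g)) == 2L) group_overlap(m, g) else NULL
    if (!is.null(ov)) {
      jsonlite::write_json(
        list(gamma_by_group = as.list(ov$groups),
             n_shared = ov$n_shared,
             gamma_combined = ov$gamma_combined,
             shared_fraction = ov$shared_fraction,
             shared_species = ov$shared_species),
        out("group_overlap.json"), auto_unbox = TRUE, digits = NA)
    }
    if (length(tests)) {
      tdf <- data.frame(test = names(tests),
                        statistic = vapply(tests, `[[`, numeric(1),
                                           "statistic"),
                        p_value = vapply(tests, `[[`, numeric(1),
                                         "p_value"))
      utils::write.csv(tdf, out("group_tests.csv"), row.names = FALSE)
    }
    groups_out <- list(between = between, within = within,
                       overlap = ov, tests = tests)
  }

  writeLines(c(
    sprintf("ventbeta %s | R %s.%s",
            as.character(utils::packageVersion("ventbeta")),
            R.version$major, R.version$minor),
    sprintf("sites=%d species=%d", nrow(m), ncol(m)),
    sprintf("seed=%d n_sim=%d n_perm=%d ci_level=%g alpha=%g",
            config$seed, config$n_sim, config$n_perm, config$ci_level,
            config$alpha)), out("run_log.txt"))

  invisible(list(matrix = m, pairs = pairs, summary = summary_df,
                 diversity = summary_extra, lcbd = lcbd_res,
                 raup_crick = rc, minimum_set = ms, ternary = tern,
                 dendrogram = h, groups = groups_out,
                 outdir = config$outdir))
}

resolve_groups_any <- function(m, groups) {
  g <- resolve_groups(m, groups)
  stats::setNames(g, site_ids(m))
}
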