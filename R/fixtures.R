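#' Bundled vent-system reference tables
#'
#' Small plain-text tables transcribed from published North Pacific
#' hydrothermal vent inventories, used in examples and tests:
#'
#' * `backarc_site_meta()` — environmental variables for the eight
#'   Mariana back-arc vent sites (coordinates in decimal degrees, depth in
#'   m, distance from the volcanic arc and to the next site south in km,
#'   maximum recorded fluid temperature in degrees C, estimated venting
#'   area in m^2).
#' * `backarc_checklist()` — the 28 macrofaunal species collected at the
#'   four northernmost back-arc sites, with taxonomic context.
#' * `vent_site_richness()` — per-site species richness (alpha) for the
#'   Mariana back-arc, Mariana volcanic arc and Juan de Fuca ridge
#'   systems, plus each system's regional richness (gamma) and
#'   along-structure extent in km.
#'
#' @return data.frame (for `vent_site_richness()`, a list with `sites`
#'   and `systems` data.frames).
#' @export
backarc_site_meta <- function() {
  read_site_meta(ventbeta_extdata("backarc_site_meta.csv"))
}

#' @rdname backarc_site_meta
#' @export
backarc_checklist <- function() {
  utils::read.csv(ventbeta_extdata("backarc_checklist.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname backarc_site_meta
#' @export
vent_site_richness <- function() {
  list(sites = utils::read.csv(ventbeta_extdata("vent_site_richness.csv"),
                               stringsAsFactors = FALSE),
       systems = utils::read.csv(ventbeta_extdata("vent_system_gamma.csv"),
                                 stringsAsFactors = FALSE))
}

ventbeta_extdata <- function(name) {
  path <- system.file("extdata", name, package = "ventbeta")
  if (path == "") stop("bundled table not found: ", name, call. = FALSE)
  path
}
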