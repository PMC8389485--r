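#' Construct a validated incidence matrix
#'
#' An incidence matrix is the universal input of the package: a sites-by-
#' species grid of presences (1) and absences (0). Rows are sites, columns
#' species; both carry unique labels. Internally the object is an integer
#' matrix of 0/1 with class `"incidence"`, so it interoperates directly with
#' base matrix arithmetic.
#'
#' @param x matrix (or object coercible to one) of 0/1 values, sites in rows.
#' @param site_ids optional character vector of site labels; defaults to
#'   `rownames(x)`.
#' @param species_ids optional character vector of species labels; defaults
#'   to `colnames(x)`.
#' @return an object of class `"incidence"`.
#' @examples
#' m <- incidence_matrix(rbind(A = c(1, 1, 0), B = c(1, 0, 1)),
#'                       species_ids = c("sp1", "sp2", "sp3"))
#' site_richness(m)
#' @export
incidence_matrix <- function(x, site_ids = NULL, species_ids = NULL) {
  x <- as.matrix(x)
  if (is.logical(x)) storage.mode(x) <- "integer"
  if (!is.numeric(x)) {
    stop("incidence values must be numeric 0/1", call. = FALSE)
  }
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop("incidence matrix cells must all be 0 or 1", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("incidence matrix needs at least one site and one species",
         call. = FALSE)
  }
  if (is.null(site_ids)) site_ids <- rownames(x)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(nrow(x)))
  if (is.null(species_ids)) species_ids <- colnames(x)
  if (is.null(species_ids)) species_ids <- paste0("sp", seq_len(ncol(x)))
  site_ids <- as.character(site_ids)
  species_ids <- as.character(species_ids)
  if (length(site_ids) != nrow(x) || length(species_ids) != ncol(x)) {
    stop("label length does not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(site_ids)) stop("duplicate site labels", call. = FALSE)
  if (anyDuplicated(species_ids)) {
    stop("duplicate species labels", call. = FALSE)
  }
  dimnames(x) <- list(site_ids, species_ids)
  class(x) <- c("incidence", class(x))
  x
}

#' @export
print.incidence <- function(x, ...) {
  cat(sprintf("Incidence matrix: %d sites x %d species (%d occurrences)\n",
              nrow(x), ncol(x), sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Site and species accessors
#'
#' @param m an [incidence_matrix()].
#' @return character vector of labels, or integer vector of per-site
#'   richness for `site_richness()`.
#' @export
site_ids <- function(m) rownames(m)

#' @rdname site_ids
#' @export
species_ids <- function(m) colnames(m)

#' @rdname site_ids
#' @export
site_richness <- function(m) rowSums(unclass(m))

as_incidence <- function(m) {
  if (inherits(m, "incidence")) m else incidence_matrix(m)
}

#' Read an incidence matrix from CSV
#'
#' Two layouts are supported. `wide`: first column holds the site label
#' (header `site`), remaining columns are species with 0/1 cells. `long`:
#' two columns `site,species`, one presence record per row; duplicates are
#' collapsed (presence is idempotent). Species order is the column order
#' (wide) or first appearance (long); site order likewise.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @return an [incidence_matrix()].
#' @export
read_incidence <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop("empty incidence file: ", path, call. = FALSE)
  }
  if (layout == "wide") {
    sites <- as.character(df[[1L]])
    cells <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(cells) || anyNA(cells) || !all(cells %in% c(0, 1))) {
      stop("wide layout requires 0/1 cells throughout", call. = FALSE)
    }
    incidence_matrix(cells, site_ids = sites,
                     species_ids = colnames(df)[-1L])
  } else {
    if (ncol(df) < 2L) {
      stop("long layout requires columns site,species", call. = FALSE)
    }
    sites <- as.character(df[[1L]])
    spp <- as.character(df[[2L]])
    usites <- unique(sites)
    uspp <- unique(spp)
    occ <- matrix(0L, length(usites), length(uspp),
                  dimnames = list(usites, uspp))
    occ[cbind(match(sites, usites), match(spp, uspp))] <- 1L
    incidence_matrix(occ)
  }
}

#' Write an incidence matrix to CSV
#'
#' Inverse of [read_incidence()]: `read_incidence(write_incidence(m))`
#' reproduces `m` exactly, including all-zero species columns (wide layout;
#' the long layout cannot represent a species with no records).
#'
#' @param m an [incidence_matrix()].
#' @param path output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(m, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  m <- as_incidence(m)
  if (layout == "wide") {
    df <- data.frame(site = site_ids(m), check.names = FALSE)
    df <- cbind(df, as.data.frame(unclass(m), check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  } else {
    idx <- which(unclass(m) == 1L, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    df <- data.frame(site = site_ids(m)[idx[, 1L]],
                     species = species_ids(m)[idx[, 2L]])
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Read site metadata
#'
#' Reads a site-metadata table with at least `site`, `latitude` and
#' `longitude` columns (decimal degrees); further environmental columns
#' (depth, distances, temperature, venting area) are carried through.
#'
#' @param path CSV path.
#' @return data.frame of site metadata.
#' @export
read_site_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("site metadata lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(abs(df$latitude) > 90, na.rm = TRUE) ||
      any(abs(df$longitude) > 180, na.rm = TRUE)) {
    stop("coordinates out of range", call. = FALSE)
  }
  df
}

#' Merge vent fields closer than a distance threshold into single sites
#'
#' Vent fields sharing a heat source are conventionally pooled into one
#' site when they lie within a few kilometres of each other. This applies
#' the rule by transitive closure: any chain of fields with consecutive
#' great-circle distances below `threshold_km` collapses into one site
#' whose occupancy is the union and whose label concatenates the member
#' labels in input order.
#'
#' Distances are haversine great-circle distances on a sphere of radius
#' 6371 km. Because the merging rule is really about shared heat sources
#' (nearby fields on distinct sources stay distinct sites), the `fields`
#' argument restricts which sites are candidates; by default all sites are
#' considered.
#'
#' @param m an [incidence_matrix()].
#' @param meta data.frame as from [read_site_meta()] covering every site.
#' @param threshold_km merge distance in kilometres (strict `<`).
#' @param fields optional character vector of site labels eligible for
#'   merging; sites outside it are never merged.
#' @param sep separator for concatenated labels.
#' @return an [incidence_matrix()] with merged sites (input order of first
#'   members preserved).
#' @export
merge_nearby_fields <- function(m, meta, threshold_km = 3,
                                fields = NULL, sep = "/") {
  m <- as_incidence(m)
  ids <- site_ids(m)
  pos <- match(ids, meta$site)
  if (anyNA(pos)) {
    stop("missing metadata for site(s): ",
         paste(ids[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  lat <- meta$latitude[pos]
  lon <- meta$longitude[pos]
  if (anyNA(lat) || anyNA(lon)) {
    stop("missing coordinates for some sites", call. = FALSE)
  }
  eligible <- if (is.null(fields)) rep(TRUE, length(ids)) else ids %in% fields
  n <- length(ids)
  # union-find over the < threshold relation (transitive closure)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (!(eligible[i] && eligible[j])) next
        d_km <- geosphere::distHaversine(c(lon[i], lat[i]),
                                         c(lon[j], lat[j]),
                                         r = 6371000) / 1000
        if (d_km < threshold_km) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  occ <- t(vapply(groups, function(g) {
    as.integer(colSums(unclass(m)[g, , drop = FALSE]) > 0)
  }, integer(ncol(m))))
  labels <- vapply(groups, function(g) paste(ids[g], collapse = sep),
                   character(1))
  ord <- order(vapply(groups, min, integer(1)))
  incidence_matrix(occ[ord, , drop = FALSE], site_ids = labels[ord],
                   species_ids = species_ids(m))
}

#' Occupancy summary of an incidence matrix
#'
#' Per-site richness (alpha), regional richness (gamma, species present at
#' one or more sites; all-zero columns are kept in the matrix but excluded
#' here), per-species occupancy frequency, and the counts/proportions of
#' ubiquitous (all sites) and single-site species.
#'
#' @param m an [incidence_matrix()].
#' @return list with `alpha`, `gamma`, `occupancy`, `n_ubiquitous`,
#'   `p_ubiquitous`, `n_single_site`, `p_single_site`.
#' @export
occupancy_summary <- function(m) {
  m <- as_incidence(m)
  occ <- colSums(unclass(m))
  present <- occ > 0
  gamma <- sum(present)
  n_ubi <- sum(occ == nrow(m))
  n_one <- sum(occ == 1L)
  list(alpha = rowSums(unclass(m)),
       gamma = gamma,
       occupancy = occ,
       n_ubiquitous = n_ubi,
       p_ubiquitous = if (gamma > 0) n_ubi / gamma else NA_real_,
       n_single_site = n_one,
       p_single_site = if (gamma > 0) n_one / gamma else NA_real_)
}
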