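# Shared fixture builders for the suite. Everything is generated in code;
# no binary data.

# small deterministic incidence matrix
toy_matrix <- function() {
  incidence_matrix(rbind(A = c(1, 1, 0, 0),
                         B = c(1, 0, 1, 0),
                         C = c(1, 1, 1, 1)),
                   species_ids = paste0("sp", 1:4))
}

# random 0/1 matrix with no empty sites or (optionally) empty species
random_incidence <- function(n_sites, n_species, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    occ <- matrix(rbinom(n_sites * n_species, 1, p), n_sites, n_species)
    if (all(rowSums(occ) > 0)) break
  }
  incidence_matrix(occ,
                   site_ids = paste0("s", seq_len(n_sites)),
                   species_ids = paste0("sp", seq_len(n_species)))
}

# independent haversine oracle (spherical earth, R = 6371 km)
haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(sqrt(h))
}

# enumerate all species subsets of a pool as a list of character vectors
all_subsets <- function(pool) {
  n <- length(pool)
  lapply(seq_len(2^n) - 1L, function(mask) {
    pool[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
  })
}
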