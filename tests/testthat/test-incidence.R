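test_that("constructor validates labels and cell values", {
  expect_error(incidence_matrix(matrix(c(0, 2), 1)), "0 or 1")
  expect_error(incidence_matrix(rbind(A = 1, A = 1)), "duplicate site")
  expect_error(
    incidence_matrix(matrix(1, 2, 2,
                            dimnames = list(c("A", "B"), c("x", "x")))),
    "duplicate species")
  m <- incidence_matrix(matrix(c(TRUE, FALSE), 1, 2))
  expect_identical(as.vector(unclass(m)), c(1L, 0L))
})

test_that("long records build presence idempotently", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,species", "A,x", "A,y", "B,x"), f)
  m <- read_incidence(f, layout = "long")
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(unname(unclass(m)), rbind(c(1L, 1L), c(1L, 0L)))

  writeLines(c("site,species", "A,x", "A,x", "A,y", "B,x"), f)
  m2 <- read_incidence(f, layout = "long")
  expect_identical(unclass(m2), unclass(m))
})

test_that("wide layout rejects non-binary cells and empty files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,sp1", "A,2"), f)
  expect_error(read_incidence(f, layout = "wide"), "0/1")
  writeLines(character(0), f)
  expect_error(read_incidence(f, layout = "wide"))
})

test_that("write/read round-trips preserve the matrix in both layouts", {
  m <- toy_matrix()
  fw <- withr::local_tempfile(fileext = ".csv")
  write_incidence(m, fw, "wide")
  expect_identical(unclass(read_incidence(fw, "wide")), unclass(m))

  fl <- withr::local_tempfile(fileext = ".csv")
  write_incidence(m, fl, "long")
  expect_identical(unclass(read_incidence(fl, "long")), unclass(m))

  # wide -> long -> wide, no species absent everywhere
  m3 <- read_incidence(fl, "long")
  write_incidence(m3, fw, "wide")
  expect_identical(unclass(read_incidence(fw, "wide")), unclass(m))
})

test_that("all-zero species columns survive the wide round trip", {
  m <- incidence_matrix(rbind(A = c(1, 0), B = c(1, 0)),
                        species_ids = c("kept", "empty"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_incidence(m, f, "wide")
  back <- read_incidence(f, "wide")
  expect_identical(species_ids(back), c("kept", "empty"))
  expect_identical(sum(unclass(back)[, "empty"]), 0L)
})

test_that("fields merge below the distance threshold, with union occupancy", {
  # two fields ~2.9 km apart along a parallel, third far away
  lon2 <- 0.02646
  meta <- data.frame(site = c("F1", "F2", "Far"),
                     latitude = c(10, 10, 12),
                     longitude = c(0, lon2, 0))
  d12 <- haversine_km(10, 0, 10, lon2)
  expect_lt(d12, 3)
  m <- incidence_matrix(rbind(F1 = c(1, 0, 0), F2 = c(0, 1, 0),
                              Far = c(0, 0, 1)),
                        species_ids = c("x", "y", "z"))
  merged <- merge_nearby_fields(m, meta)
  expect_identical(site_ids(merged), c("F1/F2", "Far"))
  expect_identical(unname(unclass(merged)[1, ]), c(1L, 1L, 0L))

  # idempotent: re-merging changes nothing (needs metadata for merged label)
  meta2 <- rbind(meta, data.frame(site = "F1/F2", latitude = 10,
                                  longitude = lon2 / 2))
  expect_identical(unclass(merge_nearby_fields(merged, meta2)),
                   unclass(merged))
})

test_that("fields above the threshold stay distinct", {
  lon2 <- 0.02921   # ~3.2 km at lat 10
  expect_gt(haversine_km(10, 0, 10, lon2), 3)
  meta <- data.frame(site = c("F1", "F2"), latitude = c(10, 10),
                     longitude = c(0, lon2))
  m <- incidence_matrix(rbind(F1 = c(1, 0), F2 = c(0, 1)))
  expect_identical(unclass(merge_nearby_fields(m, meta)), unclass(m))
})

test_that("merging is transitive and handles identical coordinates", {
  # chain: A-B 2 km, B-C 2 km, A-C 4 km -> all three merge
  step <- 0.018  # ~2 km of longitude at the equator
  meta <- data.frame(site = c("A", "B", "C"), latitude = 0,
                     longitude = c(0, step, 2 * step))
  expect_lt(haversine_km(0, 0, 0, step), 3)
  expect_gt(haversine_km(0, 0, 0, 2 * step), 3)
  m <- incidence_matrix(rbind(A = c(1, 0, 0), B = c(0, 1, 0),
                              C = c(0, 0, 1)))
  merged <- merge_nearby_fields(m, meta)
  expect_identical(nrow(merged), 1L)
  expect_identical(site_ids(merged), "A/B/C")

  meta0 <- data.frame(site = c("A", "B"), latitude = 5, longitude = 7)
  m0 <- incidence_matrix(rbind(A = c(1, 0), B = c(0, 1)))
  expect_identical(nrow(merge_nearby_fields(m0, meta0)), 1L)
})

test_that("the fields argument restricts merge candidates", {
  meta <- data.frame(site = c("A", "B"), latitude = 0, longitude = 0)
  m <- incidence_matrix(rbind(A = c(1, 0), B = c(0, 1)))
  expect_identical(nrow(merge_nearby_fields(m, meta, fields = "A")), 2L)
})

test_that("occupancy summary matches brute-force column scans", {
  m <- incidence_matrix(diag(3))
  s <- occupancy_summary(m)
  expect_identical(unname(s$alpha), c(1, 1, 1))
  expect_identical(s$gamma, 3L)
  expect_identical(s$n_single_site, 3L)
  expect_identical(s$n_ubiquitous, 0L)

  r <- random_incidence(7, 30, seed = 5)
  s2 <- occupancy_summary(r)
  occ <- unclass(r)
  expect_identical(s2$gamma,
                   sum(vapply(seq_len(ncol(occ)),
                              function(j) any(occ[, j] > 0), logical(1))))
  expect_equal(unname(s2$alpha), unname(rowSums(occ)))
  expect_lte(s2$gamma, ncol(occ))
  expect_equal(sum(s2$alpha), sum(occ))
})
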