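test_that("hand-worked pair decomposition is exact", {
  p <- decompose_pair(c("a1", "a2", "a3", "b1", "b2"),
                      c("a1", "a2", "a3", "c1"))
  # a = 3, b = 2, c = 1, n = 6
  expect_equal(p$o_j, 0.5)
  expect_equal(p$r_j, 1 / 3)
  expect_equal(p$d_j, 1 / 6)
  expect_equal(p$beta_j, 0.5)
  expect_equal(p$n_j, 2 / 3)
  expect_equal(p$i_j, 1 / 6)
  expect_equal(p$rc_j, 1 / 3)
  expect_equal(p$beta_ratio, 1 / 3)
})

test_that("identical and disjoint site pairs hit the boundary cases", {
  s <- paste0("s", 1:5)
  ident <- decompose_pair(s, s)
  expect_equal(ident$beta_j, 0)
  expect_equal(ident$o_j, 1)
  expect_equal(ident$n_j, 1)
  expect_true(is.na(ident$beta_ratio))

  disj <- decompose_pair(paste0("x", 1:3), paste0("y", 1:3))
  expect_equal(disj$beta_j, 1)
  expect_equal(disj$i_j, 0)
  expect_equal(disj$rc_j, 1)
  expect_equal(disj$r_j, 1)
  expect_equal(disj$n_j, 0)

  expect_error(decompose_pair(character(0), character(0)), "empty")
})

test_that("components satisfy the additive identities over an exhaustive
           enumeration of subset pairs", {
  pool <- paste0("sp", 1:6)
  subsets <- all_subsets(pool)
  grid <- expand.grid(i = seq_along(subsets), j = seq_along(subsets))
  grid <- grid[!(lengths(subsets)[grid$i] == 0 &
                   lengths(subsets)[grid$j] == 0), ]
  res <- do.call(rbind, Map(function(i, j) {
    cbind(decompose_pair(subsets[[i]], subsets[[j]]),
          decompose_pair(subsets[[j]], subsets[[i]])[, 6:13])
  }, grid$i, grid$j))
  # oracle counts from explicit set operations + defining formulas
  a <- mapply(function(i, j) length(intersect(subsets[[i]],
                                              subsets[[j]])),
              grid$i, grid$j)
  b <- mapply(function(i, j) length(setdiff(subsets[[i]],
                                            subsets[[j]])),
              grid$i, grid$j)
  cc <- mapply(function(i, j) length(setdiff(subsets[[j]],
                                             subsets[[i]])),
               grid$i, grid$j)
  n <- a + b + cc
  expect_equal(res$a, a)
  expect_equal(res$o_j, a / n)
  expect_equal(res$r_j, 2 * pmin(b, cc) / n)
  expect_equal(res$d_j, abs(b - cc) / n)
  # additive identities
  expect_equal(res$o_j + res$r_j + res$d_j, rep(1, nrow(res)))
  expect_equal(res$beta_j, res$r_j + res$d_j)
  expect_equal(res$i_j + res$rc_j, res$beta_j)
  expect_equal(res$n_j, ifelse(a > 0, res$o_j + res$d_j, 0))
  vals <- as.matrix(res[, c("o_j", "r_j", "d_j", "beta_j", "n_j",
                            "i_j", "rc_j")])
  expect_true(all(vals >= 0 & vals <= 1))
  # symmetry: components identical under argument swap (b and c trade
  # places by definition, so only columns 6:13 are compared)
  expect_equal(unname(as.matrix(res[, 6:13])),
               unname(as.matrix(res[, 14:21])))
})

test_that("adding a shared species strictly decreases beta_J", {
  x <- paste0("x", 1:3)
  y <- paste0("y", 1:2)
  base <- decompose_pair(x, y)
  shared <- decompose_pair(c(x, "s"), c(y, "s"))
  expect_lt(shared$beta_j, base$beta_j)
})

test_that("decompose_all enumerates all unordered pairs in index order", {
  m8 <- random_incidence(8, 30, seed = 2)
  pairs8 <- decompose_all(m8)
  expect_identical(nrow(pairs8), 28L)
  m7 <- random_incidence(7, 30, seed = 3)
  expect_identical(nrow(decompose_all(m7)), 21L)
  expect_identical(pairs8$site_i[1:7], rep("s1", 7))
  # row-swapped matrix gives the same values pair-for-pair
  swapped <- incidence_matrix(unclass(m8)[c(2, 1, 3:8), ])
  ps <- decompose_all(swapped)
  key <- function(df) {
    k <- apply(cbind(pmin(df$site_i, df$site_j),
                     pmax(df$site_i, df$site_j)), 1, paste,
               collapse = "|")
    df <- df[order(k), ]
    rownames(df) <- NULL
    df
  }
  # b and c trade places when the canonical pair order flips, so compare
  # the order-invariant columns
  sym_cols <- c("a", "o_j", "r_j", "d_j", "beta_j", "n_j", "i_j",
                "rc_j", "beta_ratio")
  expect_equal(key(ps)[, sym_cols], key(pairs8)[, sym_cols])
  expect_error(decompose_all(incidence_matrix(matrix(1, 1, 3))),
               "two sites")
})

test_that("decomposition summaries report mean and median per component", {
  pairs <- rbind(decompose_pair(c("a", "b"), c("a", "c"), "A", "B"),
                 decompose_pair(c("a", "b", "c"), c("a", "b", "d"),
                                "A", "C"),
                 decompose_pair(c("a", "b", "c", "d", "e"),
                                c("a", "b", "c", "d", "f"), "B", "C"))
  s <- summarize_decomposition(pairs)
  beta_row <- s[s$component == "beta_j", ]
  expect_equal(beta_row$mean, mean(pairs$beta_j))
  expect_equal(beta_row$median, median(pairs$beta_j))

  # identical sites: zero beta everywhere, ratio undefined and excluded
  same <- incidence_matrix(rbind(A = c(1, 1), B = c(1, 1)))
  ss <- summarize_decomposition(decompose_all(same))
  expect_equal(ss[ss$component == "beta_j", "mean"], 0)
  expect_identical(ss[ss$component == "beta_ratio", "n"], 0L)
})

test_that("Whittaker ratio equals gamma over mean alpha", {
  one <- incidence_matrix(matrix(c(1, 1, 0), 1))
  expect_equal(whittaker_ratio(one), 1)
  m <- random_incidence(6, 20, seed = 9)
  expect_equal(whittaker_ratio(m),
               whittaker_ratio(alpha = rowSums(unclass(m)),
                               gamma = sum(colSums(unclass(m)) > 0)))
  expect_error(whittaker_ratio(alpha = c(0, 0), gamma = 0), "undefined")
})

test_that("ternary coordinates place the canonical pairs at the vertices", {
  vert <- rbind(decompose_pair(c("a"), c("a"), "O", "O2"),
                decompose_pair(c("x", "y"), c("u", "v"), "R", "R2"))
  tc <- ternary_coordinates(vert)
  expect_equal(unlist(tc[1, c("x", "y")]), c(x = 1, y = 0))        # O vertex
  expect_equal(tc$x[2], 0.5)
  expect_equal(tc$y[2], sqrt(3) / 2)                               # R apex
  # strictly nested pair sits on the O-D edge (y = 0)
  nest <- ternary_coordinates(decompose_pair(c("a", "b"),
                                             c("a", "b", "c", "d")))
  expect_equal(nest$y, 0)
  expect_equal(nest$o_j + nest$r_j + nest$d_j, 1)
})
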