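#' UPGMA clustering of sites from a dissimilarity matrix
#'
#' Unweighted pair-group average-linkage hierarchical clustering, the
#' conventional way to draw site dendrograms from pairwise beta-diversity
#' values. Merge heights equal the average inter-cluster dissimilarity at
#' merge time, so the output is ultrametric; ties on the minimum
#' dissimilarity are broken deterministically (lowest cluster index
#' first, the behaviour of [stats::hclust()], which performs the
#' agglomeration).
#'
#' @param D symmetric dissimilarity matrix (zero diagonal) or a
#'   [stats::dist] object; typically the `beta_j` values of
#'   [decompose_all()] reshaped via [dissimilarity_matrix()].
#' @param labels optional leaf labels (defaults to the dimnames of `D`).
#' @return an object of class `"hclust"`.
#' @examples
#' D <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' h <- upgma(D)
#' h$height  # 0.2 then (0.6 + 0.8) / 2 = 0.7
#' @export
upgma <- function(D, labels = NULL) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12)) {
      stop("dissimilarity matrix must be symmetric", call. = FALSE)
    }
    if (any(diag(D) != 0) || any(D < 0)) {
      stop("dissimilarities must be non-negative with zero diagonal",
           call. = FALSE)
    }
    if (!is.null(labels)) dimnames(D) <- list(labels, labels)
    D <- stats::as.dist(D)
  }
  if (attr(D, "Size") < 2L) stop("need at least two sites", call. = FALSE)
  stats::hclust(D, method = "average")
}

#' Reshape pairwise decomposition output into a dissimilarity matrix
#'
#' @param pairs data.frame from [decompose_all()] (or any table with
#'   `site_i`, `site_j` and a value column).
#' @param value name of the dissimilarity column (default `"beta_j"`).
#' @return symmetric matrix with zero diagonal, sites in first-appearance
#'   order.
#' @export
dissimilarity_matrix <- function(pairs, value = "beta_j") {
  ids <- unique(c(rbind(pairs$site_i, pairs$site_j)))
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(pairs$site_i, ids)
  j <- match(pairs$site_j, ids)
  D[cbind(i, j)] <- pairs[[value]]
  D[cbind(j, i)] <- pairs[[value]]
  D
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from the ultrametric merge heights (each leaf
#' sits at depth height/2 below its parent node, as is standard for UPGMA
#' trees).
#'
#' @param h an `"hclust"` object from [upgma()].
#' @param file optional path; when given the string is also written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
dendrogram_newick <- function(h, file = NULL) {
  phy <- ape::as.phylo(h)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
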