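# Population-structure summaries: PCA of the genotype matrix and a
# neighbor-joining tree from the mean pairwise FST matrix.

#' PCA of a genotype matrix
#'
#' Missing genotypes are imputed to the per-SNP mean, SNPs with no calls
#' are dropped with a warning, and the centered (unscaled by default)
#' matrix is decomposed; coordinates are deterministic up to component
#' sign.
#'
#' @param ds A [genotype_dataset()].
#' @param k Number of components to return.
#' @param scale. Also scale each SNP to unit variance (default `FALSE`).
#' @return List with `coords` (samples x k), `explained` (variance
#'   fractions, non-increasing), `breed`.
#' @export
pca_genotypes <- function(ds, k = 2L, scale. = FALSE) {
  if (nrow(ds$G) < k + 1) stop("need at least k+1 samples")
  G <- ds$G
  all_na <- colSums(!is.na(G)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " SNP(s) with no calls dropped before PCA")
    G <- G[, !all_na, drop = FALSE]
  }
  mu <- colMeans(G, na.rm = TRUE)
  na <- which(is.na(G), arr.ind = TRUE)
  if (nrow(na)) G[na] <- mu[na[, 2]]
  if (scale.) {
    sdv <- apply(G, 2, stats::sd)
    G <- G[, sdv > 0, drop = FALSE]
  }
  pc <- stats::prcomp(G, center = TRUE, scale. = scale.)
  k <- min(k, ncol(pc$x))
  list(coords = pc$x[, seq_len(k), drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       breed = ds$breed)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimizing the
#' Q-criterion, assign branch lengths, and reduce the matrix. Negative
#' branch lengths are clamped to zero with the deficit transferred to the
#' sister branch. Ties on Q are broken towards the lowest taxon-index
#' pair for determinism.
#'
#' @param D Symmetric numeric matrix with zero diagonal; row/col names
#'   are the taxa labels.
#' @return Newick string (unrooted, with branch lengths). Parse with
#'   [ape::read.tree()] for plotting or comparison.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10)))
    stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- as.list(labels)  # newick fragment per active node

  while (n > 3) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)
    k <- k[k[, 1] < k[, 2], , drop = FALSE]
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
    i <- k[1]; j <- k[2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    br <- .clamp_branches(vi, vj)
    new_d <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    newick <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]], br[1],
                      nodes[[j]], br[2])
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], 0))
    nodes <- c(nodes[keep], newick)
    n <- n - 1
  }
  # terminal 3-taxon star: closed-form branch lengths
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nodes[[1]], v[1],
          nodes[[2]], v[2], nodes[[3]], v[3])
}

# clamp a negative branch to 0, moving the deficit to the sister branch
.clamp_branches <- function(vi, vj) {
  if (vi < 0) { vj <- vj + vi; vi <- 0 }
  if (vj < 0) { vi <- vi + vj; vj <- 0 }
  c(vi, max(vj, 0))
}
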