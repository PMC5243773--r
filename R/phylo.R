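# Distance-based phylogeny: p-distance matrix, neighbour-joining tree,
# column-resampling bootstrap, Newick output.

#' Pairwise p-distance matrix
#'
#' @param genomes Named character vector of equal-length sequences. Columns
#'   where either member of a pair has `N` are excluded for that pair.
#' @return Object of class `sarg_dist`: `taxa`, `counts` (differing columns),
#'   `compared` (columns compared), `p` (proportions), `length_compared`
#'   (alignment length).
#' @export
p_distance_matrix <- function(genomes) {
  stopifnot(length(genomes) >= 2L, !is.null(names(genomes)))
  .check_collinear(nchar(genomes))
  taxa <- names(genomes)
  n <- length(taxa)
  mat <- vapply(genomes, .chars, character(nchar(genomes[[1L]])))
  counts <- compared <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[, i] != "N" & mat[, j] != "N"
      d <- sum(ok & mat[, i] != mat[, j])
      counts[i, j] <- counts[j, i] <- d
      compared[i, j] <- compared[j, i] <- sum(ok)
    }
  }
  p <- counts / pmax(compared, 1L)
  diag(p) <- 0
  structure(list(taxa = taxa, counts = counts, compared = compared, p = p,
                 length_compared = nchar(genomes[[1L]])),
            class = "sarg_dist")
}

.as_dist_matrix <- function(x) {
  if (inherits(x, "sarg_dist")) return(x$p)
  if (inherits(x, "dist")) return(as.matrix(x))
  as.matrix(x)
}

#' Neighbour-joining tree
#'
#' Standard neighbour joining on a symmetric non-negative distance matrix.
#' For three taxa the branch lengths are the three-point formulas
#' `v_a = (d_ab + d_ac - d_bc) / 2`.
#'
#' @param x A `sarg_dist`, `dist` or symmetric matrix.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(x) {
  m <- .as_dist_matrix(x)
  if (nrow(m) < 3L) {
    .stop_sarg("at least 3 taxa are required", "sargtype_validation_error")
  }
  if (any(m < 0)) {
    .stop_sarg("distance matrix has negative entries", "sargtype_validation_error")
  }
  if (any(abs(m - t(m)) > 1e-12)) {
    .stop_sarg("distance matrix is not symmetric", "sargtype_validation_error")
  }
  if (nrow(m) == 3L) {
    v <- c((m[1, 2] + m[1, 3] - m[2, 3]) / 2,
           (m[1, 2] + m[2, 3] - m[1, 3]) / 2,
           (m[1, 3] + m[2, 3] - m[1, 2]) / 2)
    v <- pmax(v, 0)
    txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                   rownames(m)[1], v[1], rownames(m)[2], v[2],
                   rownames(m)[3], v[3])
    return(ape::read.tree(text = txt))
  }
  ape::nj(stats::as.dist(m))
}

#' Bootstrap support by alignment-column resampling
#'
#' Columns of the (collinear) alignment are resampled with replacement
#' `replicates` times, the NJ tree is recomputed from each replicate's
#' p-distances, and the fraction of replicates supporting each internal edge
#' of the full-data tree is reported. With exactly three taxa the unrooted
#' tree has no internal edge, so the reported support is the fraction of
#' replicates in which the full-data closest pair is strictly the closest —
#' the pair NJ agglomerates against the third taxon.
#'
#' @param genomes Named character vector of equal-length sequences (>= 3).
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return List with `tree` (full-data NJ tree, supports as node labels) and
#'   `supports` (named numeric vector in `[0, 1]`).
#' @export
bootstrap_support <- function(genomes, replicates = 1000L, seed = 1L) {
  if (replicates < 1L) {
    .stop_sarg("replicates must be >= 1", "sargtype_validation_error")
  }
  stopifnot(length(genomes) >= 3L, !is.null(names(genomes)))
  .check_collinear(nchar(genomes))
  L <- nchar(genomes[[1L]])
  taxa <- names(genomes)
  n <- length(taxa)
  full <- p_distance_matrix(genomes)
  tree <- nj_tree(full)
  mat <- vapply(genomes, .chars, character(L))
  pairs <- utils::combn(n, 2L)
  diffv <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- mat[, pairs[1L, k]]; b <- mat[, pairs[2L, k]]
    a != b & a != "N" & b != "N"
  })
  set.seed(seed)
  if (n == 3L) {
    d <- full$counts[lower.tri(full$counts)]
    # pair order from combn: (1,2), (1,3), (2,3)
    cnt <- c(full$counts[1, 2], full$counts[1, 3], full$counts[2, 3])
    best <- which(cnt == min(cnt))
    if (length(best) > 1L) {
      support <- 0
      best <- best[1L]
    } else {
      hits <- 0L
      for (r in seq_len(replicates)) {
        idx <- sample.int(L, L, replace = TRUE)
        rc <- vapply(diffv, function(v) sum(v[idx]), numeric(1))
        if (rc[best] < min(rc[-best])) hits <- hits + 1L
      }
      support <- hits / replicates
    }
    pairnames <- apply(pairs, 2L, function(k) paste(sort(taxa[k]), collapse = ","))
    supports <- stats::setNames(support, pairnames[best])
    tree$node.label <- as.character(support)
  } else {
    reps <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      idx <- sample.int(L, L, replace = TRUE)
      cm <- matrix(0, n, n, dimnames = list(taxa, taxa))
      nc <- matrix(0, n, n, dimnames = list(taxa, taxa))
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1L, k]; j <- pairs[2L, k]
        okv <- mat[idx, i] != "N" & mat[idx, j] != "N"
        cm[i, j] <- cm[j, i] <- sum(diffv[[k]][idx])
        nc[i, j] <- nc[j, i] <- sum(okv)
      }
      reps[[r]] <- nj_tree(cm / pmax(nc, 1))
    }
    counts <- ape::prop.clades(tree, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    supports <- counts / replicates
    names(supports) <- paste0("node", seq_along(supports) + length(taxa))
    tree$node.label <- as.character(supports)
  }
  list(tree = tree, supports = supports)
}

#' Write a tree in Newick format
#'
#' @param tree An `ape::phylo` tree (support values, if any, as node labels).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
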