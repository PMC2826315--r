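#' Pearson correlation distance between genes
#'
#' d(i, j) = 1 - r(i, j) with r the Pearson correlation (sample, n-1
#' denominator) over pairwise-complete unmasked samples.
#'
#' @param x an [xset()] on the log2 scale
#' @param min_common minimum pairwise-complete samples per gene pair
#'   (default 3); fewer is an error
#' @return symmetric numeric matrix with zero diagonal, gene ids as dimnames
#' @export
correlation_distance <- function(x, min_common = 3) {
  stopifnot(inherits(x, "xset"))
  v <- masked_values(x)
  sds <- apply(v, 1, sd, na.rm = TRUE)
  bad <- which(is.na(sds) | sds < 1e-12)
  if (length(bad) > 0) {
    stop(
      "zero-variance gene(s): ",
      paste(head(gene_ids(x)[bad], 5), collapse = ", ")
    )
  }
  obs <- (!is.na(v)) * 1
  common <- tcrossprod(obs)
  if (any(common < min_common)) {
    idx <- which(common < min_common, arr.ind = TRUE)[1, ]
    stop(
      "gene pair with fewer than ", min_common, " common samples: ",
      gene_ids(x)[idx[1]], " / ", gene_ids(x)[idx[2]]
    )
  }
  r <- cor(t(v), use = "pairwise.complete.obs")
  d <- 1 - r
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) dendrogram over genes
#'
#' Agglomerative clustering where the distance between two clusters is the
#' arithmetic mean of all cross-pair distances ([stats::hclust()] with
#' `method = "average"`). The returned object adds a deterministic leaf
#' order: at every internal node the child whose leaves contain the smaller
#' original gene index comes first.
#'
#' @param d distance matrix from [correlation_distance()] (or any symmetric
#'   distance matrix with labels)
#' @return a `gene_dendro` object: fields `merge`, `height`, `labels`,
#'   `leaf_order` (character), plus `order` indices
#' @export
average_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n == 0) stop("empty distance matrix")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 1) {
    t <- structure(
      list(
        merge = matrix(integer(0), 0, 2), height = numeric(0),
        labels = labels, order = 1L, leaf_order = labels, n = 1L
      ),
      class = "gene_dendro"
    )
    return(t)
  }
  h <- hclust(as.dist(d), method = "average")
  ord <- deterministic_leaf_order(h$merge, n)
  structure(
    list(
      merge = h$merge, height = h$height, labels = labels,
      order = ord, leaf_order = labels[ord], n = n
    ),
    class = "gene_dendro"
  )
}

# In-order traversal of an hclust merge matrix; at each node the child whose
# subtree holds the smaller minimum original leaf index goes first.
# Iterative over merge rows (children always precede parents).
deterministic_leaf_order <- function(merge, n) {
  k <- nrow(merge)
  ords <- vector("list", k)
  mins <- integer(k)
  child <- function(v) { # returns list(order, min)
    if (v < 0) list(ord = -v, min = -v) else list(ord = ords[[v]], min = mins[v])
  }
  for (i in seq_len(k)) {
    a <- child(merge[i, 1])
    b <- child(merge[i, 2])
    if (a$min <= b$min) {
      ords[[i]] <- c(a$ord, b$ord)
    } else {
      ords[[i]] <- c(b$ord, a$ord)
    }
    mins[i] <- min(a$min, b$min)
  }
  ords[[k]]
}

#' @export
print.gene_dendro <- function(x, ...) {
  cat(sprintf(
    "<gene_dendro> %d leaves, %d merges, height range [%.3g, %.3g]\n",
    x$n, length(x$height),
    if (length(x$height)) min(x$height) else NA,
    if (length(x$height)) max(x$height) else NA
  ))
  invisible(x)
}

#' Leaf order of a dendrogram
#' @param t a `gene_dendro`
#' @return character vector: permutation of the gene ids
#' @export
leaf_order <- function(t) {
  stopifnot(inherits(t, "gene_dendro"))
  t$leaf_order
}

#' Leaf sets of every internal node
#'
#' @param t a `gene_dendro`
#' @return list of integer vectors (leaf indices), one per merge row
#' @export
node_leaves <- function(t) {
  stopifnot(inherits(t, "gene_dendro"))
  k <- nrow(t$merge)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    a <- t$merge[i, 1]
    b <- t$merge[i, 2]
    out[[i]] <- c(
      if (a < 0) -a else out[[a]],
      if (b < 0) -b else out[[b]]
    )
  }
  out
}

#' Cut a dendrogram at a distance threshold
#'
#' Clusters are the maximal subtrees whose merge heights are all strictly
#' below `h` (so for correlation distance, `h = 1 - r_min` keeps together
#' genes linked at r > r_min).
#'
#' @param t a `gene_dendro`
#' @param h distance threshold (>= 0)
#' @return named integer vector of cluster memberships (names = gene ids;
#'   cluster ids are 1..K in order of first appearance)
#' @export
cut_at_distance <- function(t, h) {
  stopifnot(inherits(t, "gene_dendro"), h >= 0)
  n <- t$n
  cl <- seq_len(n)
  if (n > 1) {
    node_cl <- integer(nrow(t$merge))
    nxt <- n
    for (i in seq_len(nrow(t$merge))) {
      if (t$height[i] < h) {
        a <- t$merge[i, 1]
        b <- t$merge[i, 2]
        ca <- if (a < 0) cl[-a] else node_cl[a]
        cb <- if (b < 0) cl[-b] else node_cl[b]
        cl[cl == cb] <- ca
        node_cl[i] <- ca
      } else {
        node_cl[i] <- NA_integer_
      }
    }
  }
  ids <- match(cl, unique(cl))
  setNames(ids, t$labels)
}

#' Newick export of a dendrogram
#'
#' Branch lengths are height differences (leaves sit at height zero), so the
#' tree is ultrametric with tip depth equal to the root merge height.
#'
#' @param t a `gene_dendro`
#' @return single Newick string (terminated by ";")
#' @export
dendro_newick <- function(t) {
  stopifnot(inherits(t, "gene_dendro"))
  if (t$n == 1) return(paste0(t$labels, ";"))
  k <- nrow(t$merge)
  lab <- character(k)
  hgt <- t$height
  part <- function(v, parent_h) {
    if (v < 0) {
      sprintf("%s:%.10g", t$labels[-v], parent_h)
    } else {
      sprintf("%s:%.10g", lab[v], parent_h - hgt[v])
    }
  }
  for (i in seq_len(k)) {
    lab[i] <- sprintf(
      "(%s,%s)", part(t$merge[i, 1], hgt[i]), part(t$merge[i, 2], hgt[i])
    )
  }
  paste0(lab[k], ";")
}

#' Convert a gene_dendro to stats::hclust
#' @param x a `gene_dendro`
#' @param ... unused
#' @return an `hclust` object
#' @export
as.hclust.gene_dendro <- function(x, ...) {
  structure(
    list(
      merge = x$merge, height = x$height, order = x$order,
      labels = x$labels, method = "average",
      dist.method = "1 - Pearson r"
    ),
    class = "hclust"
  )
}
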