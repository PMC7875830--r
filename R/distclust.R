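#' Euclidean distances between sample genotypes
#'
#' `d(i, j) = sqrt(sum_l (x_il - x_jl)^2)` over raw 0/1/2 dosages (no
#' standardization). With missing data, the default is pairwise-complete
#' loci with the sum rescaled by `L / L_complete(i, j)` (the convention of
#' [stats::dist()]); `missing = "complete"` instead drops every locus with
#' any missing call before computing distances.
#'
#' @param matrix a biallelic-filtered [genotype_matrix()].
#' @param missing `"rescale"` (default) or `"complete"`.
#' @return a [stats::dist] object labeled by sample ids.
#' @export
euclidean_distances <- function(matrix, missing = c("rescale", "complete")) {
  missing <- match.arg(missing)
  if (any(is_multiallelic(matrix))) {
    stop("distance requires a biallelic-filtered matrix; run filter_biallelic()")
  }
  dos <- matrix$dosage
  if (missing == "complete") {
    dos <- dos[, colSums(is.na(dos)) == 0L, drop = FALSE]
  }
  d <- stats::dist(dos)
  if (anyNA(d)) {
    m <- as.matrix(d)
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)[1, ]
    stop("samples ", rownames(m)[bad[1]], " and ", colnames(m)[bad[2]],
         " share no jointly non-missing locus")
  }
  d
}

#' Neighbor-joining tree of samples
#'
#' Saitou-Nei neighbor joining (consistent on additive distance matrices) of
#' the genotype distance matrix; the result is the unrooted sample tree.
#' Negative branch-length estimates, which NJ can produce on noisy input,
#' are clamped to zero with the deficit transferred to the adjacent branch
#' so that tip-to-tip distances through the affected node are preserved as
#' far as possible.
#'
#' @param dist a [stats::dist] object or square symmetric matrix with
#'   at least 3 labeled samples; all entries must be finite.
#' @return an unrooted `ape::phylo` tree with non-negative branch lengths.
#' @export
neighbor_joining <- function(dist) {
  if (!inherits(dist, "dist")) dist <- stats::as.dist(as.matrix(dist))
  n <- attr(dist, "Size")
  if (n < 3) stop("neighbor joining requires at least 3 samples")
  if (any(!is.finite(dist))) stop("non-finite distances")
  tree <- ape::nj(dist)
  clamp_negative_edges(tree)
}

# Set negative edges to zero, transferring each deficit to the adjacent
# branch (the longest other edge at the child node, or at the parent node
# for terminal edges).
clamp_negative_edges <- function(tree) {
  el <- tree$edge.length
  for (pass in 1:3) {
    neg <- which(el < 0)
    if (!length(neg)) break
    for (e in neg) {
      w <- el[e]
      el[e] <- 0
      child <- tree$edge[e, 2]
      adj <- setdiff(which(tree$edge[, 1] == child | tree$edge[, 2] == child |
                             tree$edge[, 1] == tree$edge[e, 1]), e)
      if (length(adj)) {
        tgt <- adj[which.max(el[adj])]
        el[tgt] <- el[tgt] + w
      }
    }
  }
  el[el < 0] <- 0
  tree$edge.length <- el
  tree
}

#' Write a tree in Newick format
#'
#' Branch lengths are included; labels containing whitespace or Newick
#' metacharacters are single-quoted.
#'
#' @param tree an `ape::phylo` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  labs <- tree$tip.label
  placeholders <- sprintf("INTROKITTIP%06d", seq_along(labs))
  tree$tip.label <- placeholders
  s <- ape::write.tree(tree)
  for (i in seq_along(labs)) {
    s <- sub(placeholders[i], quote_newick_label(labs[i]), s, fixed = TRUE)
  }
  writeLines(s, path)
  invisible(path)
}

quote_newick_label <- function(x) {
  if (grepl("[][\\s();,:']", x, perl = TRUE)) {
    paste0("'", gsub("'", "''", x), "'")
  } else x
}

#' Read a Newick tree written by [write_newick()]
#' @param path Newick file.
#' @return an `ape::phylo` object (quoted labels unquoted).
#' @export
read_newick <- function(path) {
  s <- paste(readLines(path), collapse = "")
  # protect quoted labels from ape's tokenizer, then restore them
  pat <- "'((?:[^']|'')*)'"
  m <- gregexpr(pat, s, perl = TRUE)
  labs <- regmatches(s, m)[[1]]
  if (length(labs)) {
    placeholders <- sprintf("INTROKITTIP%06d", seq_along(labs))
    for (i in seq_along(labs)) {
      s <- sub(labs[i], placeholders[i], s, fixed = TRUE)
    }
  }
  tree <- ape::read.tree(text = s)
  if (length(labs)) {
    orig <- gsub("''", "'", sub("^'", "", sub("'$", "", labs)))
    for (i in seq_along(labs)) {
      tree$tip.label[tree$tip.label == placeholders[i]] <- orig[i]
    }
  }
  tree
}

#' Write a labeled square distance matrix as TSV
#' @param dist a [stats::dist] object.
#' @param path output file.
#' @export
write_dist_tsv <- function(dist, path) {
  m <- as.matrix(dist)
  utils::write.table(data.frame(sample = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
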