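# Sample clustering of single-mutation patterns: row standardization of the
# fraction table (the quantity a heatmap colors relative to each row),
# hierarchical clustering of samples, Newick export, and a replicate
# concordance score on the dendrogram.

#' Row-standardized mutation pattern matrix
#'
#' Transforms each row (mutation) of a fraction table to zero mean and unit
#' variance across samples, using the population standard deviation (divisor
#' n). Constant rows become all zeros. This is the quantity heatmaps color
#' when comparing a cell against the other cells in its row.
#'
#' @param fractions Numeric matrix (mutations x samples), at least 2 columns.
#' @return Matrix of the same shape with standardized rows.
#' @export
pattern_matrix <- function(fractions) {
  fractions <- as.matrix(fractions)
  if (ncol(fractions) < 2L) stop("need at least 2 samples", call. = FALSE)
  mu <- rowMeans(fractions)
  centered <- fractions - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  z <- centered / ifelse(sd_pop > 0, sd_pop, 1)
  z[sd_pop == 0, ] <- 0
  z
}

#' Hierarchical clustering of samples by mutation pattern
#'
#' Agglomerative clustering over the sample columns of a (typically
#' row-standardized) matrix. Defaults are Euclidean distance and complete
#' linkage.
#'
#' @param mat Numeric matrix (mutations x samples), >= 2 columns.
#' @param distance Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An [stats::hclust] object over the samples.
#' @export
cluster_samples <- function(mat, distance = "euclidean", linkage = "complete") {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 samples", call. = FALSE)
  hclust(dist(t(mat), method = distance), method = linkage)
}

#' Export a sample dendrogram as Newick
#'
#' Branch lengths are derived from the merge heights (via
#' [ape::as.phylo.hclust()]), so the tree round-trips through Newick with its
#' merge structure intact.
#'
#' @param hc An `hclust` object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
export_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

# Leaf sets of every internal node of an hclust tree, as lists of leaf labels.
hclust_clades <- function(hc) {
  n <- length(hc$labels %||% seq_len(nrow(hc$merge) + 1L))
  labels <- hc$labels %||% as.character(seq_len(n))
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[i, ], function(j) {
      if (j < 0L) labels[-j] else sets[[j]]
    }))
    sets[[i]] <- members
  }
  sets
}

#' Replicate concordance of a sample dendrogram
#'
#' The fraction of (plasmid, gate) groups whose replicates form a connected
#' subtree (a clade) of the dendrogram. Groups with a single member are
#' trivially connected and count as concordant.
#'
#' @param hc An `hclust` over samples, labelled by sample id.
#' @param samples Sample-metadata data frame (`sample_id`, `plasmid`, `gate`).
#' @return Score in \[0, 1\].
#' @export
replicate_concordance <- function(hc, samples) {
  stopifnot(all(c("sample_id", "plasmid", "gate") %in% names(samples)))
  labels <- hc$labels
  if (is.null(labels)) stop("hclust has no labels", call. = FALSE)
  samples <- samples[samples$sample_id %in% labels, , drop = FALSE]
  groups <- split(samples$sample_id,
                  paste(samples$plasmid, samples$gate, sep = "_"))
  clades <- hclust_clades(hc)
  clade_keys <- vapply(clades, function(s) paste(sort(s), collapse = "\r"),
                       character(1))
  ok <- vapply(groups, function(g) {
    if (length(g) <= 1L) return(TRUE)
    paste(sort(g), collapse = "\r") %in% clade_keys
  }, logical(1))
  mean(ok)
}

#' Heatmap of the standardized mutation pattern (decoration)
#'
#' Convenience wrapper drawing the row-standardized fraction matrix with the
#' sample dendrogram, if the `pheatmap` package is installed.
#'
#' @param z Row-standardized matrix from [pattern_matrix()].
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_mutation_heatmap <- function(z, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_mutation_heatmap requires the 'pheatmap' package",
         call. = FALSE)
  }
  invisible(pheatmap::pheatmap(z, cluster_rows = FALSE,
                               clustering_method = "complete", ...))
}
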