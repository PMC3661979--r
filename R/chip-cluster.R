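#' Hierarchical clustering of factor binding profiles
#'
#' Clusters factors by their binding profiles (rows of a [build_bin_matrix()]
#' matrix, or a factor-by-gene score matrix) using one minus the Pearson
#' correlation as the distance and agglomerative clustering with average
#' linkage. Zero-variance rows cannot be correlated and are dropped with a
#' warning. The pairwise correlation table is kept for heatmap rendering.
#'
#' @param x A `bin_matrix` or a numeric matrix with one row per factor
#'   (rownames required).
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"average"`.
#' @return A `profile_clustering`: list with `hclust` (the tree), `cor`
#'   (factor-by-factor Pearson correlation matrix) and `linkage`.
#' @export
cluster_profiles <- function(x, linkage = "average") {
  mat <- if (inherits(x, "bin_matrix")) x$matrix else as.matrix(x)
  if (is.null(rownames(mat))) rlang::abort("profile matrix needs rownames (factor names)")
  vars <- apply(mat, 1, stats::var)
  if (any(vars == 0)) {
    rlang::warn(sprintf("dropping zero-variance row(s): %s",
                        paste(rownames(mat)[vars == 0], collapse = ", ")))
    mat <- mat[vars > 0, , drop = FALSE]
  }
  if (nrow(mat) < 2) rlang::abort("need >= 2 factors with nonzero variance")
  cor_mat <- cor(t(mat)) # Pearson between factor rows
  d <- as.dist(1 - cor_mat)
  structure(
    list(hclust = hclust(d, method = linkage), cor = cor_mat, linkage = linkage),
    class = "profile_clustering"
  )
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("<profile_clustering: %d factor(s), 1 - Pearson r distance, %s linkage>\n",
              nrow(x$cor), x$linkage))
  invisible(x)
}

#' @describeIn cluster_profiles Pairwise factor correlations and distances as
#'   a tibble (one row per unordered pair).
#' @param ... Unused.
#' @export
tidy.profile_clustering <- function(x, ...) {
  fs <- rownames(x$cor)
  pairs <- utils::combn(fs, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble(factor_a = a, factor_b = b,
           correlation = x$cor[a, b], distance = 1 - x$cor[a, b])
  })
}

#' @describeIn cluster_profiles One-row summary (factor and profile counts,
#'   first merge height).
#' @export
glance.profile_clustering <- function(x, ...) {
  tibble(n_factors = nrow(x$cor),
         linkage = x$linkage,
         first_merge_height = min(x$hclust$height))
}

#' Write a clustering dendrogram as Newick
#'
#' @param clustering A [cluster_profiles()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "profile_clustering"))
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' @describeIn cluster_profiles Heatmap of the pairwise Pearson correlations,
#'   ordered by the dendrogram.
#' @param object A `profile_clustering`.
#' @export
autoplot.profile_clustering <- function(object, ...) {
  ord <- rownames(object$cor)[object$hclust$order]
  df <- as_tibble(as.data.frame.table(object$cor, responseName = "correlation"))
  names(df)[1:2] <- c("factor_a", "factor_b")
  df$factor_a <- factor(df$factor_a, levels = ord)
  df$factor_b <- factor(df$factor_b, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$factor_a, .data$factor_b,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = "Binding-profile correlation") +
    ggplot2::theme_minimal()
}
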