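#' Unsupervised clustering of samples
#'
#' Agglomerative clustering of samples on their log2 intensity profiles,
#' using 1 - Pearson correlation as distance and average linkage (UPGMA).
#' Deterministic given the input column order; equal-distance merges follow
#' the column order.
#'
#' @param m an [expression_matrix()] with at least 2 samples.
#' @return a `sample_cluster`: list wrapping the [stats::hclust()] tree plus
#'   the metric and linkage labels.
#' @export
cluster_samples <- function(m) {
  v <- log2(m$values)
  if (ncol(v) < 2L) stop_input("need >= 2 samples to cluster")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0)) {
    stop_input("sample(s) with zero variance across features: ",
               paste(colnames(v)[sds == 0], collapse = ", "),
               "; correlation distance is undefined - drop the sample or add",
               " features that vary")
  }
  d <- stats::as.dist(1 - stats::cor(v, method = "pearson"))
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, metric = "1 - Pearson correlation",
                 linkage = "average"),
            class = "sample_cluster")
}

#' @export
print.sample_cluster <- function(x, ...) {
  cat(sprintf("<sample_cluster> %d samples, %s distance, %s linkage\n",
              length(x$hclust$labels), x$metric, x$linkage))
  invisible(x)
}

#' @export
plot.sample_cluster <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = paste(x$metric, "/", x$linkage), ...)
}
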