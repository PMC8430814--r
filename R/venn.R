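#' Two-set overlap (Venn) summary
#'
#' Inclusion-exclusion bookkeeping for the per-clone differential feature
#' sets: how many features are called in each clone, how many are common, and
#' the common fraction of the union.
#'
#' Accepts either two id vectors, or explicit counts via `n_c1`, `n_c2`,
#' `n_common` (for reproducing published per-clone counts where the member
#' lists are not available).
#'
#' @param set_c1,set_c2 character vectors of feature ids.
#' @param n_c1,n_c2,n_common alternative count interface.
#' @return a `venn_summary`: list with `n_c1`, `n_c2`, `n_common`, `n_union`,
#'   `pct_common` (percentage of the union common to both clones).
#' @export
venn_summary <- function(set_c1 = NULL, set_c2 = NULL,
                         n_c1 = NULL, n_c2 = NULL, n_common = NULL) {
  if (!is.null(set_c1) || !is.null(set_c2)) {
    set_c1 <- unique(as.character(set_c1))
    set_c2 <- unique(as.character(set_c2))
    n_c1 <- length(set_c1); n_c2 <- length(set_c2)
    n_common <- length(intersect(set_c1, set_c2))
  }
  if (is.null(n_c1) || is.null(n_c2) || is.null(n_common)) {
    stop_usage("supply either two sets or all three counts")
  }
  if (n_common > min(n_c1, n_c2)) {
    stop_input("n_common exceeds a set size")
  }
  n_union <- n_c1 + n_c2 - n_common
  pct <- if (n_union == 0) 0 else 100 * n_common / n_union
  structure(list(n_c1 = n_c1, n_c2 = n_c2, n_common = n_common,
                 n_union = n_union, pct_common = pct),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("<venn_summary> c1: %d, c2: %d, common: %d (%.1f%% of union %d)\n",
              x$n_c1, x$n_c2, x$n_common, x$pct_common, x$n_union))
  invisible(x)
}
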