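#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (monotone-enforced, clipped to 1, input order
#' preserved). Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_input("p must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_input("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

# Welch two-sample t on log2 intensities with an explicit degenerate branch:
# on noiseless data both groups can be constant, where t.test() fails; the
# comparison is then decided by the means alone (p = 0 if they differ).
welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

signed_fc <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
}

#' Differential expression between a resistant clone and its parental control
#'
#' Per feature: Welch two-sample t-test on log2 intensities (clone vs
#' parental), Benjamini-Hochberg adjustment across all tested features of the
#' matrix, and a signed fold change `FC = 2^log2fc` for `log2fc >= 0`, else
#' `-2^(-log2fc)`. A feature is called `up` when `FC >= fold_threshold` and
#' `adj_p < alpha`, `down` when `FC <= -fold_threshold` and `adj_p < alpha`,
#' otherwise `unchanged`. Magnitudes exactly at the fold threshold are
#' retained (non-strict fold inequality; strict `< alpha`).
#'
#' @param m an [expression_matrix()].
#' @param clone resistant clone label present in the sample descriptors.
#' @param cell_line cell line to analyse; defaults to the only one present.
#' @param parental label of the control clone (default `"parental"`).
#' @param fold_threshold minimum absolute signed fold change (default 2).
#' @param alpha FDR threshold (default 0.05).
#' @return a `de_result` data frame with one row per feature: `feature_id`,
#'   `mean_log2_parental`, `mean_log2_clone`, `log2fc`, `fold_change`,
#'   `p_value`, `adj_p`, `direction`.
#' @export
differential_expression <- function(m, clone, cell_line = NULL,
                                    parental = "parental",
                                    fold_threshold = 2, alpha = 0.05) {
  s <- m$samples
  if (is.null(cell_line)) {
    cl <- unique(s$cell_line)
    if (length(cl) > 1L) {
      stop_usage("matrix holds several cell lines (",
                 paste(cl, collapse = ", "), "); pass cell_line")
    }
    cell_line <- cl
  }
  in_line <- s$cell_line == cell_line
  idx_c <- which(in_line & s$clone == clone)
  idx_p <- which(in_line & s$clone == parental)
  if (length(idx_c) < 2L || length(idx_p) < 2L) {
    stop_input("need >= 2 replicates per group; found ", length(idx_c),
               " for '", clone, "' and ", length(idx_p), " for '", parental, "'")
  }
  lv <- log2(m$values)
  mc <- rowMeans(lv[, idx_c, drop = FALSE])
  mp <- rowMeans(lv[, idx_p, drop = FALSE])
  pv <- vapply(seq_len(nrow(lv)), function(i) {
    welch_p(lv[i, idx_c], lv[i, idx_p])
  }, numeric(1))
  log2fc <- mc - mp
  fc <- signed_fc(log2fc)
  adj <- bh_adjust(pv)
  direction <- rep("unchanged", length(fc))
  direction[fc >= fold_threshold & adj < alpha] <- "up"
  direction[fc <= -fold_threshold & adj < alpha] <- "down"
  res <- data.frame(feature_id = rownames(m$values),
                    mean_log2_parental = mp, mean_log2_clone = mc,
                    log2fc = log2fc, fold_change = fc,
                    p_value = pv, adj_p = adj, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("de_result", "data.frame"),
            cell_line = cell_line, clone = clone,
            fold_threshold = fold_threshold, alpha = alpha)
}

#' Up/down feature sets of a differential-expression result
#'
#' @param de a `de_result` from [differential_expression()].
#' @return a `de_set`: list with `cell_line`, `clone`, `up`, `down`
#'   (disjoint character vectors of feature ids).
#' @export
de_set <- function(de) {
  stopifnot(inherits(de, "de_result"))
  structure(list(cell_line = attr(de, "cell_line"), clone = attr(de, "clone"),
                 up = de$feature_id[de$direction == "up"],
                 down = de$feature_id[de$direction == "down"]),
            class = "de_set")
}

#' Assemble a de_set from explicit feature lists
#'
#' Used when directions come from an external source (e.g. a published table)
#' rather than from [differential_expression()].
#'
#' @param up,down character vectors of feature ids (must be disjoint).
#' @param cell_line,clone labels.
#' @export
make_de_set <- function(up, down, cell_line = NA_character_,
                        clone = NA_character_) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down))) {
    stop_input("up and down sets must be disjoint")
  }
  structure(list(cell_line = cell_line, clone = clone, up = up, down = down),
            class = "de_set")
}

#' @export
print.de_set <- function(x, ...) {
  cat(sprintf("<de_set> %s/%s: %d up, %d down\n", x$cell_line, x$clone,
              length(x$up), length(x$down)))
  invisible(x)
}

#' Write a differential-expression table to TSV
#' @param de a `de_result`.
#' @param path output file.
#' @export
write_de <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
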