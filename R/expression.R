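#' Construct an expression matrix
#'
#' The unit of all differential-expression work: a features-by-samples matrix
#' of strictly positive, linear-scale intensities with parsed sample
#' descriptors and optional per-feature annotation.
#'
#' @param values numeric matrix, features in rows, samples in columns; row
#'   names are feature ids and column names sample ids encoded as
#'   `<cellline>_<clone>_<replicate>` (e.g. `786O_c1_2`).
#' @param feature_kind `"miRNA"` or `"gene"`.
#' @param annotation optional data frame with columns `feature_id` and
#'   `category` (for genes: `coding`, `multiple complex`, `other`,
#'   `unannotated`).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, feature_kind = c("miRNA", "gene"),
                              annotation = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("values must be a numeric matrix")
  }
  if (nrow(values) > 0L && is.null(rownames(values))) {
    stop_format("values must carry feature ids as rownames")
  }
  if (is.null(colnames(values))) {
    stop_format("values must carry sample ids as colnames")
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (anyDuplicated(rownames(values))) {
    stop_format("duplicate feature ids: ",
                paste(unique(rownames(values)[duplicated(rownames(values))]),
                      collapse = ", "))
  }
  if (anyNA(values) || any(values <= 0)) {
    stop_format("intensities must be strictly positive and non-missing")
  }
  samples <- parse_sample_ids(colnames(values))
  if (!is.null(annotation)) {
    if (!all(c("feature_id", "category") %in% names(annotation))) {
      stop_format("annotation needs columns feature_id and category")
    }
    annotation <- annotation[match(rownames(values), annotation$feature_id), ,
                             drop = FALSE]
    annotation$feature_id <- rownames(values)
    annotation$category[is.na(annotation$category)] <- "unannotated"
    rownames(annotation) <- NULL
  }
  structure(list(values = values, feature_kind = feature_kind,
                 samples = samples, annotation = annotation),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %s: %d features x %d samples\n",
              x$feature_kind, nrow(x$values), ncol(x$values)))
  grp <- unique(x$samples[c("cell_line", "clone")])
  cat("  groups:", paste(paste0(grp$cell_line, "/", grp$clone), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a header row `feature_id<TAB>sample...`; sample ids encode their
#' descriptors as `<cellline>_<clone>_<replicate>`. An optional sidecar
#' annotation TSV (`feature_id<TAB>category`) supplies gene categories.
#'
#' @param path TSV file.
#' @param feature_kind `"miRNA"` or `"gene"`.
#' @param annotation_path optional annotation TSV.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, feature_kind = c("miRNA", "gene"),
                            annotation_path = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop_input("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_format("expression TSV needs >= 2 columns")
  ids <- as.character(df[[1L]])
  body <- as.matrix(df[-1L])
  if (!is.numeric(body)) stop_format("non-numeric intensity values in ", path)
  rownames(body) <- ids
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
    names(ann)[1:2] <- c("feature_id", "category")
  }
  expression_matrix(body, feature_kind, annotation = ann)
}

#' Write an expression matrix to TSV
#'
#' Full-precision round-trip companion of [read_expression()].
#'
#' @param m an `expression_matrix`.
#' @param path output TSV.
#' @param annotation_path optional path for the annotation sidecar.
#' @export
write_expression <- function(m, path, annotation_path = NULL) {
  df <- data.frame(feature_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path) && !is.null(m$annotation)) {
    utils::write.table(m$annotation, annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

keep_features <- function(m, keep) {
  values <- m$values[keep, , drop = FALSE]
  ann <- m$annotation
  if (!is.null(ann)) {
    ann <- ann[ann$feature_id %in% rownames(values), , drop = FALSE]
    rownames(ann) <- NULL
  }
  structure(list(values = values, feature_kind = m$feature_kind,
                 samples = m$samples, annotation = ann),
            class = "expression_matrix")
}

#' Filter probes by identity or annotation category
#'
#' In `mirna` mode, keeps mature human miRNA probes by id prefix (default
#' `hsa-miR`, the wildcard used on miRNA arrays; note this literally excludes
#' `hsa-let-*` ids — pass `prefix = "hsa-"` to keep them). In `gene` mode,
#' keeps probes whose annotation category is `coding` or `multiple complex`
#' and drops unannotated symbols (missing category, or a purely numeric
#' placeholder symbol).
#'
#' @param m an `expression_matrix`.
#' @param mode `"mirna"` or `"gene"`; must match `m$feature_kind`.
#' @param prefix miRNA id prefix kept in `mirna` mode.
#' @param categories annotation categories kept in `gene` mode.
#' @return the filtered `expression_matrix`.
#' @export
filter_probes <- function(m, mode = c("mirna", "gene"), prefix = "hsa-miR",
                          categories = c("coding", "multiple complex")) {
  mode <- match.arg(mode)
  kind <- if (mode == "mirna") "miRNA" else "gene"
  if (m$feature_kind != kind) {
    stop_usage("mode '", mode, "' does not match feature_kind '",
               m$feature_kind, "'")
  }
  ids <- rownames(m$values)
  if (mode == "mirna") {
    keep <- startsWith(ids, prefix)
  } else {
    annotated <- !grepl("^[0-9]+$", ids)
    if (is.null(m$annotation)) {
      keep <- annotated
    } else {
      keep <- m$annotation$category %in% categories & annotated
    }
  }
  keep_features(m, keep)
}

#' Filter features by intensity
#'
#' Retains features whose maximum intensity across samples exceeds a
#' threshold (default 50, the conventional floor for array probes considered
#' expressed). The per-feature maximum is used so that a feature expressed in
#' any one condition survives.
#'
#' @param m an `expression_matrix`.
#' @param threshold non-negative intensity cutoff.
#' @return the filtered `expression_matrix`.
#' @export
intensity_filter <- function(m, threshold = 50) {
  if (!is.numeric(threshold) || threshold < 0) {
    stop_input("threshold must be >= 0")
  }
  if (threshold == 0) return(m)
  keep <- apply(m$values, 1L, max) > threshold
  keep_features(m, keep)
}
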