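#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' member genes. Duplicate genes within a set are collapsed.
#'
#' @param path GMT file.
#' @return a `gene_set_collection`: named list of character vectors, with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short)) {
    stop_format("GMT line(s) with fewer than 3 fields: line ",
                paste(which(short), collapse = ", "))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop_format("duplicate gene-set names in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  structure(sets, descriptions = stats::setNames(
    vapply(fields, `[[`, "", 2L), nm), class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param gsc a `gene_set_collection` (or plain named list of gene vectors).
#' @param path output file.
#' @export
write_gmt <- function(gsc, path) {
  desc <- attr(gsc, "descriptions") %||%
    stats::setNames(rep("", length(gsc)), names(gsc))
  lines <- vapply(names(gsc), function(nm) {
    paste(c(nm, desc[[nm]], gsc[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query overlaps it more than expected
#' when drawing `n = |query|` genes from the universe without replacement:
#' the upper-tail hypergeometric probability of observing at least the seen
#' overlap. P-values are Benjamini-Hochberg adjusted across sets and rows are
#' sorted by p.
#'
#' By default the universe is the union of all collection genes; sets and
#' query are intersected with the universe, so genes outside it are ignored.
#'
#' @param query character vector of gene symbols (non-empty).
#' @param gsc a `gene_set_collection`.
#' @param universe optional explicit background; default
#'   `union of all collection genes`.
#' @return data frame of class `enrichment_result`: `set`, `k` (overlap),
#'   `K` (set size), `n` (query size in universe), `N` (universe size),
#'   `p_value`, `adj_p`, `genes` (overlap, comma-separated).
#' @export
hypergeom_enrich <- function(query, gsc, universe = NULL) {
  query <- unique(as.character(query))
  if (!length(query)) stop_usage("query gene set is empty")
  if (is.null(universe)) universe <- unique(unlist(gsc, use.names = FALSE))
  universe <- unique(as.character(universe))
  sets <- lapply(gsc, intersect, universe)
  q <- intersect(query, universe)
  if (!length(q)) stop_usage("no query gene lies in the universe")
  N <- length(universe); n <- length(q)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    K <- length(s)
    ov <- intersect(q, s)
    k <- length(ov)
    # P(X >= k) drawing n from N with K successes
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p_value = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set),
             c("set", "k", "K", "n", "N", "p_value", "adj_p", "genes")]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}
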