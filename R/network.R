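#' Construct a validated miRNA:target reference network
#'
#' @param mirna,gene character vectors of equal length giving the edges.
#' @param provenance free-text source label.
#' @return a `reference_network` data frame with columns `mirna`, `gene`;
#'   duplicate edges are collapsed and bipartiteness is enforced (no token may
#'   appear both as a miRNA and as a gene).
#' @export
reference_network <- function(mirna, gene, provenance = "user") {
  mirna <- trimws(as.character(mirna)); gene <- trimws(as.character(gene))
  if (length(mirna) != length(gene)) stop_input("mirna and gene lengths differ")
  both <- intersect(mirna, gene)
  if (length(both)) {
    stop_format("token(s) appear in both columns (network must be bipartite): ",
                paste(utils::head(both, 5L), collapse = ", "))
  }
  edges <- unique(data.frame(mirna = mirna, gene = gene,
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  structure(edges, class = c("reference_network", "data.frame"),
            provenance = provenance)
}

#' Read a miRNA:target reference network from two-column TSV
#'
#' miRTarBase-style export: first column miRNA id, second column target gene
#' symbol, optional header. Ids are whitespace-trimmed and the `hsa-` species
#' prefix is case-normalised; mature-arm suffixes (`-5p`/`-3p`) are never
#' collapsed, since arm identity is meaningful in validated target databases.
#'
#' @param path TSV file.
#' @return a [reference_network()].
#' @export
read_reference_network <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_format("empty reference network file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, 1L) < 2L)) {
    stop_format("reference network rows need two tab-separated columns")
  }
  m <- vapply(fields, `[[`, "", 1L)
  g <- vapply(fields, `[[`, "", 2L)
  # drop an optional header row
  if (grepl("^(mirna|mir|source|mirna_id)$", tolower(trimws(m[1L])))) {
    m <- m[-1L]; g <- g[-1L]
    if (!length(m)) stop_format("reference network has a header but no edges")
  }
  m <- sub("^(?i)hsa-", "hsa-", trimws(m), perl = TRUE)
  reference_network(m, trimws(g), provenance = path)
}

#' Map differential features onto a reference network
#'
#' Counts how many differentially expressed features (miRNAs plus genes, as
#' unique node identities) are present as nodes of the reference network.
#'
#' @param net a [reference_network()].
#' @param mirna_de,gene_de `de_set`s for the same clone.
#' @return a `mapping_stats` list: `n_de_features`, `n_mapped`, `pct_mapped`
#'   (0 with `undefined = TRUE` when there are no DE features).
#' @export
map_de_features <- function(net, mirna_de, gene_de) {
  de_mirnas <- unique(c(mirna_de$up, mirna_de$down))
  de_genes <- unique(c(gene_de$up, gene_de$down))
  n_de <- length(de_mirnas) + length(de_genes)
  n_mapped <- sum(de_mirnas %in% net$mirna) + sum(de_genes %in% net$gene)
  undefined <- n_de == 0L
  structure(list(n_de_features = n_de, n_mapped = n_mapped,
                 pct_mapped = if (undefined) 0 else 100 * n_mapped / n_de,
                 undefined = undefined),
            class = "mapping_stats")
}

#' @export
print.mapping_stats <- function(x, ...) {
  cat(sprintf("<mapping_stats> %d/%d DE features on the network (%.1f%%)%s\n",
              x$n_mapped, x$n_de_features, x$pct_mapped,
              if (x$undefined) " [no DE features]" else ""))
  invisible(x)
}

new_directed_network <- function(edges, class, label) {
  rownames(edges) <- NULL
  structure(edges, class = c(class, "data.frame"), label = label)
}

#' Inverse-correlation clone network
#'
#' Retains a reference edge for one resistant clone iff the miRNA and its
#' target gene were differentially expressed in opposite directions in that
#' clone (up-regulated miRNA with down-regulated gene, or vice versa) —
#' the expected signature of miRNA-mediated repression.
#'
#' @param net a [reference_network()].
#' @param mirna_de,gene_de `de_set`s from the same clone.
#' @return a `clone_network` data frame: `mirna`, `mirna_dir`, `gene`,
#'   `gene_dir`, with `mirna_dir != gene_dir` on every row.
#' @export
clone_network <- function(net, mirna_de, gene_de) {
  mdir <- c(stats::setNames(rep("up", length(mirna_de$up)), mirna_de$up),
            stats::setNames(rep("down", length(mirna_de$down)), mirna_de$down))
  gdir <- c(stats::setNames(rep("up", length(gene_de$up)), gene_de$up),
            stats::setNames(rep("down", length(gene_de$down)), gene_de$down))
  md <- mdir[net$mirna]
  gd <- gdir[net$gene]
  keep <- !is.na(md) & !is.na(gd) & md != gd
  edges <- data.frame(mirna = net$mirna[keep], mirna_dir = unname(md[keep]),
                      gene = net$gene[keep], gene_dir = unname(gd[keep]),
                      stringsAsFactors = FALSE)
  new_directed_network(edges, "clone_network",
                       label = mirna_de$clone %||% NA_character_)
}

#' Direction-consistent intersection of two clone networks
#'
#' An edge enters the common network only when present in both clones with
#' identical direction annotations: an interaction inverse-correlated in
#' opposite senses across the two clones is not one consistent mechanism.
#' Commutative and idempotent.
#'
#' @param a,b `clone_network`s from the same cell line.
#' @param cell_line label for the result.
#' @return a `common_network` with the same columns as a `clone_network`.
#' @export
intersect_clones <- function(a, b, cell_line = NA_character_) {
  key <- function(x) paste(x$mirna, x$mirna_dir, x$gene, x$gene_dir, sep = "\r")
  keep <- key(a) %in% key(b)
  edges <- as.data.frame(a)[keep, , drop = FALSE]
  edges <- unique(edges)
  new_directed_network(edges, "common_network", label = cell_line)
}

#' Assemble a common network from explicit annotated edges
#'
#' For replaying externally reported networks (e.g. published interaction
#' tables) through [summarize_network()].
#'
#' @param mirna,mirna_dir,gene,gene_dir equal-length vectors;
#'   directions in `{"up","down"}` with `mirna_dir != gene_dir` per edge.
#' @param cell_line label.
#' @export
common_network <- function(mirna, mirna_dir, gene, gene_dir,
                           cell_line = NA_character_) {
  edges <- data.frame(mirna = as.character(mirna),
                      mirna_dir = as.character(mirna_dir),
                      gene = as.character(gene),
                      gene_dir = as.character(gene_dir),
                      stringsAsFactors = FALSE)
  if (!all(edges$mirna_dir %in% c("up", "down")) ||
      !all(edges$gene_dir %in% c("up", "down"))) {
    stop_input("directions must be 'up' or 'down'")
  }
  if (any(edges$mirna_dir == edges$gene_dir)) {
    stop_input("every edge must be inverse-correlated (mirna_dir != gene_dir)")
  }
  new_directed_network(unique(edges), "common_network", label = cell_line)
}

#' Summarize a common resistance network
#'
#' @param cn a `common_network` (or `clone_network`).
#' @return a `network_summary`: interaction and node counts split by miRNA
#'   direction, the per-gene in-degree table, and the most-targeted gene(s)
#'   (ties all reported, sorted lexicographically).
#' @export
summarize_network <- function(cn) {
  e <- as.data.frame(cn)
  up <- e[e$mirna_dir == "up", , drop = FALSE]
  down <- e[e$mirna_dir == "down", , drop = FALSE]
  indeg <- sort(table(e$gene), decreasing = TRUE)
  most <- if (length(indeg)) sort(names(indeg)[indeg == max(indeg)]) else character()
  structure(list(
    n_interactions = nrow(e),
    n_up_mirnas = length(unique(up$mirna)),
    n_down_mirnas = length(unique(down$mirna)),
    n_interactions_up = nrow(up),
    n_interactions_down = nrow(down),
    n_genes_targeted_by_up = length(unique(up$gene)),
    n_genes_targeted_by_down = length(unique(down$gene)),
    in_degree = indeg,
    most_targeted_genes = most
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0("<network_summary> %d interactions: %d with %d ",
                     "up-miRNAs (%d genes), %d with %d down-miRNAs (%d genes)\n"),
              x$n_interactions, x$n_interactions_up, x$n_up_mirnas,
              x$n_genes_targeted_by_up, x$n_interactions_down,
              x$n_down_mirnas, x$n_genes_targeted_by_down))
  if (length(x$most_targeted_genes)) {
    cat("  most targeted:", paste(x$most_targeted_genes, collapse = ", "),
        sprintf("(in-degree %d)\n", max(x$in_degree)))
  }
  invisible(x)
}

#' Export an annotated network
#'
#' Formats: `tsv` (lossless edge list: mirna, mirna_dir, gene, gene_dir),
#' `sif` (Cytoscape simple interaction format; the relation token encodes the
#' direction pair, e.g. `down_up`), `graphml` (via igraph, with `direction`
#' node attributes and `relation` edge attributes).
#'
#' @param cn a `clone_network` or `common_network`.
#' @param path output file.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @export
export_network <- function(cn, path, format = c("tsv", "sif", "graphml")) {
  if (!is.character(format) ||
      !all(format %in% c("tsv", "sif", "graphml"))) {
    stop_usage("unknown export format: ", paste(format, collapse = ", "))
  }
  format <- match.arg(format)
  e <- as.data.frame(cn)
  if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    lines <- if (nrow(e)) {
      paste(e$mirna, paste0(e$mirna_dir, "_", e$gene_dir), e$gene, sep = "\t")
    } else character()
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$mirna, to = e$gene,
                 relation = paste0(e$mirna_dir, "_", e$gene_dir)),
      directed = TRUE,
      vertices = unique(rbind(
        data.frame(name = e$mirna, kind = "miRNA", direction = e$mirna_dir),
        data.frame(name = e$gene, kind = "gene", direction = e$gene_dir))))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an annotated network edge list written by [export_network()]
#'
#' @param path TSV with columns mirna, mirna_dir, gene, gene_dir.
#' @param cell_line label for the result.
#' @return a `common_network`.
#' @export
read_network_edges <- function(path, cell_line = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "mirna_dir", "gene", "gene_dir")
  if (!all(need %in% names(df))) {
    stop_format("edge list needs columns: ", paste(need, collapse = ", "))
  }
  common_network(df$mirna, df$mirna_dir, df$gene, df$gene_dir, cell_line)
}
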