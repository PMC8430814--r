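#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `mirna_expression`, `gene_expression`,
#' `gene_annotation` (optional), `reference_network`, `gmt` (optional),
#' `cell_line` (optional when the matrices hold a single one), `clones`
#' (default `c1`, `c2`), `fold_threshold` (2), `alpha` (0.05),
#' `intensity_threshold` (50), `mirna_prefix` (`hsa-miR`), `out_dir`, `seed`.
#'
#' @param path YAML file; relative data paths are resolved against its
#'   directory.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) NULL
    else if (file.exists(p)) p
    else file.path(base, p)
  }
  for (k in c("mirna_expression", "gene_expression", "gene_annotation",
              "reference_network", "gmt")) {
    cfg[[k]] <- resolve(cfg[[k]])
  }
  pipeline_config(cfg)
}

#' Validate a pipeline configuration
#' @param cfg named list, see [read_pipeline_config()] for keys.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(cfg) {
  defaults <- list(clones = c("c1", "c2"), fold_threshold = 2, alpha = 0.05,
                   intensity_threshold = 50, mirna_prefix = "hsa-miR",
                   out_dir = NULL, seed = 1L, cell_line = NULL,
                   gene_annotation = NULL, gmt = NULL)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  for (k in c("mirna_expression", "gene_expression", "reference_network")) {
    if (is.null(cfg[[k]])) stop_usage("config is missing '", k, "'")
    if (!file.exists(cfg[[k]])) stop_input("config path not found: ", cfg[[k]])
  }
  if (length(unique(cfg$clones)) != 2L) {
    stop_input("exactly two distinct resistant clone labels are required")
  }
  if (cfg$fold_threshold <= 0 || cfg$alpha <= 0 || cfg$intensity_threshold < 0) {
    stop_input("thresholds must be positive")
  }
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  invisible(NULL)
}

#' Run the integrated miRNA-mRNA resistance-network workflow
#'
#' End-to-end orchestration: probe filtering -> per-clone differential
#' expression on both platforms -> clone-overlap (Venn) summaries -> mapping
#' onto the validated reference network -> inverse-correlation clone networks
#' -> direction-consistent clone intersection -> common-network summary ->
#' optional hypergeometric enrichment of the common-network genes. All
#' artifacts are written under `cfg$out_dir` (when set) and every reported
#' count is recomputed from the emitted files as a self-consistency check.
#'
#' @param cfg a `pipeline_config` (or path to a YAML config).
#' @param verbose log one line per stage.
#' @return a `run_report` (list) with per-stage results.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(as.integer(cfg$seed))

  mir <- read_expression(cfg$mirna_expression, "miRNA")
  gen <- read_expression(cfg$gene_expression, "gene",
                         annotation_path = cfg$gene_annotation)
  stage_log(verbose, "load", "miRNA %d x %d; gene %d x %d",
            nrow(mir$values), ncol(mir$values), nrow(gen$values),
            ncol(gen$values))

  mir <- filter_probes(mir, "mirna", prefix = cfg$mirna_prefix)
  gen <- filter_probes(gen, "gene")
  gen <- intensity_filter(gen, cfg$intensity_threshold)
  stage_log(verbose, "filter", "kept %d miRNA and %d gene probes",
            nrow(mir$values), nrow(gen$values))

  cell_line <- cfg$cell_line %||% unique(mir$samples$cell_line)
  if (length(cell_line) != 1L) {
    stop_usage("config must name one cell_line; matrices hold: ",
               paste(cell_line, collapse = ", "))
  }

  net <- read_reference_network(cfg$reference_network)
  de <- list(); sets <- list(); mapping <- list(); clone_nets <- list()
  for (cl in cfg$clones) {
    de[[cl]] <- list(
      mirna = differential_expression(mir, cl, cell_line = cell_line,
                                      fold_threshold = cfg$fold_threshold,
                                      alpha = cfg$alpha),
      gene = differential_expression(gen, cl, cell_line = cell_line,
                                     fold_threshold = cfg$fold_threshold,
                                     alpha = cfg$alpha))
    sets[[cl]] <- lapply(de[[cl]], de_set)
    mapping[[cl]] <- map_de_features(net, sets[[cl]]$mirna, sets[[cl]]$gene)
    clone_nets[[cl]] <- clone_network(net, sets[[cl]]$mirna, sets[[cl]]$gene)
    stage_log(verbose, "de", "%s: %d/%d miRNAs, %d/%d genes up/down; %d mapped; %d clone edges",
              cl, length(sets[[cl]]$mirna$up), length(sets[[cl]]$mirna$down),
              length(sets[[cl]]$gene$up), length(sets[[cl]]$gene$down),
              mapping[[cl]]$n_mapped, nrow(clone_nets[[cl]]))
  }

  c1 <- cfg$clones[[1L]]; c2 <- cfg$clones[[2L]]
  venn <- list(
    mirna = venn_summary(c(sets[[c1]]$mirna$up, sets[[c1]]$mirna$down),
                         c(sets[[c2]]$mirna$up, sets[[c2]]$mirna$down)),
    gene = venn_summary(c(sets[[c1]]$gene$up, sets[[c1]]$gene$down),
                        c(sets[[c2]]$gene$up, sets[[c2]]$gene$down)))
  common <- intersect_clones(clone_nets[[c1]], clone_nets[[c2]],
                             cell_line = cell_line)
  summary <- summarize_network(common)
  stage_log(verbose, "network", "common network: %d edges",
            summary$n_interactions)

  enrichment <- NULL
  if (!is.null(cfg$gmt) && nrow(common) > 0L) {
    gsc <- read_gmt(cfg$gmt)
    enrichment <- hypergeom_enrich(unique(common$gene), gsc)
    stage_log(verbose, "enrich", "%d gene sets tested", nrow(enrichment))
  }

  report <- structure(list(
    package_version = as.character(utils::packageVersion("mirtarnet")),
    config = unclass(cfg), cell_line = cell_line,
    de = de, de_sets = sets, venn = venn, mapping = mapping,
    clone_networks = clone_nets, common_network = common,
    network_summary = summary, enrichment = enrichment
  ), class = "run_report")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cl in cfg$clones) {
      write_de(de[[cl]]$mirna, file.path(cfg$out_dir,
                                         paste0("de_mirna_", cl, ".tsv")))
      write_de(de[[cl]]$gene, file.path(cfg$out_dir,
                                        paste0("de_gene_", cl, ".tsv")))
      export_network(clone_nets[[cl]],
                     file.path(cfg$out_dir, paste0("clone_network_", cl, ".tsv")),
                     "tsv")
    }
    export_network(common, file.path(cfg$out_dir, "common_network.tsv"), "tsv")
    export_network(common, file.path(cfg$out_dir, "common_network.sif"), "sif")
    if (!is.null(enrichment)) {
      utils::write.table(as.data.frame(enrichment),
                         file.path(cfg$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report_counts(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    verify_report(report)
    stage_log(verbose, "write", "artifacts in %s (self-consistency ok)",
              cfg$out_dir)
  }
  report
}

# numeric view of a run report (serialised alongside the artifacts)
report_counts <- function(report) {
  cls <- names(report$de)
  de_counts <- lapply(report$de_sets, function(s) {
    list(mirna_up = length(s$mirna$up), mirna_down = length(s$mirna$down),
         gene_up = length(s$gene$up), gene_down = length(s$gene$down))
  })
  list(package_version = report$package_version,
       cell_line = report$cell_line,
       de = de_counts,
       venn = lapply(report$venn, unclass),
       mapping = lapply(report$mapping, function(m) unclass(m)[1:3]),
       clone_network_edges = lapply(report$clone_networks, nrow),
       common_network = unclass(report$network_summary)[
         c("n_interactions", "n_up_mirnas", "n_down_mirnas",
           "n_genes_targeted_by_up", "n_genes_targeted_by_down")])
}

# re-read the emitted files and check that the report's counts match
verify_report <- function(report) {
  out <- report$config$out_dir
  for (cl in names(report$de)) {
    for (kind in c("mirna", "gene")) {
      f <- file.path(out, paste0("de_", kind, "_", cl, ".tsv"))
      df <- utils::read.delim(f, stringsAsFactors = FALSE)
      s <- report$de_sets[[cl]][[kind]]
      stopifnot(sum(df$direction == "up") == length(s$up),
                sum(df$direction == "down") == length(s$down))
    }
    cn <- read_network_edges(file.path(out, paste0("clone_network_", cl,
                                                   ".tsv")))
    stopifnot(nrow(cn) == nrow(report$clone_networks[[cl]]))
  }
  common <- read_network_edges(file.path(out, "common_network.tsv"))
  stopifnot(nrow(common) == report$network_summary$n_interactions)
  invisible(TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s (mirtarnet %s)\n", x$cell_line,
              x$package_version))
  for (cl in names(x$de_sets)) {
    s <- x$de_sets[[cl]]
    cat(sprintf("  %s: miRNAs %d up / %d down; genes %d up / %d down; %d clone edges\n",
                cl, length(s$mirna$up), length(s$mirna$down),
                length(s$gene$up), length(s$gene$down),
                nrow(x$clone_networks[[cl]])))
  }
  cat(sprintf("  miRNA overlap: %d/%d (%.1f%%); gene overlap: %d/%d (%.1f%%)\n",
              x$venn$mirna$n_common, x$venn$mirna$n_union,
              x$venn$mirna$pct_common, x$venn$gene$n_common,
              x$venn$gene$n_union, x$venn$gene$pct_common))
  print(x$network_summary)
  invisible(x)
}

#' Compare a recovered common network against a planted truth
#'
#' Precision and recall of the recovered edge set (miRNA, gene pairs) with
#' respect to the planted pairs.
#'
#' @param common a `common_network`.
#' @param truth a `planted_truth` data frame (from [simulate_experiment()]).
#' @return list with `precision`, `recall`, `n_recovered`, `n_true`,
#'   `true_positives`.
#' @export
recovery_stats <- function(common, truth) {
  got <- paste(common$mirna, common$gene, sep = "\r")
  want <- paste(truth$mirna, truth$gene, sep = "\r")
  tp <- sum(got %in% want)
  list(precision = if (length(got)) tp / length(got) else NA_real_,
       recall = tp / length(want),
       n_recovered = length(got), n_true = length(want),
       true_positives = tp)
}

#' Published common resistance networks bundled with the package
#'
#' Returns the common miRNA:gene interaction network reported for one
#' sunitinib-resistant ccRCC cell line (786-O, A498 or Caki-1), re-encoded
#' from the published interaction table, as a `common_network` ready for
#' [summarize_network()].
#'
#' @param cell_line `"786-O"`, `"A498"` or `"Caki-1"`.
#' @return a `common_network`.
#' @export
published_common_network <- function(cell_line = c("786-O", "A498", "Caki-1")) {
  cell_line <- match.arg(cell_line)
  path <- system.file("extdata", "ccrcc_sunitinib_common_networks.tsv",
                      package = "mirtarnet", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- df[df$cell_line == cell_line, , drop = FALSE]
  common_network(df$mirna, df$mirna_dir, df$gene, df$gene_dir,
                 cell_line = cell_line)
}

#' Published sunitinib IC50 replicate tables bundled with the package
#'
#' Per-replicate IC50 values (µM, biological triplicates) for parental and
#' resistant clones of the three ccRCC cell lines, from the MTT viability
#' experiments: the sunitinib dose-response table and the CD274-silencing
#' (siRNA vs scramble control) table.
#'
#' @param which `"resistance"` or `"silencing"`.
#' @return data frame with columns `cell_line`, `group`, `replicate`, `ic50`.
#' @export
published_ic50 <- function(which = c("resistance", "silencing")) {
  which <- match.arg(which)
  f <- if (which == "resistance") "ccrcc_sunitinib_ic50.csv" else
    "ccrcc_cd274_silencing_ic50.csv"
  path <- system.file("extdata", f, package = "mirtarnet", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published per-clone differential-expression counts bundled with the package
#'
#' Counts of differentially expressed features (annotated genes, and mature
#' human miRNAs) per resistant clone and their clone overlap, as reported for
#' the three sunitinib-resistant ccRCC cell lines. Feed the rows to
#' [venn_summary()] to reproduce the published union sizes and common
#' percentages.
#'
#' @return data frame with columns `feature_kind`, `cell_line`, `n_c1`,
#'   `n_c2`, `n_common`.
#' @export
published_de_counts <- function() {
  path <- system.file("extdata", "ccrcc_de_counts.csv", package = "mirtarnet",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
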