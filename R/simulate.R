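#' Simulation design for a planted-signal resistance experiment
#'
#' Describes a synthetic two-platform microarray experiment emulating the
#' acquired-resistance design: one or more cell lines, each with a parental
#' population and two independently derived resistant clones, measured in
#' biological triplicate on a miRNA and a gene platform. A set of
#' miRNA->gene repression pairs is planted: in every resistant clone the
#' miRNA and its target move in opposite directions by `effect_log2fc` on the
#' log2 scale, consistently across clones. All planted pairs are emitted as
#' reference-network edges, diluted with decoy edges.
#'
#' Non-planted features are "background-active" in each clone independently
#' with rate `background_de_rate` (direction resampled per clone), emulating
#' clone-private transcriptional drift: such features can create
#' inverse-correlated edges within a single clone that the clone intersection
#' must remove. Decoy edges never join two planted features, since a decoy
#' connecting two coordinately shifted features would be signal by
#' construction.
#'
#' @param n_mirnas,n_genes feature counts (defaults 100 and 120, sized by a Monte-Carlo power analysis so a
#'   2-log2 effect is detectable after FDR control in a triplicate design).
#' @param n_replicates replicates per (cell line, clone) group, default 3.
#' @param cell_lines character vector of cell-line labels.
#' @param clones resistant clone labels (a `parental` group always exists).
#' @param n_true_pairs planted miRNA->gene repression pairs (default 50).
#' @param n_decoy_edges reference edges that are not planted (default 450).
#' @param effect_log2fc planted absolute log2 fold change, >= 1 so planted
#'   pairs exceed the 2-fold filter in expectation (default 2).
#' @param noise_sd replicate standard deviation on the log2 scale (default
#'   0.25).
#' @param baseline_log2_mean,baseline_log2_sd log2-intensity baseline
#'   distribution (defaults 10 and 1.5: log-normal linear intensities typical
#'   of expressed array probes, comfortably above the conventional
#'   intensity-50 expression floor).
#' @param background_de_rate per-clone probability that a non-planted feature
#'   drifts by `effect_log2fc` in a random direction (default 0.05).
#' @param seed RNG seed.
#' @return a validated `simulation_design` list.
#' @export
simulation_design <- function(n_mirnas = 100, n_genes = 120,
                              n_replicates = 3,
                              cell_lines = "SIM",
                              clones = c("c1", "c2"),
                              n_true_pairs = 50, n_decoy_edges = 450,
                              effect_log2fc = 2, noise_sd = 0.25,
                              baseline_log2_mean = 10, baseline_log2_sd = 1.5,
                              background_de_rate = 0.05, seed = 1L) {
  d <- list(n_mirnas = n_mirnas, n_genes = n_genes,
            n_replicates = n_replicates, cell_lines = cell_lines,
            clones = clones, n_true_pairs = n_true_pairs,
            n_decoy_edges = n_decoy_edges, effect_log2fc = effect_log2fc,
            noise_sd = noise_sd, baseline_log2_mean = baseline_log2_mean,
            baseline_log2_sd = baseline_log2_sd,
            background_de_rate = background_de_rate, seed = as.integer(seed))
  counts <- c("n_mirnas", "n_genes", "n_replicates", "n_true_pairs")
  for (nm in counts) {
    if (!is.numeric(d[[nm]]) || d[[nm]] < 1) {
      stop_input(nm, " must be a positive count")
    }
  }
  if (d$n_decoy_edges < 0) stop_input("n_decoy_edges must be >= 0")
  if (d$n_true_pairs > min(d$n_mirnas, d$n_genes)) {
    stop_input("n_true_pairs must be <= min(n_mirnas, n_genes)")
  }
  if (d$effect_log2fc < 1) {
    stop_input("effect_log2fc must be >= 1 so planted pairs clear the ",
               "2-fold filter in expectation")
  }
  if (d$noise_sd < 0) stop_input("noise_sd must be >= 0")
  if (d$background_de_rate < 0 || d$background_de_rate > 1) {
    stop_input("background_de_rate must be in [0, 1]")
  }
  if (!length(d$clones) || anyDuplicated(c(d$clones, "parental"))) {
    stop_input("clones must be non-empty, distinct, and not 'parental'")
  }
  structure(d, class = "simulation_design")
}

sim_feature_ids <- function(design) {
  list(mirnas = sprintf("hsa-miR-%04d-5p", seq_len(design$n_mirnas)),
       genes = sprintf("GENE%04d", seq_len(design$n_genes)))
}

#' Simulate a planted-signal miRNA/gene expression experiment
#'
#' Intensities are generated on the log2 scale (baseline per feature, group
#' effect, replicate Gaussian noise) then exponentiated, so linear-scale
#' intensities are log-normal and planted effects are additive in log2.
#' Deterministic under a fixed `design$seed`.
#'
#' @param design a [simulation_design()].
#' @return list with `mirnas` and `genes` ([expression_matrix()]s),
#'   `reference` (a [reference_network()] of true pairs plus decoys) and
#'   `truth` (a `planted_truth` data frame: `mirna`, `mirna_dir`, `gene`,
#'   `gene_dir` — the directions applied in every resistant clone).
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  ids <- sim_feature_ids(design)
  np <- design$n_true_pairs

  # planted pairs: first np miRNAs paired 1:1 with np sampled genes
  pair_mirnas <- ids$mirnas[seq_len(np)]
  pair_genes <- sample(ids$genes, np)
  mirna_dir <- sample(c("up", "down"), np, replace = TRUE)
  gene_dir <- ifelse(mirna_dir == "up", "down", "up")
  truth <- data.frame(mirna = pair_mirnas, mirna_dir = mirna_dir,
                      gene = pair_genes, gene_dir = gene_dir,
                      stringsAsFactors = FALSE)
  class(truth) <- c("planted_truth", "data.frame")

  # decoy edges: any miRNA x gene pair except (planted miRNA, planted gene)
  free_m <- setdiff(ids$mirnas, pair_mirnas)
  free_g <- setdiff(ids$genes, pair_genes)
  decoys <- unique(rbind(
    data.frame(mirna = sample(free_m, design$n_decoy_edges, replace = TRUE),
               gene = sample(ids$genes, design$n_decoy_edges, replace = TRUE),
               stringsAsFactors = FALSE),
    data.frame(mirna = sample(ids$mirnas, design$n_decoy_edges, replace = TRUE),
               gene = sample(free_g, design$n_decoy_edges, replace = TRUE),
               stringsAsFactors = FALSE)))
  decoys <- decoys[sample(nrow(decoys)), , drop = FALSE]
  decoys <- utils::head(decoys, design$n_decoy_edges)
  ref <- reference_network(c(truth$mirna, decoys$mirna),
                           c(truth$gene, decoys$gene),
                           provenance = "simulated")

  sgn <- function(dir) ifelse(dir == "up", 1, -1)
  build <- function(feat_ids, planted_ids, planted_dir) {
    nf <- length(feat_ids)
    baseline <- stats::rnorm(nf, design$baseline_log2_mean,
                             design$baseline_log2_sd)
    effect <- stats::setNames(rep(0, nf), feat_ids)
    effect[planted_ids] <- sgn(planted_dir) * design$effect_log2fc
    cols <- list()
    for (cl in design$cell_lines) {
      for (grp in c("parental", design$clones)) {
        shift <- if (grp == "parental") rep(0, nf) else {
          bg <- !(feat_ids %in% planted_ids) &
            stats::runif(nf) < design$background_de_rate
          e <- effect
          e[bg] <- sample(c(-1, 1), sum(bg), replace = TRUE) *
            design$effect_log2fc
          e
        }
        for (r in seq_len(design$n_replicates)) {
          noise <- if (design$noise_sd > 0) {
            stats::rnorm(nf, 0, design$noise_sd)
          } else rep(0, nf)
          cols[[paste(cl, grp, r, sep = "_")]] <- baseline + shift + noise
        }
      }
    }
    v <- 2^do.call(cbind, cols)
    rownames(v) <- feat_ids
    v
  }
  mir_m <- expression_matrix(build(ids$mirnas, truth$mirna, truth$mirna_dir),
                             "miRNA")
  gene_ann <- data.frame(feature_id = ids$genes, category = "coding",
                         stringsAsFactors = FALSE)
  gene_m <- expression_matrix(build(ids$genes, truth$gene, truth$gene_dir),
                              "gene", annotation = gene_ann)
  list(mirnas = mir_m, genes = gene_m, reference = ref, truth = truth)
}

#' Simulate a 4PL dose-response viability curve
#'
#' Viabilities are drawn from [four_pl()] plus Gaussian noise; deterministic
#' under a fixed seed. Default doses follow a typical MTT titration
#' (1.25-40 µM).
#'
#' @param ic50 midpoint concentration, µM.
#' @param hill slope (> 0 for falling viability).
#' @param top,bottom asymptotic viabilities (%); `top > bottom` required.
#' @param doses positive dose vector, µM.
#' @param n_replicates replicates per dose.
#' @param noise_sd Gaussian noise SD in viability percent.
#' @param seed RNG seed.
#' @param sample label.
#' @return a [dose_response()].
#' @export
simulate_dose_response <- function(ic50, hill = 1, top = 100, bottom = 0,
                                   doses = c(1.25, 2.5, 5, 7.5, 10, 15, 20,
                                             30, 40),
                                   n_replicates = 3, noise_sd = 0,
                                   seed = 1L, sample = "sim") {
  if (any(doses <= 0)) stop_input("doses must be positive")
  if (top <= bottom) stop_input("top must exceed bottom")
  set.seed(as.integer(seed))
  dose <- rep(doses, each = n_replicates)
  mu <- four_pl(dose, ic50, hill, top, bottom)
  v <- mu + if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
  dose_response(dose, v, sample = sample)
}

#' Write all simulated fixtures to a directory
#'
#' Emits the expression TSVs (plus the gene annotation sidecar), the
#' reference-network TSV and the planted-truth TSV.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mirnas = file.path(dir, "mirna_expression.tsv"),
             genes = file.path(dir, "gene_expression.tsv"),
             gene_annotation = file.path(dir, "gene_annotation.tsv"),
             reference = file.path(dir, "reference_network.tsv"),
             truth = file.path(dir, "planted_truth.tsv"))
  write_expression(sim$mirnas, paths["mirnas"])
  write_expression(sim$genes, paths["genes"],
                   annotation_path = paths["gene_annotation"])
  utils::write.table(as.data.frame(sim$reference), paths["reference"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$truth), paths["truth"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
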