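# Independent oracles, deliberately naive; they never call package internals.

# Benjamini-Hochberg by the literal step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws
hyper_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # successes are items 1..K
  mean(hits >= k)
}

# closed-form Welch two-sample t-test (two-sided)
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# closed-form pooled (Student) two-sample t-test (two-sided)
student_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(t), nx + ny - 2)
}

# exhaustive nearest-pair average-linkage (UPGMA) agglomeration; returns the
# cophenetic distance matrix, which is invariant to merge bookkeeping
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bestd; coph[b, a] <- bestd
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# random directed-annotation inputs for network property tests
random_network_instance <- function(n_mirnas = 8, n_genes = 10,
                                    n_edges = 20) {
  mir <- paste0("m", seq_len(n_mirnas))
  gen <- paste0("g", seq_len(n_genes))
  net <- reference_network(sample(mir, n_edges, replace = TRUE),
                           sample(gen, n_edges, replace = TRUE))
  rand_set <- function(ids, clone) {
    picked <- ids[runif(length(ids)) < 0.6]
    dirs <- sample(c("up", "down"), length(picked), replace = TRUE)
    make_de_set(picked[dirs == "up"], picked[dirs == "down"], "SIM", clone)
  }
  list(net = net,
       m1 = rand_set(mir, "c1"), g1 = rand_set(gen, "c1"),
       m2 = rand_set(mir, "c2"), g2 = rand_set(gen, "c2"))
}

default_pipeline_run <- function(seed, noise_sd = NULL) {
  args <- list(seed = seed)
  if (!is.null(noise_sd)) args$noise_sd <- noise_sd
  sim <- simulate_experiment(do.call(simulation_design, args))
  td <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_simulation(sim, td)
  cfg <- pipeline_config(list(
    mirna_expression = unname(paths[["mirnas"]]),
    gene_expression = unname(paths[["genes"]]),
    gene_annotation = unname(paths[["gene_annotation"]]),
    reference_network = unname(paths[["reference"]]),
    out_dir = file.path(td, "out"), seed = seed))
  list(sim = sim, report = run_pipeline(cfg), dir = td)
}

# comparable numeric view of a run report
report_counts_view <- function(rep) {
  list(de = lapply(rep$de_sets, function(s)
         c(length(s$mirna$up), length(s$mirna$down),
           length(s$gene$up), length(s$gene$down))),
       venn = lapply(rep$venn, unclass),
       common = unclass(rep$network_summary)[
         c("n_interactions", "n_up_mirnas", "n_down_mirnas")])
}
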