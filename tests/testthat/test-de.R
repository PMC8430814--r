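de_toy <- function(parental, clone, extra = NULL) {
  # one feature of interest plus optional filler rows, 3 vs 3 replicates
  rows <- rbind(feat = c(parental, clone), extra)
  colnames(rows) <- c(paste0("L_parental_", 1:3), paste0("L_c1_", 1:3))
  expression_matrix(2^rows, "miRNA")
}

test_that("Welch p-values match the closed-form oracle on fixed values", {
  parental <- c(7.1, 7.9, 7.4); clone <- c(9.6, 9.1, 10.2)
  m <- de_toy(parental, clone)
  de <- differential_expression(m, "c1")
  expect_equal(de$p_value, welch_oracle(clone, parental), tolerance = 1e-12)
  expect_equal(de$log2fc, mean(clone) - mean(parental))
  # heteroscedastic case too
  p2 <- c(5, 5.05, 4.95); c2 <- c(8, 10, 6)
  de2 <- differential_expression(de_toy(p2, c2), "c1")
  expect_equal(de2$p_value, welch_oracle(c2, p2), tolerance = 1e-12)
})

test_that("identical groups are unchanged; signed fold change obeys its convention", {
  m <- de_toy(c(8, 8.5, 9), c(8, 8.5, 9),
              extra = matrix(c(4, 4, 4, 6, 6, 6), 1))
  de <- differential_expression(m, "c1")
  expect_equal(de$log2fc[1], 0)
  expect_equal(de$direction[1], "unchanged")
  # filler row: log2fc = +2 exactly, noiseless -> p = 0 -> up
  expect_equal(de$fold_change[2], 4)
  expect_equal(de$direction[2], "up")
  # sign convention: FC = -2^(-log2fc) for negative log2fc
  m2 <- de_toy(c(6, 6, 6), c(4.5, 4.5, 4.5))
  de2 <- differential_expression(m2, "c1")
  expect_equal(de2$fold_change, -2^1.5)
  expect_equal(sign(de2$fold_change), sign(de2$log2fc + .Machine$double.eps))
  expect_equal(abs(de2$fold_change), 2^abs(de2$log2fc))
})

test_that("insufficient replication is an error", {
  v <- matrix(2^c(8, 9, 8, 9), 2,
              dimnames = list(c("a", "b"), c("L_parental_1", "L_c1_1")))
  m <- expression_matrix(v, "miRNA")
  expect_error(differential_expression(m, "c1"), "replicates")
})

test_that("BH adjustment equals the hand step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.7), 0.7)                  # single p unchanged
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))  # symmetry
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
    # permutation invariance up to re-ordering, and adj >= raw
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
    expect_true(all(bh_adjust(p) >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("noiseless planted data is recovered exactly at default thresholds", {
  d <- simulation_design(n_mirnas = 40, n_genes = 50, n_true_pairs = 15,
                         n_decoy_edges = 30, noise_sd = 0,
                         background_de_rate = 0, seed = 8)
  sim <- simulate_experiment(d)
  for (cl in c("c1", "c2")) {
    s <- de_set(differential_expression(sim$mirnas, cl))
    expect_setequal(c(s$up, s$down), sim$truth$mirna)
    expect_setequal(s$up, sim$truth$mirna[sim$truth$mirna_dir == "up"])
    g <- de_set(differential_expression(sim$genes, cl))
    expect_setequal(c(g$up, g$down), sim$truth$gene)
  }
})

test_that("de_set splits directions disjointly and respects thresholds", {
  sim <- simulate_experiment(simulation_design(seed = 4))
  de <- differential_expression(sim$genes, "c1")
  s <- de_set(de)
  expect_length(intersect(s$up, s$down), 0)
  called <- de[de$direction != "unchanged", ]
  expect_true(all(abs(called$fold_change) >= 2))
  expect_true(all(called$adj_p < 0.05))
  expect_true(all(de$adj_p >= de$p_value))
})
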