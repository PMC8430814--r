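write_net_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("reference network parsing dedupes, trims, and enforces bipartiteness", {
  f <- write_net_tsv(c("mirna\tgene", "hsa-miR-1\tTP53", "hsa-miR-1\tTP53",
                       " HSA-miR-2 \tMYC"))
  net <- read_reference_network(f)
  expect_equal(nrow(net), 2)
  expect_true("hsa-miR-2" %in% net$mirna)  # species prefix case-normalised
  f2 <- write_net_tsv(c("hsa-miR-1\tTP53", "TP53\tMYC"))
  expect_error(read_reference_network(f2), "bipartite")
  f3 <- write_net_tsv(character())
  expect_error(read_reference_network(f3), "empty")
})

test_that("clone networks retain exactly the inverse-correlated reference edges", {
  net <- reference_network(c("m1", "m2", "m3", "m4"),
                           c("g1", "g2", "g3", "g4"))
  mde <- make_de_set(up = c("m2"), down = c("m1", "m3"), "L", "c1")
  gde <- make_de_set(up = c("g1", "g5"), down = c("g2", "g3"), "L", "c1")
  cn <- clone_network(net, mde, gde)
  # m1(down)-g1(up) kept; m2(up)-g2(down) kept; m3(down)-g3(down) same-dir
  # excluded; m4 not DE excluded; (m3,g5) not a reference edge
  expect_equal(nrow(cn), 2)
  expect_setequal(paste(cn$mirna, cn$mirna_dir, cn$gene, cn$gene_dir),
                  c("m1 down g1 up", "m2 up g2 down"))
  expect_true(all(cn$mirna_dir != cn$gene_dir))
})

test_that("clone intersection requires identical direction annotations", {
  a <- common_network("m1", "down", "g1", "up")
  b <- common_network("m1", "up", "g1", "down")
  expect_equal(nrow(intersect_clones(a, b)), 0)   # flipped pattern drops out
  expect_equal(nrow(intersect_clones(a, a)), 1)   # idempotent
})

test_that("intersection is commutative/idempotent and nested in its inputs", {
  set.seed(21)
  for (i in 1:1000) {
    inst <- random_network_instance()
    cn1 <- clone_network(inst$net, inst$m1, inst$g1)
    cn2 <- clone_network(inst$net, inst$m2, inst$g2)
    common <- intersect_clones(cn1, cn2)
    key <- function(x) paste(x$mirna, x$mirna_dir, x$gene, x$gene_dir)
    ekey <- function(x) paste(x$mirna, x$gene)
    # CommonNetwork <= each CloneNetwork <= ReferenceNetwork
    expect_true(all(key(common) %in% key(cn1)))
    expect_true(all(key(common) %in% key(cn2)))
    expect_true(all(ekey(cn1) %in% ekey(inst$net)))
    expect_true(all(ekey(cn2) %in% ekey(inst$net)))
    # no same-direction edge anywhere
    expect_true(all(c(cn1$mirna_dir != cn1$gene_dir,
                      cn2$mirna_dir != cn2$gene_dir,
                      common$mirna_dir != common$gene_dir)))
    # commutative
    expect_setequal(key(common), key(intersect_clones(cn2, cn1)))
    # idempotent
    expect_setequal(key(intersect_clones(common, common)), key(common))
  }
})

test_that("mapping stats count unique node identities", {
  net <- reference_network(c("m1", "m2"), c("g1", "g2"))
  mde <- make_de_set("m1", "m3", "L", "c1")
  gde <- make_de_set(c("g1", "g2"), "g9", "L", "c1")
  ms <- map_de_features(net, mde, gde)
  expect_equal(ms$n_de_features, 5)
  expect_equal(ms$n_mapped, 3)
  expect_equal(ms$pct_mapped, 60)
  empty <- map_de_features(net, make_de_set(character(), character()),
                           make_de_set(character(), character()))
  expect_equal(empty$n_mapped, 0)
  expect_true(empty$undefined)
  expect_equal(empty$pct_mapped, 0)
})

test_that("network summaries report counts and most-targeted genes with ties", {
  cn <- common_network(c("m1", "m2", "m3", "m4"),
                       c("down", "down", "up", "down"),
                       c("gA", "gA", "gB", "gB"),
                       c("up", "up", "down", "up"))
  s <- summarize_network(cn)
  expect_equal(s$n_interactions, 4)
  expect_equal(s$n_down_mirnas, 3)
  expect_equal(s$n_up_mirnas, 1)
  expect_equal(s$n_genes_targeted_by_down, 2)
  expect_equal(s$most_targeted_genes, c("gA", "gB"))  # tie, lexicographic
  empty <- summarize_network(common_network(character(), character(),
                                            character(), character()))
  expect_equal(empty$n_interactions, 0)
  expect_length(empty$most_targeted_genes, 0)
})

test_that("network exports round-trip (TSV) and encode directions (SIF/GraphML)", {
  cn <- common_network(c("m1", "m2"), c("down", "up"), c("g1", "g2"),
                       c("up", "down"))
  td <- withr::local_tempdir()
  tsv <- file.path(td, "net.tsv")
  export_network(cn, tsv, "tsv")
  back <- read_network_edges(tsv)
  expect_equal(as.data.frame(back), as.data.frame(cn))
  sif <- file.path(td, "net.sif")
  export_network(cn, sif, "sif")
  expect_equal(readLines(sif), c("m1\tdown_up\tg1", "m2\tup_down\tg2"))
  gml <- file.path(td, "net.graphml")
  export_network(cn, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::edge_attr(g, "relation"), c("down_up", "up_down"))
  # empty network -> header-only TSV
  empty <- common_network(character(), character(), character(), character())
  export_network(empty, tsv, "tsv")
  expect_equal(length(readLines(tsv)), 1)
  expect_error(export_network(cn, tsv, "xlsx"), "format")
})

test_that("the published 786-O network has 77 printed interactions", {
  cn <- published_common_network("786-O")
  td <- withr::local_tempdir()
  sif <- file.path(td, "net.sif")
  export_network(cn, sif, "sif")
  expect_length(readLines(sif), 77)
})
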