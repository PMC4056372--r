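test_that("a single reference coloring everything has proportion 1", {
  s <- random_seq(400, seed = 101)
  g <- build_graph(c(s, s, s), k = 31)  # uniform coverage 3
  invisible(color_graph(g, c(only = s), "ns"))
  pr <- reference_proportions(g, "ns")
  expect_equal(pr$proportion, 1)
  expect_equal(pr$mode_unique, 3)
  expect_equal(pr$observations, 370 * 3)
})

test_that("two disjoint references split proportions by the closed form", {
  # N1 = 20 k-mers at coverage 3, N2 = 10 k-mers at coverage 4
  s1 <- random_seq(50, seed = 102)  # 20 k-mers at k = 31
  s2 <- random_seq(40, seed = 103)  # 10 k-mers
  g <- build_graph(c(rep(s1, 3), rep(s2, 4)), k = 31)
  invisible(color_graph(g, c(r1 = s1, r2 = s2), "ns"))
  pr <- reference_proportions(g, "ns")
  expect_equal(nrow(pr), 2L)
  n1c1 <- 20 * 3; n2c2 <- 10 * 4
  expect_equal(pr$observations, c(n1c1, n2c2))
  expect_equal(pr$proportion, c(n1c1, n2c2) / (n1c1 + n2c2))
  # brute-force oracle over the serialized graph
  flat <- graph_flat(g)
  colored <- flat[flat$colors != "", ]
  expect_equal(sum(colored$coverage), n1c1 + n2c2)
})

test_that("a duplicated reference is flagged with zero proportion", {
  s <- random_seq(300, seed = 104)
  t2 <- random_seq(300, seed = 105)
  g <- build_graph(c(s, s, t2, t2), k = 31)
  invisible(color_graph(g, c(dup1 = s, dup2 = s, solo = t2), "ns"))
  pr <- reference_proportions(g, "ns")
  expect_equal(pr$proportion[pr$reference == "dup1"], 0)
  expect_equal(pr$proportion[pr$reference == "dup2"], 0)
  expect_true(all(pr$no_unique_kmers[pr$reference != "solo"]))
  expect_false(pr$no_unique_kmers[pr$reference == "solo"])
  expect_gt(pr$proportion[pr$reference == "solo"], 0)
})

test_that("an uncolored namespace warns and returns an empty table", {
  g <- build_graph(random_seq(100, seed = 106), k = 31)
  invisible(color_graph(g, c(x = random_seq(100, seed = 107)), "ns"))
  expect_warning(pr <- reference_proportions(g, "ns"), "no colored")
  expect_equal(nrow(pr), 0L)
})

test_that("lca_assign handles single colors, siblings and distant kingdoms", {
  nodes <- tibble::tibble(
    node_id = 1:8,
    parent_id = c(NA, 1L, 1L, 2L, 2L, 3L, 4L, 4L),
    rank = c("root", "kingdom", "kingdom", "genus", "genus", "species",
             "species", "species"),
    name = c("root", "k1", "k2", "g1", "g2", "s_k2", "s1", "s2"))
  tax <- taxonomy(nodes)
  expect_equal(lca_assign(7L, tax), 7L)          # single species -> itself
  expect_equal(lca_assign(c(7L, 8L), tax), 4L)   # siblings -> their genus
  expect_equal(lca_assign(c(7L, 6L), tax), 1L)   # across kingdoms -> root
  expect_error(lca_assign(99L, tax), "unknown")
})

test_that("lca_assign matches the brute-force root-path oracle", {
  tax <- rand_taxonomy(30, seed = 108)
  ids <- tax$nodes$node_id
  set.seed(109)
  for (i in 1:200) {
    pick <- sample(ids, sample(1:5, 1))
    expect_identical(lca_assign(pick, tax, color_nodes = setNames(ids, ids)),
                     lca_oracle(tax, pick))
  }
})

test_that("taxonomic profile assigns shared coverage to the LCA with exact sums", {
  # 10 k-mers coverage 2 unique to species A; 5 k-mers coverage 4 shared
  # by sibling species A and B under genus G
  sa <- random_seq(40, seed = 110)  # 10 k-mers
  sh <- random_seq(35, seed = 111)  # 5 k-mers
  g <- build_graph(c(rep(sa, 2), rep(sh, 4)), k = 31)
  nodes <- tibble::tibble(
    node_id = 1:4, parent_id = c(NA, 1L, 2L, 2L),
    rank = c("root", "genus", "species", "species"),
    name = c("root", "G", "A", "B"))
  cm <- tibble::tibble(reference = c("A", "B"), node_id = c(3L, 4L))
  tax <- taxonomy(nodes, cm)
  invisible(color_graph(g, c(A = paste0(sa, sh), B = sh), "ns"))
  # junction k-mers of A's concatenation don't exist in the graph
  tp <- taxonomic_profile(g, tax, "ns")
  nd <- tp$nodes
  expect_equal(nd$direct_obs[nd$name == "A"], 20)   # 10 x 2
  expect_equal(nd$direct_obs[nd$name == "G"], 20)   # 5 x 4 at the LCA
  expect_equal(nd$direct_obs[nd$name == "B"], 0)
  expect_equal(nd$subtree_obs[nd$name == "G"], 40)
  expect_equal(tp$total_observations, 40)
  sp <- tp$ranks[tp$ranks$rank == "species", ]
  expect_equal(sp$observations[sp$name == "unclassified"], 20)
  # conservation is exact
  expect_equal(sum(nd$direct_obs), tp$total_observations)
})

test_that("rank rollups are monotone and conserve totals on simulated data", {
  sim <- small_sim()
  g <- build_graph(sim$reads, k = 31)
  comm <- sim$genomes[sim$genomes$role == "community", ]
  invisible(color_graph(g, comm, "genomes"))
  tp <- taxonomic_profile(g, sim$references$taxonomy, "genomes")
  expect_equal(sum(tp$nodes$direct_obs), tp$total_observations)
  # every rank's node total plus its unclassified bucket equals the total
  for (r in unique(tp$ranks$rank)) {
    expect_equal(sum(tp$ranks$observations[tp$ranks$rank == r]),
                 tp$total_observations)
  }
  # subtree observations never grow when descending
  par <- tp$nodes$parent_id
  sub <- setNames(tp$nodes$subtree_obs, tp$nodes$node_id)
  kids <- !is.na(par)
  expect_true(all(sub[as.character(par[kids])] >= sub[as.character(tp$nodes$node_id[kids])]))
  expect_s3_class(autoplot(tp, rank = "genus"), "ggplot")
  expect_equal(glance(tp)$total_observations, tp$total_observations)
})

test_that("ontology terms are credited once per vertex and unannotated is kept", {
  s <- random_seq(130, seed = 112)  # 100 k-mers
  g <- build_graph(c(s, s), k = 31)  # coverage 2
  # two CDS with identical sequence -> every vertex carries both colors
  invisible(color_graph(g, c(cds1 = s, cds2 = s), "cds"))
  shared_term <- tibble::tibble(
    cds = c("cds1", "cds2"), go_id = "GO:0000001",
    domain = "biological_process")
  prof <- ontology_profile(g, shared_term, "cds")
  # the shared term is counted once per vertex: 100 k-mers x coverage 2
  expect_equal(prof$observations[prof$go_id == "GO:0000001"], 200)
  # distinct terms on the same vertex are each credited
  two_terms <- tibble::tibble(
    cds = c("cds1", "cds2"), go_id = c("GO:0000001", "GO:0000002"),
    domain = c("biological_process", "molecular_function"))
  prof2 <- ontology_profile(g, two_terms, "cds")
  expect_equal(prof2$observations[prof2$go_id == "GO:0000001"], 200)
  expect_equal(prof2$observations[prof2$go_id == "GO:0000002"], 200)
  # a CDS with no mapping at all lands in the unannotated row
  prof3 <- ontology_profile(g, two_terms[0, ], "cds")
  expect_equal(prof3$go_id, "unannotated")
  expect_equal(prof3$observations, 200)
})

test_that("greengenes-style lineages build a consistent taxonomy", {
  lin <- c(
    a = "k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Fam;g__Gen;s__a",
    b = "k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Fam;g__Gen;s__b",
    c = "k__Bacteria;p__Bacteroidetes;c__;o__;f__;g__;s__")
  tax <- taxonomy_from_lineages(lin)
  cm <- setNames(tax$color_map$node_id, tax$color_map$reference)
  # a and b are sibling species under one genus
  expect_equal(lca_assign(c("a", "b"), tax),
               tax$nodes$node_id[tax$nodes$name == "Gen"])
  # c's lineage stops at its phylum
  expect_equal(tax$nodes$rank[tax$nodes$node_id == cm[["c"]]], "phylum")
  expect_equal(lca_assign(c("a", "c"), tax),
               tax$nodes$node_id[tax$nodes$name == "Bacteria"])
  # round trip through TSV
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, p1, p2)
  back <- read_taxonomy(p1, p2)
  expect_equal(back$nodes, tax$nodes)
  expect_equal(back$depth, tax$depth)
})
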