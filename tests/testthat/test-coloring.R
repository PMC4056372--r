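test_that("coloring marks only pre-existing vertices and reports matches", {
  sim <- small_sim()
  g <- build_graph(sim$reads, k = 31)
  before <- graph_stats(g)
  comm <- sim$genomes[sim$genomes$role == "community", ]
  rep <- color_graph(g, comm, namespace = "genomes")
  after <- graph_stats(g)
  # topology and coverage untouched
  expect_identical(before$n_vertices, after$n_vertices)
  expect_identical(before$coverage_sum, after$coverage_sum)
  # at ~17-30x with 0.25% errors, essentially every reference k-mer is
  # in the graph
  expect_true(all(rep$fraction_matched > 0.995))
  # with error-free reads tiling every position the match is exact
  g1 <- random_seq(3000, seed = 881)
  g2 <- random_seq(3000, seed = 882)
  reads0 <- c(tile_reads(g1, 80L, 20L), tile_reads(g2, 80L, 20L))
  reads0 <- c(reads0, rep(c(substr(g1, 2921, 3000), substr(g2, 2921, 3000)), 2))
  g0 <- build_graph(c(reads0, reads0), k = 31)
  rep0 <- color_graph(g0, c(g1 = g1, g2 = g2), "exact")
  expect_true(all(rep0$fraction_matched == 1))
  # a foreign reference matches nothing
  rep2 <- color_graph(g, c(alien = random_seq(5000, seed = 99)), "genomes")
  expect_equal(rep2$matched_kmers, 0)
})

test_that("references shorter than k match zero k-mers with a warning", {
  g <- build_graph(c("AATGCAATG"), k = 5)
  expect_warning(rep <- color_graph(g, c(tiny = "ACG"), "ns"), "shorter than k")
  expect_equal(rep$matched_kmers, 0)
  expect_equal(rep$total_kmers, 0)
})

test_that("a sequence registered twice leaves no uniquely colored k-mers", {
  s <- random_seq(400, seed = 81)
  g <- build_graph(c(s, s), k = 31)
  invisible(color_graph(g, c(a = s, b = s), "dup"))
  cls <- color_class(g, substr(s, 1, 31), "dup")
  expect_equal(cls$class, "shared")
  pr <- reference_proportions(g, "dup")
  expect_true(all(pr$no_unique_kmers))
  expect_true(all(pr$proportion == 0))
})

test_that("color classes distinguish uncolored, unique and shared", {
  s1 <- random_seq(100, seed = 82)
  s2 <- random_seq(100, seed = 83)
  s3 <- random_seq(100, seed = 84)
  g <- build_graph(c(s1, s2, s3), k = 31)
  invisible(color_graph(g, c(r1 = s1, r2 = s2, both = paste0(s1, s2)), "ns"))
  expect_equal(color_class(g, substr(s1, 1, 31), "ns")$class, "shared")
  expect_equal(color_class(g, substr(s2, 11, 41), "ns")$class, "shared")
  expect_equal(color_class(g, substr(s3, 1, 31), "ns")$class, "uncolored")
  # a k-mer only in r1's private... all of s1 is shared with "both"; the
  # junction k-mers of "both" exist nowhere in the graph, so "both" also
  # has no private vertex. Add a namespace where s3 is unique:
  invisible(color_graph(g, c(r3 = s3), "other"))
  expect_equal(color_class(g, substr(s3, 1, 31), "other")$class, "unique")
  expect_error(color_class(g, substr(s1, 1, 31), "nope"), "namespace")
})

test_that("uniqueness is evaluated per namespace independently", {
  s <- random_seq(200, seed = 85)
  g <- build_graph(c(s, s), k = 31)
  invisible(color_graph(g, c(x = s), "ns1"))
  invisible(color_graph(g, c(y = s, z = s), "ns2"))
  km <- substr(s, 1, 31)
  expect_equal(color_class(g, km, "ns1")$class, "unique")
  expect_equal(color_class(g, km, "ns2")$class, "shared")
})

test_that("coloring twice with the same reference set changes nothing", {
  sim <- small_sim()
  g <- build_graph(sim$reads[1:1000, ], k = 31)
  comm <- sim$genomes[sim$genomes$role == "community", ]
  invisible(color_graph(g, comm, "genomes"))
  pr1 <- reference_proportions(g, "genomes")
  flat1 <- graph_flat(g)
  invisible(color_graph(g, comm, "genomes"))
  expect_identical(reference_proportions(g, "genomes"), pr1)
  expect_identical(graph_flat(g), flat1)
})

test_that("assembly output is byte-identical with or without coloring", {
  sim <- small_sim()
  reads <- sim$reads[1:3000, ]
  plain <- assemble(reads, k = 31)
  g <- build_graph(reads, k = 31)
  invisible(color_graph(g, sim$genomes[sim$genomes$role == "community", ],
                        "genomes"))
  colored <- assemble(reads, k = 31, graph = g)
  expect_identical(plain$contigs, colored$contigs)
  expect_identical(plain$scaffolds$sequence, colored$scaffolds$sequence)
})

test_that("color sets are interned across vertices", {
  s1 <- random_seq(300, seed = 86)
  s2 <- random_seq(300, seed = 87)
  g <- build_graph(c(s1, s2), k = 31)
  invisible(color_graph(g, c(a = s1, b = s1, c = s2), "ns"))
  # distinct combinations encountered: {}, {a}, {a,b} growth path, {c}
  # (plus transient {a} during set growth); far fewer than vertices
  expect_lte(metacolor:::cpp_dbg_n_color_sets(g$ptr), 4L)
})

test_that("assembly overlap counts shared nucleotides per direction", {
  a <- vapply(81:84, function(s) random_seq(700, seed = s), character(1))
  # identical assemblies share everything
  ov <- assembly_overlap(a, a, k = 31, min_len = 500)
  expect_equal(ov$shared_nt, ov$total_nt)
  expect_equal(ov$total_nt, rep(2800, 2))
  # disjoint random sequences share nothing at k = 31
  b <- vapply(91:94, function(s) random_seq(700, seed = s), character(1))
  ov2 <- assembly_overlap(a, b, k = 31)
  expect_equal(ov2$shared_nt, c(0, 0))
  # short sequences fall under the length floor
  ov3 <- assembly_overlap(c(a, random_seq(120, seed = 1)), a, min_len = 500)
  expect_equal(ov3$total_nt[1], 2800)
})

test_that("a single substitution removes at most 2k-1 shared bases", {
  k <- 31L
  a <- random_seq(700, seed = 95)
  b <- a
  substr(b, 350, 350) <- if (substr(a, 350, 350) == "A") "C" else "A"
  ov <- assembly_overlap(a, b, k = k)
  lost <- ov$total_nt[1] - ov$shared_nt[1]
  expect_gt(lost, 0)
  expect_lte(lost, 2 * k - 1)
  # brute-force oracle: a base of `a` is shared iff one of its windows
  # occurs in b on either strand
  b_windows <- extract_kmers(b, k)$kmer
  aw <- extract_kmers(a, k)
  hit <- aw$offset[aw$kmer %in% b_windows]
  covered <- unique(unlist(lapply(hit, function(o) o + seq_len(k))))
  expect_equal(ov$shared_nt[1], length(covered))
})
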