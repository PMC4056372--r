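test_that("a clean linear sequence yields exactly one full-length seed", {
  s <- random_seq(300, seed = 11)
  g <- build_graph(c(s, s), k = 31)  # coverage 2 everywhere
  seeds <- find_seeds(g)
  expect_equal(nrow(seeds), 1L)
  expect_equal(seeds$length, 300L)
  expect_true(seeds$sequence %in% c(s, revcomp(s)))
})

test_that("a branch vertex splits seeds and low-coverage paths are absent", {
  x <- random_seq(80, seed = 12)
  za <- random_seq(80, seed = 13)
  zc <- random_seq(80, seed = 14)
  r1 <- paste0(x, "A", za)
  r2 <- paste0(x, "C", zc)
  g <- build_graph(c(r1, r1, r2, r2), k = 31)
  seeds <- find_seeds(g)
  expect_lte(nrow(seeds), 3L)
  expect_gte(nrow(seeds), 2L)
  # coverage-1 branches are not present: same reads once each
  g1 <- build_graph(c(r1, r2), k = 31)
  # only the shared prefix reaches coverage 2
  expect_equal(nrow(find_seeds(g1)), 1L)
  expect_equal(find_seeds(g1)$length, 80L)
})

test_that("empty graph gives no seeds", {
  g <- suppressMessages(build_graph(character(0), k = 31))
  expect_equal(nrow(find_seeds(g)), 0L)
})

test_that("seed-local coverage mode breaks ties toward the smaller value", {
  # S has 32 windows at k=31; an extra 46 nt prefix read lifts exactly the
  # first 16 windows to coverage 4, leaving a 16/16 tie between 3 and 4
  s <- random_seq(62, seed = 21)
  g <- build_graph(c(s, s, s, substr(s, 1, 46)), k = 31)
  st <- seed_local_coverage(g, s)
  expect_equal(sort(unique(st$coverages)), c(3L, 4L))
  expect_equal(sum(st$coverages == 3L), 16L)
  expect_equal(sum(st$coverages == 4L), 16L)
  expect_equal(st$mode, 3L)
  expect_equal(st$min, 3L)
  # no tie: mode is the majority value
  g2 <- build_graph(c(s, s, s, substr(s, 1, 47)), k = 31)
  st2 <- seed_local_coverage(g2, s)
  expect_equal(st2$mode, 4L)
  expect_equal(st2$min, 3L)
})

test_that("markers anchor at the first eligible read k-mer", {
  s <- random_seq(200, seed = 31)
  reads <- c(s, s)
  g <- build_graph(reads, k = 31)
  rs <- index_reads(c(substr(s, 41, 140), substr(s, 41, 140)), k = 31)
  mk <- select_read_markers(g, rs, s)
  expect_equal(nrow(mk), 2L)
  expect_equal(mk$read_offset, c(0L, 0L))
  expect_equal(mk$path_offset, c(40L, 40L))
  expect_equal(mk$strand, c("+", "+"))
  expect_equal(mk$proj_start, c(40, 40))
})

test_that("repeat k-mers above the coverage cutoff are skipped for anchoring", {
  s <- random_seq(200, seed = 32)
  first_kmer <- substr(s, 41, 71)         # first k-mer of the query read
  inflate <- rep(first_kmer, 30)          # drive it far beyond 3 x mode
  g <- build_graph(c(s, s, inflate), k = 31)
  st <- seed_local_coverage(g, s)
  expect_equal(st$mode, 2L)
  rs <- index_reads(c(substr(s, 41, 140), substr(s, 41, 140)), k = 31)
  mk <- select_read_markers(g, rs, s, stats = st)
  # the read's first k-mer has coverage 32 > 6, so the marker moves along
  expect_equal(nrow(mk), 2L)
  expect_equal(mk$read_offset, c(1L, 1L))
})

test_that("reads sharing no k-mer with the seed yield no marker", {
  s <- random_seq(150, seed = 33)
  g <- build_graph(c(s, s), k = 31)
  rs <- index_reads(rep(random_seq(100, seed = 34), 2), k = 31)
  expect_equal(nrow(select_read_markers(g, rs, s)), 0L)
})

test_that("marker votes resolve branches by the 2-vote 2x rule", {
  x <- random_seq(80, seed = 41)
  za <- random_seq(80, seed = 42)
  zc <- random_seq(80, seed = 43)
  ra <- paste0(x, "A", za)
  rc <- paste0(x, "C", zc)
  # 5 votes for the A branch vs 2 for the C branch: decisive (5 >= 2, 5 >= 4)
  reads <- c(rep(ra, 5), rep(rc, 2))
  g <- build_graph(reads, k = 31)
  rs <- index_reads(reads, k = 31, paired = FALSE)
  seeds <- find_seeds(g)
  seed <- seeds$sequence[seeds$sequence %in% c(x, revcomp(x))]
  ext <- extend_seed(g, rs, seed)
  want <- ra
  expect_true(ext$sequence %in% c(want, revcomp(want)))
  expect_setequal(c(ext$stop_left, ext$stop_right), "no-successor")
  # 2 vs 2: a tie is never decisive -> ambiguous stop at the branch
  reads2 <- c(rep(ra, 2), rep(rc, 2))
  g2 <- build_graph(reads2, k = 31)
  rs2 <- index_reads(reads2, k = 31, paired = FALSE)
  seeds2 <- find_seeds(g2)
  branch_seed <- seeds2$sequence[seeds2$sequence %in% c(x, revcomp(x))]
  expect_length(branch_seed, 1L)
  ext2 <- extend_seed(g2, rs2, branch_seed)
  expect_true("ambiguous" %in% c(ext2$stop_left, ext2$stop_right))
  # the x side of the contig stays unextended past the branch
  expect_equal(nchar(ext2$sequence), 80L)
})

test_that("a vote below the 2x runner-up margin is not decisive", {
  x <- random_seq(80, seed = 44)
  za <- random_seq(80, seed = 45)
  zc <- random_seq(80, seed = 46)
  ra <- paste0(x, "A", za)
  rc <- paste0(x, "C", zc)
  reads <- c(rep(ra, 3), rep(rc, 2))  # 3 vs 2: 3 < 2*2
  g <- build_graph(reads, k = 31)
  rs <- index_reads(reads, k = 31, paired = FALSE)
  seeds <- find_seeds(g)
  branch_seed <- seeds$sequence[seeds$sequence %in% c(x, revcomp(x))]
  ext <- extend_seed(g, rs, branch_seed)
  expect_true("ambiguous" %in% c(ext$stop_left, ext$stop_right))
})

test_that("extension reconstructs a repeat-free genome end to end", {
  genome <- random_seq(1000, seed = 51)
  starts <- rep(c(seq(1L, 938L, by = 3L), 941L), 2)  # tile to the last base
  reads <- substring(genome, starts, starts + 59L)
  g <- build_graph(reads, k = 31)
  rs <- index_reads(reads, k = 31, paired = FALSE)
  seed <- find_seeds(g)$sequence[1]
  ext <- extend_seed(g, rs, seed)
  expect_true(ext$sequence %in% c(genome, revcomp(genome)))
  expect_equal(ext$stop_left, "no-successor")
  expect_equal(ext$stop_right, "no-successor")
})

test_that("insert size is estimated from concordant seed pairs", {
  genome <- random_seq(2000, seed = 61)
  starts <- seq(1L, 1700L, by = 11L)
  r1 <- substring(genome, starts, starts + 99L)
  r2 <- revcomp(substring(genome, starts + 200L, starts + 299L))
  reads <- interleave(r1, r2)
  g <- build_graph(reads, k = 31)
  rs <- index_reads(reads, k = 31, paired = TRUE)
  seeds <- find_seeds(g)
  est <- estimate_insert_size(g, rs, seeds)
  expect_false(est$fallback)
  expect_equal(est$mean, 300)
  expect_equal(est$sd, 0)
  # too few pairs -> prior fallback with a warning
  few <- interleave(r1[1:5], r2[1:5])
  g2 <- build_graph(few, k = 31)
  rs2 <- index_reads(few, k = 31, paired = TRUE)
  expect_warning(est2 <- estimate_insert_size(g2, rs2, find_seeds(g2),
                                              prior = c(123, 7)),
                 "falling back")
  expect_true(est2$fallback)
  expect_equal(est2$mean, 123)
})

test_that("assemble handles degenerate input", {
  expect_warning(a <- assemble(c("ACGT", "GGG"), k = 31, paired = FALSE),
                 "empty|no seeds")
  expect_equal(nrow(a$contigs), 0L)
})

test_that("two k-mer-disjoint genomes assemble without chimeras", {
  cfg <- sim_config(n_genomes = 2, genome_length = 15000, alpha = 0,
                    error_rate = 0, contamination = 0, host_length = 0,
                    top_depth = 25, seed = 62)
  sim <- simulate_metagenome(cfg)
  asm <- assemble(sim$reads, k = 31)
  pl <- align_contigs(asm, sim$genomes)
  # every contig places on exactly one genome with near-total breadth
  per_contig <- split(pl, pl$contig)
  for (p in per_contig) {
    expect_equal(length(unique(p$reference)), 1L)
    expect_gte(max(p$breadth), 0.99)
  }
  mis <- classify_misassemblies(asm, sim$genomes)
  expect_equal(mis$n_misassembled, 0L)
})

test_that("assembly is deterministic and strand invariant", {
  sim <- small_sim()
  reads <- sim$reads[1:2000, ]
  a1 <- assemble(reads, k = 31)
  a2 <- assemble(reads, k = 31)
  expect_identical(a1$contigs, a2$contigs)
  arc <- assemble(revcomp(reads$sequence), k = 31)
  expect_identical(sort(a1$contigs$sequence), sort(arc$contigs$sequence))
})

test_that("contigs below the reporting floor are suppressed", {
  s <- random_seq(80, seed = 63)
  a <- assemble(c(s, s), k = 31, paired = FALSE, min_contig = 100L)
  expect_equal(nrow(a$contigs), 0L)
  a2 <- assemble(c(s, s), k = 31, paired = FALSE, min_contig = 50L)
  expect_equal(nrow(a2$contigs), 1L)
})

test_that("scaffolding links need 3 concordant pairs and fills the gap", {
  genome <- random_seq(3000, seed = 71)
  contig_a <- substr(genome, 1, 1200)
  contig_b <- substr(genome, 1401, 3000)
  contigs <- tibble::tibble(name = c("a", "b"),
                            sequence = c(contig_a, contig_b))
  mk_pairs <- function(starts) {
    r1 <- substring(genome, starts, starts + 99L)
    r2 <- revcomp(substring(genome, starts + 300L, starts + 399L))
    interleave(r1, r2)
  }
  ins <- list(mean = 400, sd = 20)
  # 3 pairs spanning the gap -> one scaffold with ~200 Ns
  rs3 <- index_reads(mk_pairs(c(1101L, 1102L, 1103L)), k = 31, paired = TRUE)
  sc3 <- scaffold_contigs(contigs, rs3, ins)
  expect_equal(nrow(sc3$scaffolds), 1L)
  expect_equal(sc3$scaffolds$n_contigs, 2L)
  n_gap <- nchar(sc3$scaffolds$sequence) - nchar(contig_a) - nchar(contig_b)
  expect_true(n_gap >= 190 && n_gap <= 210)
  expect_true(grepl("N", sc3$scaffolds$sequence, fixed = TRUE))
  # 2 pairs only -> below the link threshold, contigs pass through
  rs2 <- index_reads(mk_pairs(c(1101L, 1102L)), k = 31, paired = TRUE)
  sc2 <- scaffold_contigs(contigs, rs2, ins)
  expect_equal(nrow(sc2$scaffolds), 2L)
  expect_equal(sc2$scaffolds$n_contigs, c(1L, 1L))
})

test_that("contradictory links keep the higher-support one", {
  ga <- random_seq(1500, seed = 72)
  gb <- random_seq(1500, seed = 73)
  gc_ <- random_seq(1500, seed = 74)
  # two alternative genomes share the same left arm
  genome_ab <- paste0(substr(ga, 1, 1200), substr(gb, 1, 1200))
  genome_ac <- paste0(substr(ga, 1, 1200), substr(gc_, 1, 1200))
  contigs <- tibble::tibble(
    name = c("a", "b", "c"),
    sequence = c(substr(ga, 1, 1200), substr(gb, 101, 1200),
                 substr(gc_, 101, 1200)))
  mk <- function(genome, starts) {
    r1 <- substring(genome, starts, starts + 99L)
    r2 <- revcomp(substring(genome, starts + 300L, starts + 399L))
    interleave(r1, r2)
  }
  reads <- c(mk(genome_ab, c(1001L, 1002L, 1003L, 1004L)),
             mk(genome_ac, c(1001L, 1002L, 1003L)))
  rs <- index_reads(reads, k = 31, paired = TRUE)
  sc <- scaffold_contigs(contigs, rs, list(mean = 400, sd = 20))
  expect_equal(sum(!sc$links$kept), 1L)
  kept <- sc$links[sc$links$kept, ]
  expect_equal(kept$from, 1L)
  expect_equal(kept$to, 2L)  # the 4-pair link to b wins
  expect_equal(nrow(sc$scaffolds), 2L)
})

test_that("tidy and glance summarise an assembly", {
  sim <- small_sim()
  a <- assemble(sim$reads[1:1000, ], k = 31)
  expect_identical(tidy(a), a$contigs)
  gl <- glance(a)
  expect_equal(gl$count, nrow(a$contigs))
  expect_s3_class(autoplot(a), "ggplot")
})
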