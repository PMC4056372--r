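test_that("power-law proportions follow the closed form", {
  expect_equal(power_law_proportions(2, -1), c(2 / 3, 1 / 3))
  expect_equal(power_law_proportions(5, 0), rep(0.2, 5))
  expect_equal(power_law_proportions(1, -0.5), 1)
  expect_error(power_law_proportions(0, -0.5), "positive")
  p <- power_law_proportions(100, -0.5)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(diff(p) < 0))
  # the log-log slope is exactly the exponent
  fit <- stats::lm(log10(p) ~ log10(seq_along(p)))
  expect_equal(unname(stats::coef(fit)[2]), -0.5, tolerance = 1e-10)
})

test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_genomes = 2, genome_length = 5000, n_pairs = 300,
                    seed = 7)
  a <- simulate_metagenome(cfg)
  b <- simulate_metagenome(cfg)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  cfg2 <- sim_config(n_genomes = 2, genome_length = 5000, n_pairs = 300,
                     seed = 8)
  expect_false(identical(simulate_genomes(cfg2), a$genomes))
})

test_that("near-duplicate genomes diverge at the configured rate", {
  dup0 <- tibble::tibble(source = 1L, divergence = 0)
  cfg <- sim_config(n_genomes = 1, genome_length = 1e5, duplicates = dup0,
                    host_length = 0, n_pairs = 10L, seed = 9)
  gn <- simulate_genomes(cfg)
  expect_identical(gn$sequence[gn$role == "duplicate"],
                   gn$sequence[gn$role == "community"])
  dup2 <- tibble::tibble(source = 1L, divergence = 0.02)
  cfg2 <- sim_config(n_genomes = 1, genome_length = 1e5, duplicates = dup2,
                     host_length = 0, n_pairs = 10L, seed = 9)
  gn2 <- simulate_genomes(cfg2)
  d <- metacolor:::cpp_hamming(gn2$sequence[gn2$role == "community"],
                               gn2$sequence[gn2$role == "duplicate"])
  expect_gt(d / 1e5, 0.018)
  expect_lt(d / 1e5, 0.022)
})

test_that("error-free reads are exact substrings at their truth coordinates", {
  cfg <- sim_config(n_genomes = 2, genome_length = 8000, error_rate = 0,
                    contamination = 0, host_length = 0, n_pairs = 400,
                    seed = 10)
  sim <- simulate_metagenome(cfg)
  gs <- setNames(sim$genomes$sequence, sim$genomes$genome)
  rl <- cfg$read_length
  expected <- substring(gs[sim$truth$genome], sim$truth$start + 1,
                        sim$truth$start + rl)
  rev <- sim$truth$strand == "-"
  expected[rev] <- revcomp(expected[rev])
  expect_identical(sim$reads$sequence, unname(expected))
})

test_that("the empirical substitution rate matches the configured rate", {
  cfg <- sim_config(n_genomes = 1, genome_length = 5e4, error_rate = 0.0025,
                    contamination = 0, host_length = 0, n_pairs = 5000,
                    seed = 11)
  sim <- simulate_metagenome(cfg)
  gs <- sim$genomes$sequence[1]
  rl <- cfg$read_length
  expected <- substring(gs, sim$truth$start + 1, sim$truth$start + rl)
  rev <- sim$truth$strand == "-"
  expected[rev] <- revcomp(expected[rev])
  mism <- sum(metacolor:::cpp_hamming(sim$reads$sequence, expected))
  bases <- length(expected) * rl
  rate <- mism / bases
  sigma <- sqrt(0.0025 * 0.9975 / bases)
  expect_lt(abs(rate - 0.0025), 3 * sigma)
})

test_that("pair sampling follows the power-law proportions", {
  cfg <- sim_config(n_genomes = 5, genome_length = 2000, alpha = -0.5,
                    error_rate = 0, contamination = 0, host_length = 0,
                    n_pairs = 30000L, seed = 12)
  sim <- simulate_metagenome(cfg)
  freq <- table(sim$truth$genome[sim$truth$mate == 1L]) / cfg$n_pairs
  p <- cfg$proportions
  names(p) <- sim$genomes$genome[sim$genomes$role == "community"]
  expect_lt(max(abs(freq[names(p)] - p)), 0.01)
})

test_that("insert lengths follow the configured truncated normal", {
  cfg <- sim_config(n_genomes = 1, genome_length = 5e4, contamination = 0,
                    host_length = 0, n_pairs = 20000L, seed = 13)
  sim <- simulate_metagenome(cfg)
  tt <- sim$truth[sim$truth$mate == 1L, ]
  # recompute the outer distance from the two mates' coordinates
  m2 <- sim$truth[sim$truth$mate == 2L, ]
  outer <- pmax(tt$start, m2$start) + cfg$read_length -
    pmin(tt$start, m2$start)
  expect_equal(mean(outer), 400, tolerance = 3 * 40 / sqrt(nrow(tt)) / 400)
  expect_gt(min(outer), cfg$read_length - 1)
})

test_that("contaminating host pairs appear at the configured fraction", {
  cfg <- sim_config(n_genomes = 2, genome_length = 5000, contamination = 0.1,
                    host_length = 5000, n_pairs = 20000L, seed = 14)
  sim <- simulate_metagenome(cfg)
  frac <- mean(sim$truth$genome[sim$truth$mate == 1L] == "host")
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 20000))
})

test_that("reference fixtures round-trip and stay coordinate-consistent", {
  sim <- small_sim()
  refs <- sim$references
  comm <- sim$genomes[sim$genomes$role == "community", ]
  # every community genome is a species leaf with a color mapping
  cm <- refs$taxonomy$color_map
  expect_true(all(comm$genome %in% cm$reference))
  ranks <- refs$taxonomy$nodes$rank[match(cm$node_id[match(comm$genome, cm$reference)],
                                          refs$taxonomy$nodes$node_id)]
  expect_true(all(ranks == "species"))
  # CDS slices re-extract exactly from their genomes
  gs <- setNames(comm$sequence, comm$genome)
  again <- substring(gs[refs$cds$genome], refs$cds$start + 1, refs$cds$end)
  expect_identical(refs$cds$sequence, unname(again))
  # every CDS has 1-3 annotations from the three domains
  per <- table(refs$go_map$cds)
  expect_true(all(per >= 1 & per <= 3))
  expect_true(all(refs$go_map$domain %in% c("biological_process",
                                            "cellular_component",
                                            "molecular_function")))
})

test_that("near-duplicates are registered as sibling species", {
  dup <- tibble::tibble(source = 1L, divergence = 0.01)
  cfg <- sim_config(n_genomes = 3, genome_length = 3000, duplicates = dup,
                    host_length = 0, n_pairs = 10L, seed = 15)
  gn <- simulate_genomes(cfg)
  refs <- simulate_references(gn, cfg)
  tax <- refs$taxonomy
  dup_name <- gn$genome[gn$role == "duplicate"]
  lca <- lca_assign(c("genome_01", dup_name), tax)
  expect_equal(tax$nodes$rank[tax$nodes$node_id == lca], "genus")
})

test_that("written outputs are deterministic and manifest-checksummed", {
  cfg <- sim_config(n_genomes = 2, genome_length = 3000, n_pairs = 200,
                    seed = 16)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_metagenome(cfg, outdir = d1)
  simulate_metagenome(cfg, outdir = d2)
  for (f in c("reads_R1.fastq", "reads_R2.fastq", "genomes.fasta",
              "truth.tsv", "taxonomy.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 16)
  expect_true(length(man$files) >= 8)
})
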