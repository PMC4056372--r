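#' Power-law community proportions
#'
#' The i-th ranked genome gets proportion i^alpha / sum(j^alpha), the
#' abundance structure used for the simulated metagenomes (alpha = -0.5
#' for the 100-genome design, -0.3 for the 1,000-genome design).
#'
#' @param n Number of genomes (>= 1).
#' @param alpha Power-law exponent; negative values give decreasing
#'   proportions.
#' @return Numeric vector of length `n` summing to 1.
#' @examples
#' power_law_proportions(2, -1)  # 2/3, 1/3
#' @export
power_law_proportions <- function(n, alpha = -0.5) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  w <- seq_len(n)^alpha
  w / sum(w)
}

#' Simulation configuration
#'
#' Defaults mirror the 100-genome study design scaled to desk size: 101 nt
#' reads, 0.25% substitution errors, mean insert 400 (sd 10% of the mean),
#' 1% host contamination, power-law exponent -0.5, and enough pairs for a
#' 30x expected depth on the most abundant genome.
#'
#' @param n_genomes Number of community genomes.
#' @param genome_length Length of each genome in nt (scalar or vector).
#' @param alpha Power-law exponent over abundance ranks.
#' @param read_length Read length in nt.
#' @param error_rate Per-base substitution probability, in \[0, 1\].
#' @param insert_mean,insert_sd Insert-size (outer fragment) distribution;
#'   `insert_sd = NULL` defaults to 10% of the mean.
#' @param contamination Fraction of pairs drawn from the host genome.
#' @param host_length Host genome length (0 disables the host).
#' @param top_depth Expected coverage depth of the most abundant genome;
#'   used to derive `n_pairs` when that is NULL.
#' @param n_pairs Number of read pairs (overrides `top_depth`).
#' @param duplicates Optional tibble with `source` (genome index) and
#'   `divergence` (per-base substitution rate) describing near-duplicate
#'   reference genomes to generate.
#' @param seed Mandatory random seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genomes = 10L, genome_length = 1e5, alpha = -0.5,
                       read_length = 101L, error_rate = 0.0025,
                       insert_mean = 400, insert_sd = NULL,
                       contamination = 0.01, host_length = 1e5,
                       top_depth = 30, n_pairs = NULL, duplicates = NULL,
                       seed = 1L) {
  if (is.null(insert_sd)) insert_sd <- 0.1 * insert_mean
  rates <- c(error_rate = error_rate, contamination = contamination)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  genome_length <- rep_len(as.numeric(genome_length), n_genomes)
  if (any(genome_length < read_length)) stop("genomes must be at least one read long")
  if (is.null(seed)) stop("a seed is mandatory for stochastic simulation")
  p <- power_law_proportions(n_genomes, alpha)
  if (is.null(n_pairs)) {
    bases_top <- top_depth * genome_length[1]
    n_pairs <- ceiling(bases_top / (p[1] * (1 - contamination) * 2 * read_length))
  }
  structure(list(n_genomes = as.integer(n_genomes),
                 genome_length = genome_length, alpha = alpha,
                 proportions = p, read_length = as.integer(read_length),
                 error_rate = error_rate, insert_mean = insert_mean,
                 insert_sd = insert_sd, contamination = contamination,
                 host_length = host_length, n_pairs = as.integer(n_pairs),
                 duplicates = duplicates, seed = as.integer(seed)),
            class = "sim_config")
}

# run code under a derived seed without disturbing the caller's RNG state
with_sim_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate community, host and near-duplicate genomes
#'
#' Community genomes are i.i.d. uniform ACGT sequences. A near-duplicate
#' copies its source genome and applies substitutions at the configured
#' divergence rate (0 gives a byte-identical copy), emulating duplicated
#' or almost-identical reference genomes. The host genome models the
#' contaminating organism. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return Tibble with `genome`, `role` (community / host / duplicate),
#'   `length`, `source`, `divergence`, `sequence`, `proportion`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed + 101L, {
    n <- config$n_genomes
    seqs <- vapply(config$genome_length, random_dna, character(1))
    out <- tibble(genome = sprintf("genome_%02d", seq_len(n)),
                  role = "community", length = config$genome_length,
                  source = NA_character_, divergence = NA_real_,
                  sequence = seqs, proportion = config$proportions)
    if (!is.null(config$host_length) && config$host_length > 0) {
      out <- bind_rows(out, tibble(
        genome = "host", role = "host", length = config$host_length,
        source = NA_character_, divergence = NA_real_,
        sequence = random_dna(config$host_length), proportion = NA_real_))
    }
    if (!is.null(config$duplicates)) {
      for (i in seq_len(nrow(config$duplicates))) {
        src <- config$duplicates$source[i]
        div <- config$duplicates$divergence[i]
        s <- out$sequence[src]
        if (div > 0) s <- mutate_sequence(s, div)
        out <- bind_rows(out, tibble(
          genome = sprintf("%s_dup%d", out$genome[src], i), role = "duplicate",
          length = nchar(s), source = out$genome[src], divergence = div,
          sequence = s, proportion = NA_real_))
      }
    }
    out
  })
}

# substitute each base independently with probability `rate`
mutate_sequence <- function(s, rate) {
  n <- nchar(s)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(s)
  pos <- sample.int(n, k)
  cur <- substring(s, pos, pos)
  repl <- substitute_bases(cur)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  chars[pos] <- repl
  paste(chars, collapse = "")
}

# uniformly one of the three other bases, vectorized
substitute_bases <- function(cur) {
  alt <- matrix(c("C", "G", "T",
                  "A", "G", "T",
                  "A", "C", "T",
                  "A", "C", "G"), nrow = 4, byrow = TRUE,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  alt[cbind(match(cur, rownames(alt)), sample.int(3L, length(cur), replace = TRUE))]
}

#' Simulate paired reads with truth tracking
#'
#' Each pair is drawn from community genome i with probability
#' proportional to its power-law proportion, or from the host with the
#' contamination probability. Fragment starts are uniform; the insert
#' (outer fragment length) is Normal(mean, sd) rounded, truncated to at
#' least one read length and resampled (with a retry cap) when longer
#' than the genome. Mate 1 reads the fragment's 5' end, mate 2 is the
#' reverse complement of its 3' end; whole fragments flip strand with
#' probability 1/2. Substitution errors hit every base independently at
#' the configured rate, replacing it with one of the other three bases.
#'
#' @param config A [sim_config()].
#' @param genomes Output of [simulate_genomes()].
#' @return A list: `reads` (tibble `id`, `pair`, `mate`, `sequence`) in
#'   interleaved order, and `truth` (tibble `id`, `genome`, `start`,
#'   `strand`, `pair`, `mate`, `insert`) with 0-based starts.
#' @export
simulate_reads <- function(config, genomes) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed + 202L, {
    comm <- genomes[genomes$role == "community", ]
    host <- genomes[genomes$role == "host", ]
    n <- config$n_pairs
    rl <- config$read_length
    use_host <- nrow(host) == 1L && config$contamination > 0
    from_host <- if (use_host) runif(n) < config$contamination else rep(FALSE, n)
    gi <- integer(n)
    gi[!from_host] <- sample.int(nrow(comm), sum(!from_host), replace = TRUE,
                                 prob = comm$proportion)
    pool_seq <- c(comm$sequence, if (use_host) host$sequence)
    pool_name <- c(comm$genome, if (use_host) host$genome)
    pool_len <- c(comm$length, if (use_host) host$length)
    gi[from_host] <- nrow(comm) + 1L
    glen <- pool_len[gi]
    insert <- round(rnorm(n, config$insert_mean, config$insert_sd))
    insert <- pmax(insert, rl)
    for (try in seq_len(50L)) {
      bad <- insert > glen
      if (!any(bad)) break
      insert[bad] <- pmax(round(rnorm(sum(bad), config$insert_mean,
                                      config$insert_sd)), rl)
    }
    insert <- pmin(insert, glen)  # after the retry cap, clamp
    start <- floor(runif(n) * (glen - insert + 1))
    flip <- runif(n) < 0.5
    left <- substring(pool_seq[gi], start + 1, start + rl)
    right_rc <- revcomp_fast(substring(pool_seq[gi], start + insert - rl + 1,
                                       start + insert))
    r1 <- ifelse(flip, right_rc, left)
    r2 <- ifelse(flip, left, right_rc)
    r1_start <- ifelse(flip, start + insert - rl, start)
    r2_start <- ifelse(flip, start, start + insert - rl)
    r1_strand <- ifelse(flip, "-", "+")
    r2_strand <- ifelse(flip, "+", "-")
    r1 <- apply_substitution_errors(r1, config$error_rate)
    r2 <- apply_substitution_errors(r2, config$error_rate)
    ids1 <- sprintf("read_%07d/1", seq_len(n))
    ids2 <- sprintf("read_%07d/2", seq_len(n))
    reads <- tibble(
      id = as.character(rbind(ids1, ids2)),
      pair = rep(seq_len(n), each = 2L),
      mate = rep(c(1L, 2L), n),
      sequence = as.character(rbind(r1, r2))
    )
    truth <- tibble(
      id = reads$id,
      genome = rep(pool_name[gi], each = 2L),
      start = as.numeric(rbind(r1_start, r2_start)),
      strand = as.character(rbind(r1_strand, r2_strand)),
      pair = reads$pair,
      mate = reads$mate,
      insert = rep(insert, each = 2L)
    )
    list(reads = reads, truth = truth)
  })
}

revcomp_fast <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

apply_substitution_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  idx <- which(n_err > 0L)
  if (!length(idx)) return(seqs)
  reads_i <- rep(idx, n_err[idx])
  pos <- unlist(lapply(idx, function(i) sample.int(lens[i], n_err[i])),
                use.names = FALSE)
  cur <- substring(seqs[reads_i], pos, pos)
  repl <- substitute_bases(cur)
  occ <- stats::ave(reads_i, reads_i, FUN = seq_along)
  for (r in seq_len(max(occ))) {
    sel <- occ == r
    s2 <- seqs[reads_i[sel]]
    substr(s2, pos[sel], pos[sel]) <- repl[sel]
    seqs[reads_i[sel]] <- s2
  }
  seqs
}

#' Simulate reference-side fixtures: taxonomy, CDS and GO annotations
#'
#' Builds a random rooted taxonomy over the seven ranks with every
#' community genome attached as a species leaf (near-duplicates become
#' sibling species under the source's genus; the host gets its own
#' kingdom-to-species lineage), a reference-to-taxon map, non-overlapping
#' CDS slices cut from the genomes (default 900 nt every 3 kb), and a
#' synthetic gene-ontology annotation (terms across the three domains,
#' 1-3 terms per CDS).
#'
#' @param genomes Output of [simulate_genomes()].
#' @param config A [sim_config()].
#' @param cds_length,cds_every CDS slice length and spacing in nt.
#' @param n_terms Number of synthetic GO terms.
#' @return A list: `taxonomy` (a [taxonomy()] with `color_map`), `cds`
#'   (tibble `id`, `genome`, `start`, `end`, `sequence`), `go_map`
#'   (tibble `cds`, `go_id`, `domain`).
#' @export
simulate_references <- function(genomes, config, cds_length = 900L,
                                cds_every = 3000L, n_terms = 30L) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed + 303L, {
    comm <- genomes[genomes$role == "community", ]
    ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
    pool_sizes <- c(kingdom = 2L, phylum = 3L, class = 4L, order = 5L,
                    family = 6L, genus = max(2L, nrow(comm) - 1L))
    nodes <- tibble(node_id = 1L, parent_id = NA_integer_, rank = "root",
                    name = "root")
    nxt <- 2L
    index <- new.env(parent = emptyenv())
    make_node <- function(parent, rank, name) {
      key <- paste(parent, rank, name, sep = "|")
      id <- index[[key]]
      if (!is.null(id)) return(id)
      id <- nxt
      nodes <<- bind_rows(nodes, tibble(node_id = id, parent_id = parent,
                                        rank = rank, name = name))
      nxt <<- nxt + 1L
      index[[key]] <- id
      id
    }
    genus_of <- integer(nrow(comm))
    for (i in seq_len(nrow(comm))) {
      cur <- 1L
      for (r in ranks) {
        pick <- sample.int(pool_sizes[[r]], 1L)
        cur <- make_node(cur, r, sprintf("%s_%02d", r, pick))
      }
      genus_of[i] <- cur
    }
    leaves <- integer(0); leaf_names <- character(0)
    for (i in seq_len(nrow(comm))) {
      leaves <- c(leaves, make_node(genus_of[i], "species", comm$genome[i]))
      leaf_names <- c(leaf_names, comm$genome[i])
    }
    dups <- genomes[genomes$role == "duplicate", ]
    for (i in seq_len(nrow(dups))) {
      src <- match(dups$source[i], comm$genome)
      leaves <- c(leaves, make_node(genus_of[src], "species", dups$genome[i]))
      leaf_names <- c(leaf_names, dups$genome[i])
    }
    if (any(genomes$role == "host")) {
      cur <- 1L
      for (r in ranks) cur <- make_node(cur, r, paste0("host_", r))
      leaves <- c(leaves, make_node(cur, "species", "host"))
      leaf_names <- c(leaf_names, "host")
    }
    tax <- taxonomy(nodes, tibble(reference = leaf_names, node_id = leaves))

    # CDS slices and synthetic GO annotation
    cds <- purrr::map_dfr(seq_len(nrow(comm)), function(i) {
      starts <- seq(0L, comm$length[i] - cds_length, by = cds_every)
      tibble(id = sprintf("%s_cds_%03d", comm$genome[i], seq_along(starts)),
             genome = comm$genome[i], start = starts,
             end = starts + cds_length,
             sequence = substring(comm$sequence[i], starts + 1,
                                  starts + cds_length))
    })
    domains <- c("biological_process", "cellular_component", "molecular_function")
    terms <- tibble(go_id = sprintf("GO:%07d", seq_len(n_terms)),
                    domain = sample(domains, n_terms, replace = TRUE))
    go_map <- purrr::map_dfr(seq_len(nrow(cds)), function(i) {
      pick <- sample.int(n_terms, sample.int(3L, 1L))
      tibble(cds = cds$id[i], go_id = terms$go_id[pick],
             domain = terms$domain[pick])
    })
    list(taxonomy = tax, cds = cds, go_map = go_map)
  })
}

#' Simulate a full metagenome experiment
#'
#' Orchestrates [simulate_genomes()], [simulate_reads()] and
#' [simulate_references()]. With `outdir` set, writes R1/R2 FASTQ
#' (constant quality `I`), genomes FASTA, truth TSV, taxonomy and map
#' TSVs, a config echo JSON and a checksum manifest.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @return A `metagenome_sim` list: `config`, `genomes`, `reads`,
#'   `truth`, `references` and (when written) `paths`.
#' @export
simulate_metagenome <- function(config, outdir = NULL) {
  genomes <- simulate_genomes(config)
  rd <- simulate_reads(config, genomes)
  refs <- simulate_references(genomes, config)
  out <- list(config = config, genomes = genomes, reads = rd$reads,
              truth = rd$truth, references = refs)
  class(out) <- "metagenome_sim"
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- c(
      r1 = file.path(outdir, "reads_R1.fastq"),
      r2 = file.path(outdir, "reads_R2.fastq"),
      genomes = file.path(outdir, "genomes.fasta"),
      truth = file.path(outdir, "truth.tsv"),
      taxonomy = file.path(outdir, "taxonomy.tsv"),
      taxon_map = file.path(outdir, "taxon_map.tsv"),
      cds = file.path(outdir, "cds.fasta"),
      go_map = file.path(outdir, "go_map.tsv"),
      config = file.path(outdir, "config.json")
    )
    write_fastq(rd$reads[rd$reads$mate == 1L, ], p["r1"])
    write_fastq(rd$reads[rd$reads$mate == 2L, ], p["r2"])
    write_fasta(setNames(genomes$sequence, genomes$genome), p["genomes"])
    write_tsv_hash(rd$truth, p["truth"])
    write_taxonomy(refs$taxonomy, p["taxonomy"], p["taxon_map"])
    write_fasta(setNames(refs$cds$sequence, refs$cds$id), p["cds"])
    write_tsv_hash(refs$go_map, p["go_map"])
    cfg <- unclass(config)
    cfg$duplicates <- if (!is.null(cfg$duplicates)) as.data.frame(cfg$duplicates)
    jsonlite::write_json(cfg, p["config"], auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    write_manifest(p, file.path(outdir, "manifest.json"),
                   extra = list(seed = config$seed))
    out$paths <- p
  }
  out
}

#' @export
print.metagenome_sim <- function(x, ...) {
  cat("simulated metagenome: ", sum(x$genomes$role == "community"),
      " community genomes, ", x$config$n_pairs, " read pairs\n", sep = "")
  cat("  error rate ", x$config$error_rate, ", insert ",
      x$config$insert_mean, " +/- ", x$config$insert_sd,
      ", contamination ", x$config$contamination, "\n", sep = "")
  invisible(x)
}
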