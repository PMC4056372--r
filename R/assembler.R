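#' Find seed paths (unitigs)
#'
#' A seed is a maximal path whose internal vertices have exactly one
#' present predecessor and one present successor, where presence means
#' coverage at least `cov_present`. Seeds are vertex-disjoint, reported in
#' canonical orientation (lexicographic minimum of the sequence and its
#' reverse complement) and sorted, so the output is deterministic
#' regardless of read order or shard count. Paths shorter than
#' `min_seed_nt` (default 2k - 1) are discarded.
#'
#' @param graph A `dbg_graph`.
#' @param cov_present Minimum vertex coverage to be considered present
#'   (default 2; this is the traversal-time error filter).
#' @param min_seed_nt Minimum seed length in nucleotides; default 2k - 1.
#' @return Tibble with `seed` (id), `sequence`, `length`.
#' @export
find_seeds <- function(graph, cov_present = 2L, min_seed_nt = NULL) {
  stopifnot(inherits(graph, "dbg_graph"))
  if (is.null(min_seed_nt)) min_seed_nt <- 2L * graph$k - 1L
  s <- cpp_find_seeds(graph$ptr, as.integer(cov_present), as.integer(min_seed_nt))
  tibble(seed = seq_along(s), sequence = s, length = nchar(s))
}

#' Local coverage statistics of a seed path
#'
#' The mode and minimum coverage are computed from exactly the seed's own
#' vertices -- never from any global coverage distribution. Ties in the
#' mode break toward the smaller coverage value.
#'
#' @param graph A `dbg_graph`.
#' @param seed A seed sequence (single string).
#' @return A list with `mode`, `min` and the integer `coverages` multiset
#'   in path order.
#' @export
seed_local_coverage <- function(graph, seed) {
  stopifnot(inherits(graph, "dbg_graph"), is.character(seed), length(seed) == 1L)
  cpp_seed_stats(graph$ptr, seed)
}

#' Select read markers on a seed
#'
#' A read is markered at its first k-mer (in read order) that lies on the
#' seed and whose coverage is at least the seed's minimum coverage and at
#' most `repeat_mult` times the seed's mode coverage (repeat avoidance).
#' One marker per read per seed. Markers record where the read projects
#' onto the path and on which strand, and are what votes at branch points
#' during extension.
#'
#' @param graph A `dbg_graph`.
#' @param reads A read set from [index_reads()], or the same inputs
#'   [build_graph()] accepts (indexed on the fly).
#' @param seed Seed sequence.
#' @param stats Optional result of [seed_local_coverage()] (recomputed when
#'   missing).
#' @param repeat_mult Repeat-avoidance multiplier on the mode (default 3).
#' @param cov_present Presence threshold carried by the traversal (default 2).
#' @return Tibble with `read` (index into the read set), `path_offset`
#'   (k-mer index of the anchor on the seed), `read_offset`, `strand`
#'   (read direction relative to the seed) and `proj_start` (projected
#'   0-based start of the whole read on the path).
#' @export
select_read_markers <- function(graph, reads, seed, stats = NULL,
                                repeat_mult = 3, cov_present = 2L) {
  stopifnot(inherits(graph, "dbg_graph"))
  rs <- as_readset(reads, graph$k)
  if (is.null(stats)) stats <- seed_local_coverage(graph, seed)
  as_tibble(cpp_select_markers(graph$ptr, rs$ptr, seed,
                               as.integer(stats$min),
                               repeat_mult * stats$mode,
                               as.integer(cov_present)))
}

#' Index a read set for marker queries
#'
#' Builds the k-mer -> (read, offset, strand) index the assembler uses for
#' marker selection and vote counting. Reads must be in interleaved order
#' (mate 2 of a pair directly after mate 1) when `paired = TRUE`.
#'
#' @param reads Same inputs as [build_graph()].
#' @param k K-mer length (must match the graph).
#' @param paired Whether reads are interleaved pairs.
#' @return A `read_index` object.
#' @export
index_reads <- function(reads, k = 31L, paired = TRUE) {
  seqs <- as_read_vector(reads)
  if (paired && length(seqs) %% 2L != 0L) {
    stop("paired read sets must have an even number of reads (interleaved)")
  }
  structure(list(ptr = cpp_readset_build(seqs, as.integer(k), paired),
                 n = length(seqs), k = as.integer(k), paired = paired),
            class = "read_index")
}

as_readset <- function(reads, k, paired = TRUE) {
  if (inherits(reads, "read_index")) {
    if (reads$k != k) stop("read index was built with k = ", reads$k)
    return(reads)
  }
  index_reads(reads, k = k, paired = paired)
}

#' Estimate the insert-size distribution from seed markers
#'
#' Uses pairs whose two mates are both markered on one seed, takes the
#' outer fragment distance of each, discards the top and bottom 5% as
#' outliers, and reports the mean and standard deviation. With fewer than
#' `min_pairs` usable pairs the configured prior is returned with a
#' warning.
#'
#' @param graph A `dbg_graph`.
#' @param reads A `read_index` (interleaved pairs) or read input.
#' @param seeds Seed tibble from [find_seeds()] or a character vector of
#'   seed sequences.
#' @param prior Fallback `c(mean, sd)` (default 400, 40).
#' @param min_pairs Minimum usable pairs before falling back (default 30).
#' @param repeat_mult,cov_present Marker-selection parameters.
#' @return A list with `mean`, `sd`, `n_used`, `fallback`.
#' @export
estimate_insert_size <- function(graph, reads, seeds, prior = c(400, 40),
                                 min_pairs = 30L, repeat_mult = 3,
                                 cov_present = 2L) {
  stopifnot(inherits(graph, "dbg_graph"))
  rs <- as_readset(reads, graph$k)
  seqs <- if (is.data.frame(seeds)) seeds$sequence else as.character(seeds)
  obs <- cpp_insert_observations(graph$ptr, rs$ptr, seqs, repeat_mult,
                                 as.integer(cov_present))
  if (length(obs) < min_pairs) {
    warning("only ", length(obs), " concordant pairs; falling back to prior insert ",
            prior[1], " +/- ", prior[2])
    return(list(mean = prior[1], sd = prior[2], n_used = 0L, fallback = TRUE))
  }
  qs <- quantile(obs, c(0.05, 0.95), type = 1)
  kept <- obs[obs >= qs[1] & obs <= qs[2]]
  list(mean = mean(kept), sd = stats::sd(kept), n_used = length(kept),
       fallback = FALSE)
}

#' Extend a seed through the graph with marker voting
#'
#' Both ends of the seed are extended. At every step the present
#' successors (coverage >= `cov_present`) are candidates; with a single
#' candidate the walk advances. At a branch, candidates are scored first
#' by votes from markered reads that, laid along the path from their
#' marker, cover the decision position and read out the candidate base;
#' if those votes are not decisive, by votes from mates of forward
#' on-path reads projected over the decision position (within
#' `insert_mean` +/- 3 `insert_sd`) that contain the candidate k-mer. The
#' top candidate is taken iff it has at least `vote_min` votes and at
#' least `vote_ratio` times the runner-up; otherwise extension stops with
#' reason `"ambiguous"` (or `"conflict"` when the two vote stages name
#' different decisive winners). Re-entering a vertex already on the path
#' stops with `"cycle"`; no present successor stops with
#' `"no-successor"`. The contig is emitted in canonical orientation.
#'
#' @param graph A `dbg_graph`.
#' @param reads A `read_index` or read input.
#' @param seed Seed sequence.
#' @param cov_present Presence threshold (default 2).
#' @param repeat_mult Repeat-avoidance multiplier (default 3).
#' @param vote_min,vote_ratio Decision rule constants (defaults 2 and 2).
#' @param insert_mean,insert_sd Insert-size model for mate votes.
#' @return A list with `sequence`, `stop_left`, `stop_right`.
#' @export
extend_seed <- function(graph, reads, seed, cov_present = 2L, repeat_mult = 3,
                        vote_min = 2L, vote_ratio = 2, insert_mean = 400,
                        insert_sd = 40) {
  stopifnot(inherits(graph, "dbg_graph"))
  rs <- as_readset(reads, graph$k)
  cpp_extend_seed(graph$ptr, rs$ptr, seed, as.integer(cov_present),
                  repeat_mult, as.integer(vote_min), vote_ratio,
                  insert_mean, insert_sd)
}

#' Assemble reads into contigs and scaffolds
#'
#' Orchestrates the whole pipeline: graph build, seed finding, insert-size
#' estimation, marker selection, heuristic extension, duplicate and
#' containment removal, and scaffolding. Contigs shorter than `min_contig`
#' (default 100 nt) are suppressed from the output. The result is
#' deterministic for fixed input: independent of read order and shard
#' count, and identical whether or not the graph is colored.
#'
#' @param reads Interleaved read character vector / tibble, or
#'   `list(r1 =, r2 =)` character vectors, or FASTQ path(s).
#' @param k Odd k-mer length (default 31).
#' @param paired Whether reads form pairs (interleaved order).
#' @param graph Optionally a pre-built `dbg_graph` for these reads.
#' @param cov_present,repeat_mult,vote_min,vote_ratio Traversal constants,
#'   see [extend_seed()].
#' @param min_seed_nt Seed length floor (default 2k - 1).
#' @param min_contig Reporting floor in nucleotides (default 100).
#' @param insert_prior Fallback insert `c(mean, sd)`.
#' @param shards Shard count for the graph build.
#' @param scaffold_min_links Pair support needed to link two contigs
#'   (default 3).
#' @return A `dbg_assembly` object: tibbles `contigs` and `scaffolds`, the
#'   `report` list (seed count, stop-reason tallies, insert estimate,
#'   parameters) and the `graph`.
#' @export
assemble <- function(reads, k = 31L, paired = TRUE, graph = NULL,
                     cov_present = 2L, repeat_mult = 3, vote_min = 2L,
                     vote_ratio = 2, min_seed_nt = NULL, min_contig = 100L,
                     insert_prior = c(400, 40), shards = 4L,
                     scaffold_min_links = 3L) {
  if (is.list(reads) && !is.data.frame(reads) && all(c("r1", "r2") %in% names(reads))) {
    n <- length(reads$r1)
    if (n != length(reads$r2)) stop("r1 and r2 lengths differ")
    reads <- as.character(rbind(reads$r1, reads$r2))
    paired <- TRUE
  }
  seqs <- as_read_vector(reads)
  if (is.null(graph)) graph <- build_graph(seqs, k = k, shards = shards)
  k <- graph$k
  if (is.null(min_seed_nt)) min_seed_nt <- 2L * k - 1L
  seeds <- find_seeds(graph, cov_present = cov_present, min_seed_nt = min_seed_nt)
  empty <- tibble(name = character(), sequence = character(), length = integer(),
                  stop_left = character(), stop_right = character(), seed = integer())
  if (nrow(seeds) == 0L) {
    warning("no seeds found; empty assembly")
    return(new_assembly(empty, tibble(name = character(), sequence = character(),
                                      length = integer(), n_contigs = integer()),
                        list(n_seeds = 0L, stop_reasons = table(character())),
                        graph))
  }
  rs <- index_reads(seqs, k = k, paired = paired)
  ins <- if (paired) {
    # longest seeds carry the most concordant pairs
    top <- seeds$sequence[order(-seeds$length)][seq_len(min(nrow(seeds), 50L))]
    suppressWarnings(estimate_insert_size(graph, rs, top, prior = insert_prior,
                                          repeat_mult = repeat_mult,
                                          cov_present = cov_present))
  } else {
    list(mean = insert_prior[1], sd = insert_prior[2], n_used = 0L, fallback = TRUE)
  }
  # deterministic processing order: longest first, ties by sequence
  ord <- order(-seeds$length, seeds$sequence)
  ext <- cpp_extend_all(graph$ptr, rs$ptr, seeds$sequence[ord],
                        as.integer(cov_present), repeat_mult,
                        as.integer(vote_min), vote_ratio,
                        ins$mean, max(ins$sd, 1e-9))
  contigs <- as_tibble(ext$contigs)
  contigs$length <- nchar(contigs$sequence)
  contigs <- contigs |>
    filter(.data$length >= min_contig) |>
    arrange(desc(.data$length), .data$sequence) |>
    mutate(name = sprintf("contig_%05d", row_number())) |>
    select("name", "sequence", "length", "stop_left", "stop_right", "seed")
  stop_tally <- table(c(contigs$stop_left, contigs$stop_right))
  scaf <- scaffold_contigs(contigs, rs, ins, min_links = scaffold_min_links)
  report <- list(
    n_seeds = nrow(seeds),
    n_contigs = nrow(contigs),
    n_skipped_claimed = ext$n_skipped_claimed,
    n_dropped_contained = ext$n_dropped_contained,
    stop_reasons = stop_tally,
    insert = ins,
    params = list(k = k, cov_present = cov_present, repeat_mult = repeat_mult,
                  vote_min = vote_min, vote_ratio = vote_ratio,
                  min_seed_nt = min_seed_nt, min_contig = min_contig,
                  scaffold_min_links = scaffold_min_links)
  )
  new_assembly(contigs, scaf$scaffolds, report, graph, links = scaf$links)
}

new_assembly <- function(contigs, scaffolds, report, graph, links = NULL) {
  structure(list(contigs = contigs, scaffolds = scaffolds, report = report,
                 graph = graph, links = links),
            class = "dbg_assembly")
}

#' @export
print.dbg_assembly <- function(x, ...) {
  st <- assembly_stats(x$contigs, floor = 0)
  cat("assembly: ", nrow(x$contigs), " contigs, ", nrow(x$scaffolds),
      " scaffolds\n", sep = "")
  cat("  total ", st$total, " nt; N50 ", st$n50, "; longest ", st$longest, "\n", sep = "")
  if (!is.null(x$report$stop_reasons) && length(x$report$stop_reasons)) {
    sr <- x$report$stop_reasons
    cat("  stop reasons:", paste(names(sr), as.integer(sr), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Scaffold contigs with paired-read links
#'
#' Mates anchored on different contigs in convergent orientation propose a
#' link between two contig ends with an implied gap
#' (`insert mean - observed span`). Links supported by at least
#' `min_links` pairs are kept; when two links compete for the same contig
#' end the higher-support one wins and the loser is dropped (logged in the
#' returned `links` tibble with `kept = FALSE`). Linked contigs are joined
#' with `max(1, round(median implied gap))` Ns; singletons pass through.
#'
#' @param contigs Contig tibble (`name`, `sequence`) or character vector.
#' @param reads A `read_index` with interleaved pairs.
#' @param insert Insert model list (`mean`, `sd`) from
#'   [estimate_insert_size()].
#' @param min_links Minimum supporting pairs (default 3).
#' @return List with `scaffolds` tibble (`name`, `sequence`, `length`,
#'   `n_contigs`) and the `links` tibble.
#' @export
scaffold_contigs <- function(contigs, reads, insert, min_links = 3L) {
  if (is.character(contigs)) {
    contigs <- tibble(name = sprintf("contig_%05d", seq_along(contigs)),
                      sequence = contigs)
  }
  n <- nrow(contigs)
  lens <- nchar(contigs$sequence)
  empty_links <- tibble(from = integer(), from_end = character(),
                        to = integer(), to_end = character(),
                        support = integer(), gap = numeric(), kept = logical())
  if (n == 0L) {
    return(list(scaffolds = tibble(name = character(), sequence = character(),
                                   length = integer(), n_contigs = integer()),
                links = empty_links))
  }
  singletons <- function(links) {
    list(scaffolds = tibble(name = sprintf("scaffold_%05d", seq_len(n)),
                            sequence = contigs$sequence, length = lens,
                            n_contigs = 1L),
         links = links)
  }
  if (n == 1L || !inherits(reads, "read_index") || !reads$paired) {
    return(singletons(empty_links))
  }
  anc <- as_tibble(cpp_anchor_reads(contigs$sequence, reads$ptr))
  if (nrow(anc) == 0L) return(singletons(empty_links))
  anc$len <- nchar(contigs$sequence)[anc$contig]
  # mate of read r is r xor 1 on 0-based ids
  anc$pair <- (anc$read - 1L) %/% 2L
  anc <- arrange(anc, .data$read)
  both <- anc |> group_by(.data$pair) |> filter(n() == 2L) |> ungroup()
  if (nrow(both) == 0L) return(singletons(empty_links))
  a <- both[seq(1L, nrow(both), by = 2L), ]
  b <- both[seq(2L, nrow(both), by = 2L), ]
  use <- a$contig != b$contig & a$strand != b$strand
  a <- a[use, ]; b <- b[use, ]
  if (nrow(a) == 0L) return(singletons(empty_links))
  # orient so `fwd` is the forward-anchored mate: the link leaves the right
  # end of fwd's contig and enters the left end of rev's contig
  swap <- a$strand != "+"
  fwd <- a; rev <- b
  fwd[swap, ] <- b[swap, ]; rev[swap, ] <- a[swap, ]
  links_raw <- tibble(
    from = fwd$contig, to = rev$contig,
    # span consumed on each side of the junction
    span = (fwd$len - fwd$start) + (rev$start + rev$read_len)
  )
  links_raw$gap <- insert$mean - links_raw$span
  grp <- links_raw |>
    group_by(.data$from, .data$to) |>
    summarise(support = n(), gap = stats::median(.data$gap), .groups = "drop") |>
    filter(.data$support >= min_links) |>
    arrange(desc(.data$support), .data$from, .data$to)
  if (nrow(grp) == 0L) return(singletons(empty_links))
  # resolve conflicts: one outgoing link per right end, one incoming per left end
  used_from <- logical(n); used_to <- logical(n)
  grp$kept <- FALSE
  for (i in seq_len(nrow(grp))) {
    f <- grp$from[i]; t <- grp$to[i]
    if (!used_from[f] && !used_to[t] && f != t) {
      grp$kept[i] <- TRUE; used_from[f] <- TRUE; used_to[t] <- TRUE
    }
  }
  kept <- grp[grp$kept, ]
  # chain contigs
  nxt <- rep(NA_integer_, n); gap_after <- rep(NA_real_, n)
  nxt[kept$from] <- kept$to
  gap_after[kept$from] <- kept$gap
  has_pred <- logical(n); has_pred[kept$to] <- TRUE
  scaff_seq <- character(); scaff_n <- integer()
  visited <- logical(n)
  starts <- which(!has_pred)
  for (s in starts) {
    if (visited[s]) next
    cur <- s; parts <- character(); cnt <- 0L
    while (!is.na(cur) && !visited[cur]) {
      visited[cur] <- TRUE
      parts <- c(parts, contigs$sequence[cur])
      cnt <- cnt + 1L
      g <- gap_after[cur]
      cur <- nxt[cur]
      if (!is.na(cur) && !visited[cur]) {
        parts <- c(parts, strrep("N", max(1L, round(g))))
      }
    }
    scaff_seq <- c(scaff_seq, paste(parts, collapse = ""))
    scaff_n <- c(scaff_n, cnt)
  }
  # anything still unvisited (cycles) passes through as-is
  for (s in which(!visited)) {
    visited[s] <- TRUE
    scaff_seq <- c(scaff_seq, contigs$sequence[s])
    scaff_n <- c(scaff_n, 1L)
  }
  ord <- order(-nchar(scaff_seq), scaff_seq)
  scaffolds <- tibble(name = sprintf("scaffold_%05d", seq_along(scaff_seq)),
                      sequence = scaff_seq[ord], length = nchar(scaff_seq[ord]),
                      n_contigs = scaff_n[ord])
  grp$from_end <- "right"; grp$to_end <- "left"
  list(scaffolds = scaffolds,
       links = grp[, c("from", "from_end", "to", "to_end", "support", "gap", "kept")])
}

#' Write assembly outputs
#'
#' Contigs and scaffolds as wrapped FASTA plus a JSON run report.
#'
#' @param assembly A `dbg_assembly`.
#' @param dir Output directory (created if needed).
#' @return Named paths, invisibly.
#' @export
write_assembly <- function(assembly, dir) {
  stopifnot(inherits(assembly, "dbg_assembly"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- file.path(dir, "contigs.fasta")
  scaffolds <- file.path(dir, "scaffolds.fasta")
  report <- file.path(dir, "report.json")
  write_fasta(setNames(assembly$contigs$sequence, assembly$contigs$name), contigs)
  write_fasta(setNames(assembly$scaffolds$sequence, assembly$scaffolds$name), scaffolds)
  rep <- assembly$report
  rep$stop_reasons <- as.list(rep$stop_reasons)
  jsonlite::write_json(rep, report, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(contigs = contigs, scaffolds = scaffolds, report = report)
  write_manifest(paths, file.path(dir, "manifest.json"))
  invisible(paths)
}

#' @exportS3Method generics::tidy
tidy.dbg_assembly <- function(x, ...) x$contigs

#' @exportS3Method generics::glance
glance.dbg_assembly <- function(x, ...) {
  st <- assembly_stats(x$contigs, floor = 0)
  st$n_scaffolds <- nrow(x$scaffolds)
  st$n_seeds <- x$report$n_seeds
  st
}

#' @exportS3Method ggplot2::autoplot
autoplot.dbg_assembly <- function(object, ...) {
  df <- object$contigs |> arrange(desc(.data$length)) |>
    mutate(cumulative = cumsum(.data$length), rank = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "contigs (longest first)", y = "cumulative length (nt)") +
    ggplot2::theme_minimal()
}
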