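# shared fixtures built in code; all randomness under explicit seeds

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# error-free tiling reads over a sequence (single strand), step 1
tile_reads <- function(s, read_len = 60L, step = 10L) {
  n <- nchar(s)
  starts <- seq(1L, n - read_len + 1L, by = step)
  substring(s, starts, starts + read_len - 1L)
}

# interleave two equal-length read vectors into r1a, r2a, r1b, r2b, ...
interleave <- function(r1, r2) as.character(rbind(r1, r2))

# a small random taxonomy with full 7-rank lineages; species leaves named
rand_taxonomy <- function(n_species, seed) {
  set.seed(seed)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  pools <- c(kingdom = 2L, phylum = 3L, class = 4L, order = 4L, family = 5L,
             genus = 6L)
  nodes <- tibble::tibble(node_id = 1L, parent_id = NA_integer_,
                          rank = "root", name = "root")
  nxt <- 2L
  idx <- new.env(parent = emptyenv())
  add <- function(parent, rank, name) {
    key <- paste(parent, rank, name, sep = "|")
    id <- idx[[key]]
    if (!is.null(id)) return(id)
    id <- nxt
    nodes <<- rbind(nodes, tibble::tibble(node_id = id, parent_id = parent,
                                          rank = rank, name = name))
    nxt <<- nxt + 1L
    idx[[key]] <- id
    id
  }
  leaves <- integer(n_species)
  for (i in seq_len(n_species)) {
    cur <- 1L
    for (r in ranks) cur <- add(cur, r, paste0(r, "_", sample.int(pools[[r]], 1)))
    leaves[i] <- add(cur, "species", paste0("sp_", i))
  }
  taxonomy(nodes, tibble::tibble(reference = paste0("sp_", seq_len(n_species)),
                                 node_id = leaves))
}

# brute-force LCA oracle: intersect full root paths, take the deepest node
lca_oracle <- function(tax, nodes) {
  paths <- lapply(as.character(nodes), function(id) {
    p <- id
    while (!is.na(tax$parent[p[1]])) {
      p <- c(as.character(tax$parent[p[1]]), p)
    }
    p
  })
  common <- Reduce(intersect, paths)
  deepest <- common[which.max(tax$depth[common])]
  tax$nodes$node_id[match(deepest, as.character(tax$nodes$node_id))]
}

# a small simulated metagenome shared by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genomes = 3, genome_length = 20000,
                        contamination = 0, host_length = 0, seed = 5)
      cache <<- simulate_metagenome(cfg)
    }
    cache
  }
})
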