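#' Build a de Bruijn graph from reads
#'
#' Every valid k-mer window of every read becomes (or increments) a vertex
#' keyed by its canonical form; coverage pools both strands. Edges are
#' marked only between adjacent windows actually observed within a read.
#' Vertices live in `shards` independent maps addressed by a pure hash of
#' the packed canonical word; the shard count never changes results, it
#' only partitions storage.
#'
#' Sequencing-error k-mers are stored like any others: no coverage floor is
#' applied at build time. Low-coverage vertices are excluded later, during
#' seed finding and traversal, so that erroneous k-mers have little chance
#' of being used by the assembly.
#'
#' @param reads Character vector of read sequences, a
#'   [Biostrings::DNAStringSet], a tibble with a `sequence` column (as
#'   returned by [read_sequences()]), or a path to a FASTA/FASTQ file.
#' @param k Odd k-mer length, default 31.
#' @param shards Number of storage shards (default 4).
#' @return A `dbg_graph` object.
#' @examples
#' g <- build_graph(c("ACGTACGT"), k = 5)
#' g
#' @export
build_graph <- function(reads, k = 31L, shards = 4L) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("k must be a positive odd integer")
  if (k > 31L) stop("k > 31 is not supported")
  seqs <- as_read_vector(reads)
  g <- new.env(parent = emptyenv())
  g$ptr <- cpp_dbg_build(seqs, k, as.integer(shards))
  g$k <- k
  g$shards <- as.integer(shards)
  g$registry <- tibble(
    namespace = character(), color = integer(), reference = character(),
    length = integer(), total_kmers = numeric(), matched_kmers = numeric()
  )
  g$next_color <- 1L
  class(g) <- "dbg_graph"
  st <- cpp_dbg_stats(g$ptr)
  if (st$skipped_records > 0) {
    message(st$skipped_records, " record(s) shorter than k or malformed were skipped")
  }
  g
}

# normalise the accepted read inputs to a plain character vector
as_read_vector <- function(reads) {
  if (inherits(reads, "DNAStringSet")) return(as.character(reads))
  if (is.data.frame(reads)) {
    if (!"sequence" %in% names(reads)) stop("read tibble must have a `sequence` column")
    return(as.character(reads$sequence))
  }
  if (is.character(reads) && length(reads) >= 1L && all(file.exists(reads))) {
    # treat as file path(s) only when every element is an existing file
    recs <- dplyr::bind_rows(lapply(reads, read_sequences))
    return(as.character(recs$sequence))
  }
  as.character(reads)
}

#' @export
print.dbg_graph <- function(x, ...) {
  st <- cpp_dbg_stats(x$ptr)
  cat("de Bruijn graph (k = ", x$k, ", ", x$shards, " shards)\n", sep = "")
  cat("  vertices: ", format(st$n_vertices, big.mark = ","),
      "; k-mer windows ingested: ", format(st$windows, big.mark = ","), "\n", sep = "")
  ns <- unique(x$registry$namespace)
  if (length(ns)) {
    cat("  colored namespaces: ", paste(ns, collapse = ", "),
        " (", nrow(x$registry), " references)\n", sep = "")
  }
  invisible(x)
}

#' Number of vertices in a graph
#' @param graph A `dbg_graph`.
#' @return Vertex count.
#' @export
n_vertices <- function(graph) {
  stopifnot(inherits(graph, "dbg_graph"))
  cpp_dbg_stats(graph$ptr)$n_vertices
}

#' Graph build statistics
#' @param graph A `dbg_graph`.
#' @return One-row tibble: vertex count, windows ingested, coverage sum,
#'   saturated increments, skipped records.
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "dbg_graph"))
  as_tibble(cpp_dbg_stats(graph$ptr))
}

#' Coverage histogram of a graph
#'
#' Diagnostic only: the assembler never consumes any global coverage
#' distribution; all of its coverage statistics are sampled locally from
#' each seed path.
#'
#' @param graph A `dbg_graph`.
#' @return Tibble with `coverage` and `n` (vertex count); `sum(n)` equals
#'   the total number of vertices.
#' @export
coverage_histogram <- function(graph) {
  stopifnot(inherits(graph, "dbg_graph"))
  as_tibble(cpp_dbg_histogram(graph$ptr))
}

#' Query vertices by k-mer
#'
#' @param graph A `dbg_graph`.
#' @param kmers Character vector of k-mers (any strand; looked up by
#'   canonical form).
#' @return Tibble with canonical `kmer`, `present`, `coverage`, the 4-bit
#'   `out_mask`/`in_mask` edge marks and a `colors` list-column.
#' @export
graph_vertices <- function(graph, kmers) {
  stopifnot(inherits(graph, "dbg_graph"))
  as_tibble(cpp_dbg_vertices(graph$ptr, as.character(kmers)))
}

#' Neighbors of a vertex
#'
#' Lists marked edges of a canonical k-mer that resolve to stored vertices.
#' `"forward"` extends the canonical word on its right; `"reverse"` walks
#' toward its predecessors.
#'
#' @param graph A `dbg_graph`.
#' @param kmer A k-mer present in the graph.
#' @param direction `"forward"` or `"reverse"`.
#' @return Tibble with `base` (the extension nucleotide in walk direction)
#'   and `kmer` (the canonical neighbor); at most 4 rows.
#' @export
neighbors <- function(graph, kmer, direction = c("forward", "reverse")) {
  stopifnot(inherits(graph, "dbg_graph"))
  direction <- match.arg(direction)
  as_tibble(cpp_dbg_neighbors(graph$ptr, kmer, direction == "forward"))
}

#' Serialize a graph to a flat table
#'
#' One row per vertex, sorted by canonical k-mer: coverage, the out/in edge
#' masks and the color list. The dump is byte-identical across shard counts
#' and read orderings, which makes it the golden format for determinism
#' tests.
#'
#' @param graph A `dbg_graph`.
#' @param path Optional file; when given, the table is written as TSV
#'   (header line prefixed with `#`).
#' @return The tibble, invisibly when `path` is given.
#' @export
graph_flat <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "dbg_graph"))
  df <- as_tibble(cpp_dbg_serialize(graph$ptr))
  if (!is.null(path)) {
    header <- paste0("#", paste(names(df), collapse = "\t"))
    writeLines(c(header, do.call(paste, c(df, sep = "\t"))), path)
    return(invisible(df))
  }
  df
}

#' Plot the coverage histogram
#'
#' @param graph A `dbg_graph`.
#' @param log_y Log-scale the vertex counts (default TRUE).
#' @return A ggplot object.
#' @export
plot_coverage_histogram <- function(graph, log_y = TRUE) {
  h <- coverage_histogram(graph)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$coverage, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "k-mer coverage depth", y = "vertices") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
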