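#' Color a graph with reference sequences
#'
#' Every k-mer of each reference that already exists in the graph gains
#' that reference's color. Coloring never creates vertices and never
#' touches coverage or edges, so genome assembly is completely independent
#' of it. References are grouped in independent namespaces: a k-mer unique
#' to one reference in the genome namespace may well be shared in a CDS
#' namespace, and all uniqueness questions are answered per namespace.
#' Color sets are interned, so vertices sharing a combination share one
#' stored set.
#'
#' @param graph A `dbg_graph`.
#' @param references Named character vector, `DNAStringSet`, tibble with
#'   `id`/`name` + `sequence`, or a FASTA path.
#' @param namespace Namespace name (default `"default"`).
#' @return Coloring report: tibble with `namespace`, `color`, `reference`,
#'   `length`, `total_kmers`, `matched_kmers`, `fraction_matched`. Also
#'   recorded in the graph's registry.
#' @export
color_graph <- function(graph, references, namespace = "default") {
  stopifnot(inherits(graph, "dbg_graph"))
  refs <- as_reference_vector(references)
  if (any(duplicated(names(refs)))) stop("duplicated reference names")
  short <- nchar(refs) < graph$k
  if (any(short)) {
    warning(sum(short), " reference(s) shorter than k have zero matchable k-mers")
  }
  # idempotence: a (namespace, reference-name) pair keeps its color id, so
  # re-coloring with the same reference set changes no vertex color set
  prior <- graph$registry[graph$registry$namespace == namespace, ]
  ids <- integer(length(refs))
  known <- match(names(refs), prior$reference)
  ids[!is.na(known)] <- prior$color[known[!is.na(known)]]
  n_new <- sum(is.na(known))
  ids[is.na(known)] <- seq.int(graph$next_color, length.out = n_new)
  graph$next_color <- graph$next_color + n_new
  rep <- cpp_dbg_color(graph$ptr, unname(refs), as.integer(ids))
  out <- tibble(
    namespace = namespace, color = as.integer(ids), reference = names(refs),
    length = nchar(unname(refs)), total_kmers = rep$total,
    matched_kmers = rep$matched,
    fraction_matched = ifelse(rep$total > 0, rep$matched / rep$total, NA_real_)
  )
  graph$registry <- bind_rows(
    graph$registry[!(graph$registry$namespace == namespace &
                       graph$registry$reference %in% names(refs)), ],
    out[names(graph$registry)]
  )
  out
}

as_reference_vector <- function(references) {
  if (inherits(references, "DNAStringSet")) {
    refs <- as.character(references)
  } else if (is.data.frame(references)) {
    nm <- if ("id" %in% names(references)) references$id
    else if ("name" %in% names(references)) references$name
    else if ("genome" %in% names(references)) references$genome
    else NULL
    refs <- setNames(as.character(references$sequence), nm)
  } else if (is.character(references) && length(references) == 1L &&
             is.null(names(references)) && file.exists(references)) {
    x <- read_sequences(references, format = "fasta")
    refs <- setNames(x$sequence, x$id)
  } else {
    refs <- references
  }
  if (is.null(names(refs)) || any(names(refs) == "")) {
    names(refs) <- paste0("ref_", seq_along(refs))
  }
  refs
}

ns_colors <- function(graph, namespace) {
  reg <- graph$registry[graph$registry$namespace == namespace, ]
  if (nrow(reg) == 0L) stop("unknown or uncolored namespace: ", namespace)
  reg
}

#' Classify the color state of k-mers
#'
#' Within one namespace, a vertex is `uncolored`, `unique` (exactly one
#' color: its k-mer occurs in one and only one reference) or `shared`.
#'
#' @param graph A `dbg_graph`.
#' @param kmers K-mers to classify.
#' @param namespace Namespace to evaluate uniqueness in.
#' @return Tibble with `kmer`, `class`, `colors` (list-column of color
#'   ids restricted to the namespace).
#' @export
color_class <- function(graph, kmers, namespace = "default") {
  stopifnot(inherits(graph, "dbg_graph"))
  reg <- ns_colors(graph, namespace)
  v <- graph_vertices(graph, kmers)
  if (any(!v$present)) stop("k-mer not present in graph: ", v$kmer[!v$present][1])
  cols <- lapply(v$colors, function(cs) cs[cs %in% reg$color])
  cls <- vapply(cols, function(cs) {
    if (length(cs) == 0L) "uncolored" else if (length(cs) == 1L) "unique" else "shared"
  }, character(1))
  tibble(kmer = v$kmer, class = cls, colors = cols)
}

#' Shared nucleotides between two assemblies
#'
#' A base of assembly `a` counts as shared when it is covered by at least
#' one window of width `k` whose canonical k-mer occurs anywhere in
#' assembly `b` -- exact matches only, no mismatches allowed in k-mers.
#' Only sequences of at least `min_len` nucleotides participate on either
#' side. The quantity is directional, so both directions are reported.
#'
#' @param a,b Character vectors of sequences, tibbles with `sequence`, or
#'   FASTA paths.
#' @param k K-mer length (default 31).
#' @param min_len Sequence length floor (default 500).
#' @return Tibble with one row per direction: `direction`, `shared_nt`,
#'   `total_nt`.
#' @export
assembly_overlap <- function(a, b, k = 31L, min_len = 500L) {
  sa <- as_sequence_vector(a); sb <- as_sequence_vector(b)
  sa <- sa[nchar(sa) >= min_len]; sb <- sb[nchar(sb) >= min_len]
  one_way <- function(x, y) {
    if (length(x) == 0L) return(c(0, 0))
    if (length(y) == 0L) return(c(0, sum(nchar(x))))
    c(sum(cpp_shared_nt(x, y, as.integer(k))), sum(nchar(x)))
  }
  ab <- one_way(sa, sb); ba <- one_way(sb, sa)
  tibble(direction = c("a_in_b", "b_in_a"),
         shared_nt = c(ab[1], ba[1]), total_nt = c(ab[2], ba[2]))
}

as_sequence_vector <- function(x) {
  if (inherits(x, "dbg_assembly")) return(x$contigs$sequence)
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (is.data.frame(x)) return(as.character(x$sequence))
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x)) {
    return(read_sequences(x)$sequence)
  }
  as.character(x)
}
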