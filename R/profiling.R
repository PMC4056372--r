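#' Per-reference abundance by uniquely-colored k-mer demultiplexing
#'
#' For each reference color c in the namespace, the number of k-mer
#' observations is the number of distinct graph k-mers carrying c times
#' the mode coverage of the k-mers colored uniquely by c (mode ties break
#' toward the smaller coverage). The total number of k-mer observations
#' is the sum of coverage depths over all colored k-mers in the
#' namespace, and each proportion is observations divided by that total.
#' A reference with zero uniquely colored k-mers -- the signature of a
#' duplicated or near-identical reference -- gets proportion 0 and the
#' `no_unique_kmers` flag; such signals can only be recovered at a higher
#' taxon through [taxonomic_profile()].
#'
#' @param graph A colored `dbg_graph`.
#' @param namespace Namespace of the references.
#' @return Tibble with `color`, `reference`, `matched_kmers`,
#'   `unique_kmers`, `mode_unique`, `observations`, `proportion`,
#'   `no_unique_kmers`.
#' @export
reference_proportions <- function(graph, namespace = "default") {
  stopifnot(inherits(graph, "dbg_graph"))
  reg <- ns_colors(graph, namespace)
  sm <- cpp_dbg_color_summary(graph$ptr, as.integer(reg$color))
  if (sm$total_coverage == 0) {
    warning("no colored k-mers in namespace '", namespace, "'")
    return(tibble(color = integer(), reference = character(),
                  matched_kmers = numeric(), unique_kmers = numeric(),
                  mode_unique = numeric(), observations = numeric(),
                  proportion = numeric(), no_unique_kmers = logical()))
  }
  matched <- as_tibble(sm$matched)
  uh <- as_tibble(sm$unique_hist)
  # per-color mode over uniquely colored k-mers; ties break low (the
  # histogram arrives sorted by (color, coverage))
  modes <- uh |>
    group_by(.data$color) |>
    summarise(unique_kmers = sum(.data$n_kmers),
              mode_unique = .data$coverage[which.max(.data$n_kmers)][1],
              .groups = "drop")
  out <- tibble(color = reg$color, reference = reg$reference) |>
    left_join(matched, by = "color") |>
    left_join(modes, by = "color") |>
    mutate(
      matched_kmers = dplyr::coalesce(.data$n_kmers, 0),
      unique_kmers = dplyr::coalesce(.data$unique_kmers, 0),
      mode_unique = dplyr::coalesce(.data$mode_unique, 0),
      observations = .data$matched_kmers * .data$mode_unique,
      proportion = .data$observations / sm$total_coverage,
      no_unique_kmers = .data$unique_kmers == 0
    ) |>
    select("color", "reference", "matched_kmers", "unique_kmers",
           "mode_unique", "observations", "proportion", "no_unique_kmers")
  attr(out, "total_observations") <- sm$total_coverage
  out
}

#' Construct a taxonomy tree
#'
#' @param nodes Tibble with `node_id`, `parent_id` (NA or self for the
#'   root), `rank` (one of root, kingdom, phylum, class, order, family,
#'   genus, species) and `name`.
#' @param color_map Optional tibble mapping `reference` names to
#'   `node_id` leaves.
#' @return A `taxonomy` object.
#' @export
taxonomy <- function(nodes, color_map = NULL) {
  nodes <- as_tibble(nodes)
  ranks <- c("root", "kingdom", "phylum", "class", "order", "family",
             "genus", "species")
  stopifnot(all(c("node_id", "parent_id", "rank", "name") %in% names(nodes)))
  if (!all(nodes$rank %in% ranks)) {
    stop("unknown rank(s): ", paste(setdiff(nodes$rank, ranks), collapse = ", "))
  }
  root <- nodes$node_id[is.na(nodes$parent_id) | nodes$parent_id == nodes$node_id]
  if (length(root) != 1L) stop("taxonomy must have exactly one root")
  parent <- setNames(nodes$parent_id, as.character(nodes$node_id))
  parent[as.character(root)] <- NA
  # parent rank must strictly precede child rank
  ri <- setNames(match(nodes$rank, ranks), as.character(nodes$node_id))
  ok <- is.na(parent) | ri[as.character(parent)] < ri
  if (!all(ok, na.rm = TRUE)) {
    stop("rank order violated at node(s): ",
         paste(utils::head(nodes$node_id[!ok], 3), collapse = ", "))
  }
  depth <- setNames(integer(nrow(nodes)), as.character(nodes$node_id))
  for (id in as.character(nodes$node_id)) {
    d <- 0L; cur <- id
    while (!is.na(parent[cur])) { cur <- as.character(parent[cur]); d <- d + 1L }
    depth[id] <- d
  }
  structure(list(nodes = nodes, parent = parent, depth = depth,
                 root = root, ranks = ranks, color_map = color_map),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("taxonomy: ", nrow(x$nodes), " nodes, root = ", x$root, "\n", sep = "")
  print(table(x$nodes$rank))
  invisible(x)
}

#' Read a taxonomy from TSV
#'
#' Expects tab-separated columns node id, parent id, rank, name (header
#' line prefixed with `#`). The root's parent may be empty, `NA` or the
#' root's own id.
#'
#' @param path Taxonomy TSV path.
#' @param color_map_path Optional reference-to-taxon TSV (`reference`,
#'   `node_id`).
#' @return A `taxonomy`.
#' @export
read_taxonomy <- function(path, color_map_path = NULL) {
  nodes <- read_tsv_hash(path)
  names(nodes)[1:4] <- c("node_id", "parent_id", "rank", "name")
  cm <- if (!is.null(color_map_path)) {
    m <- read_tsv_hash(color_map_path)
    names(m)[1:2] <- c("reference", "node_id")
    m
  }
  taxonomy(nodes, cm)
}

#' Write a taxonomy (and optional color map) to TSV
#' @param tax A `taxonomy`.
#' @param path Nodes TSV path.
#' @param color_map_path Optional path for the reference-to-node map.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path, color_map_path = NULL) {
  write_tsv_hash(tax$nodes, path)
  if (!is.null(color_map_path) && !is.null(tax$color_map)) {
    write_tsv_hash(tax$color_map, color_map_path)
  }
  invisible(path)
}

#' Build a taxonomy from Greengenes-style lineage strings
#'
#' Converts strings like `"k__Bacteria;p__Firmicutes;...;s__species"` into
#' a taxonomy whose leaves are the input references. Empty fields
#' (`g__`) end the lineage at the last named rank.
#'
#' @param lineages Named character vector: names are reference ids,
#'   values are semicolon-separated lineages with `k__`/`p__`/... prefixes.
#' @return A `taxonomy` with a `color_map` from reference to leaf node.
#' @export
taxonomy_from_lineages <- function(lineages) {
  prefixes <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                f = "family", g = "genus", s = "species")
  nodes <- tibble(node_id = 1L, parent_id = NA_integer_, rank = "root",
                  name = "root")
  index <- new.env(parent = emptyenv())  # "parent|rank|name" -> node id
  nxt <- 2L
  leaf <- integer(length(lineages))
  for (i in seq_along(lineages)) {
    fields <- strsplit(lineages[[i]], ";", fixed = TRUE)[[1]]
    cur <- 1L
    for (f in fields) {
      f <- trimws(f)
      pre <- substr(f, 1, 1); nm <- sub("^[kpcofgs]__", "", f)
      if (!pre %in% names(prefixes) || nm == "") break
      key <- paste(cur, pre, nm, sep = "|")
      id <- index[[key]]
      if (is.null(id)) {
        id <- nxt; nxt <- nxt + 1L
        index[[key]] <- id
        nodes <- bind_rows(nodes, tibble(node_id = id, parent_id = cur,
                                         rank = prefixes[[pre]], name = nm))
      }
      cur <- id
    }
    leaf[i] <- cur
  }
  taxonomy(nodes, tibble(reference = names(lineages), node_id = leaf))
}

#' Nearest common ancestor of a color set
#'
#' A single color classifies at its own node; several colors classify at
#' the deepest node ancestral to all of their nodes. Classification walks
#' the two current nodes up level by level after equalizing depths, which
#' is exact on a tree.
#'
#' @param colors Color ids (or reference names when `tax$color_map` maps
#'   names) observed on one k-mer.
#' @param tax A `taxonomy`.
#' @param color_nodes Named vector translating each color to a `node_id`;
#'   defaults to `tax$color_map` (reference -> node).
#' @return The `node_id` of the nearest common ancestor.
#' @export
lca_assign <- function(colors, tax, color_nodes = NULL) {
  stopifnot(inherits(tax, "taxonomy"))
  if (is.null(color_nodes) && !is.null(tax$color_map)) {
    color_nodes <- setNames(tax$color_map$node_id, tax$color_map$reference)
  }
  nodes <- if (is.null(color_nodes)) colors else {
    miss <- !as.character(colors) %in% names(color_nodes)
    if (any(miss)) stop("color not mapped to a taxon: ", colors[miss][1])
    unname(color_nodes[as.character(colors)])
  }
  lca_nodes(tax, nodes)
}

lca_nodes <- function(tax, nodes) {
  if (length(nodes) == 0L) stop("empty color set")
  bad <- !as.character(nodes) %in% names(tax$parent)
  if (any(bad)) stop("unknown taxonomy node: ", nodes[bad][1])
  Reduce(function(a, b) lca_pair(tax, a, b), nodes)
}

lca_pair <- function(tax, a, b) {
  a <- as.character(a); b <- as.character(b)
  da <- tax$depth[a]; db <- tax$depth[b]
  while (da > db) { a <- as.character(tax$parent[a]); da <- da - 1L }
  while (db > da) { b <- as.character(tax$parent[b]); db <- db - 1L }
  while (a != b) {
    a <- as.character(tax$parent[a]); b <- as.character(tax$parent[b])
  }
  nid <- tax$nodes$node_id
  nid[match(a, as.character(nid))]
}

#' Taxonomic profile of colored coverage
#'
#' Every colored vertex contributes its full coverage depth to the
#' nearest common ancestor of its color set's taxa: k-mers specific to
#' one reference count at that species, k-mers shared across references
#' move up to the deepest taxon containing them all. Per-rank tables
#' report, for every node of the rank, the subtree sum of assigned
#' observations plus an `unclassified` bucket for coverage assigned
#' above that rank. The sum of directly assigned observations equals the
#' sum of colored-vertex coverages exactly (integer conservation).
#'
#' @param graph A colored `dbg_graph`.
#' @param tax A `taxonomy` whose `color_map` covers every reference of
#'   the namespace.
#' @param namespace Namespace of the coloring.
#' @return A `taxonomic_profile`: list with `nodes` (per-node direct and
#'   subtree observations and proportions), `ranks` (per-rank rollup with
#'   unclassified buckets) and `total_observations`.
#' @export
taxonomic_profile <- function(graph, tax, namespace = "default") {
  stopifnot(inherits(graph, "dbg_graph"), inherits(tax, "taxonomy"))
  reg <- ns_colors(graph, namespace)
  cm <- setNames(tax$color_map$node_id, tax$color_map$reference)
  miss <- !reg$reference %in% names(cm)
  if (any(miss)) stop("reference without a taxon mapping: ", reg$reference[miss][1])
  color_node <- setNames(unname(cm[reg$reference]), as.character(reg$color))
  sm <- cpp_dbg_color_summary(graph$ptr, as.integer(reg$color))
  direct <- setNames(numeric(nrow(tax$nodes)), as.character(tax$nodes$node_id))
  for (i in seq_along(sm$sets)) {
    cs <- sm$sets[[i]]
    node <- lca_nodes(tax, unname(color_node[as.character(cs)]))
    direct[as.character(node)] <- direct[as.character(node)] + sm$set_coverage[i]
  }
  total <- sm$total_coverage
  # subtree sums: accumulate children into parents, deepest first
  subtree <- direct
  ord <- order(tax$depth[as.character(tax$nodes$node_id)], decreasing = TRUE)
  for (id in as.character(tax$nodes$node_id)[ord]) {
    p <- tax$parent[id]
    if (!is.na(p)) subtree[as.character(p)] <- subtree[as.character(p)] + subtree[id]
  }
  nodes <- tax$nodes |>
    mutate(direct_obs = unname(direct[as.character(.data$node_id)]),
           subtree_obs = unname(subtree[as.character(.data$node_id)]),
           proportion = if (total > 0) .data$subtree_obs / total else 0)
  rank_tables <- lapply(setdiff(tax$ranks, "root"), function(r) {
    at <- nodes |> filter(.data$rank == r) |>
      select("node_id", "name", "rank", observations = "subtree_obs")
    uncl <- total - sum(at$observations)
    bind_rows(at, tibble(node_id = NA_integer_, name = "unclassified",
                         rank = r, observations = uncl)) |>
      mutate(proportion = if (total > 0) .data$observations / total else 0)
  })
  structure(list(nodes = nodes, ranks = bind_rows(rank_tables),
                 total_observations = total, namespace = namespace),
            class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat("taxonomic profile: ", x$total_observations, " k-mer observations\n", sep = "")
  top <- x$nodes |> filter(.data$direct_obs > 0) |>
    arrange(desc(.data$direct_obs)) |> utils::head(8)
  print(select(top, "node_id", "name", "rank", "direct_obs", "subtree_obs"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.taxonomic_profile <- function(x, ...) x$nodes

#' @exportS3Method generics::glance
glance.taxonomic_profile <- function(x, ...) {
  tibble(total_observations = x$total_observations,
         n_nodes_hit = sum(x$nodes$direct_obs > 0),
         namespace = x$namespace)
}

#' @exportS3Method ggplot2::autoplot
autoplot.taxonomic_profile <- function(object, rank = "phylum", top_n = 12, ...) {
  df <- object$ranks |> filter(.data$rank == !!rank) |>
    arrange(desc(.data$observations)) |> utils::head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$name, .data$observations),
                                   y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proportion of k-mer observations",
                  title = paste("rank:", rank)) +
    ggplot2::theme_minimal()
}

#' Gene-ontology term profile of colored coverage
#'
#' The graph is expected to be colored with coding sequences (CDS) in
#' their own namespace. Every colored vertex adds its coverage depth once
#' to each distinct GO term annotating any of its colors; a vertex whose
#' colors carry no annotation at all is counted in an `unannotated` row.
#' Terms are reported grouped by ontology domain and sorted by
#' observations. Terms are counted flat -- no ancestor propagation along
#' the GO DAG.
#'
#' @param graph A `dbg_graph` colored with CDS sequences.
#' @param go_map Tibble mapping `cds` (reference names of the namespace)
#'   to `go_id` and `domain` (biological_process, cellular_component,
#'   molecular_function).
#' @param namespace CDS namespace (default `"cds"`).
#' @return Tibble with `go_id`, `domain`, `observations`, `proportion`.
#' @export
ontology_profile <- function(graph, go_map, namespace = "cds") {
  stopifnot(inherits(graph, "dbg_graph"))
  reg <- ns_colors(graph, namespace)
  go_map <- as_tibble(go_map)
  stopifnot(all(c("cds", "go_id", "domain") %in% names(go_map)))
  sm <- cpp_dbg_color_summary(graph$ptr, as.integer(reg$color))
  color_ref <- setNames(reg$reference, as.character(reg$color))
  terms_of <- split(paste(go_map$go_id, go_map$domain, sep = "\r"), go_map$cds)
  acc <- new.env(parent = emptyenv())
  unannotated <- 0
  for (i in seq_along(sm$sets)) {
    refs <- color_ref[as.character(sm$sets[[i]])]
    terms <- unique(unlist(terms_of[refs], use.names = FALSE))
    cov <- sm$set_coverage[i]
    if (length(terms) == 0L) { unannotated <- unannotated + cov; next }
    for (t in terms) acc[[t]] <- (acc[[t]] %||0% 0) + cov
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- tibble(
    go_id = vapply(parts, `[`, character(1), 1),
    domain = vapply(parts, `[`, character(1), 2),
    observations = vapply(keys, function(k) acc[[k]], numeric(1),
                          USE.NAMES = FALSE)
  )
  if (unannotated > 0) {
    out <- bind_rows(out, tibble(go_id = "unannotated", domain = "unannotated",
                                 observations = unannotated))
  }
  total <- sm$total_coverage
  out |>
    mutate(proportion = if (total > 0) .data$observations / total else 0) |>
    arrange(.data$domain, desc(.data$observations))
}

`%||0%` <- function(a, b) if (is.null(a)) b else a
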