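#' Place contigs on reference genomes with exact anchors
#'
#' Finds maximal exact matches of at least `anchor_min` nucleotides on
#' both strands (as maximal runs of matching k-mer windows), then chains
#' colinear, non-overlapping anchors per (reference, strand) and keeps the
#' best chain for each. Substitutions in a contig are tolerated by
#' chaining across the mismatch gap; the chain's anchor coverage of the
#' contig is its breadth. This exact-anchor placement stands in for
#' inexact alignment and is adequate for truth-aware evaluation of
#' low-error synthetic data.
#'
#' @param contigs Character vector / tibble / FASTA path of contigs.
#' @param references Same input forms for the reference genomes.
#' @param anchor_min Minimum anchor length (default 31).
#' @return Placements tibble: `contig`, `reference`, `strand`,
#'   `contig_start`, `contig_end`, `ref_start`, `ref_end`, `n_anchors`,
#'   `anchor_bases`, `breadth` (anchored fraction of the contig). One row
#'   per (contig, reference, strand) best chain; 0-based half-open
#'   coordinates.
#' @export
align_contigs <- function(contigs, references, anchor_min = 31L) {
  ctg <- as_named_sequences(contigs, "contig")
  ref <- as_named_sequences(references, "ref")
  anc <- as_tibble(cpp_exact_anchors(unname(ctg), unname(ref),
                                     as.integer(anchor_min)))
  empty <- tibble(contig = character(), reference = character(),
                  strand = character(), contig_start = numeric(),
                  contig_end = numeric(), ref_start = numeric(),
                  ref_end = numeric(), n_anchors = integer(),
                  anchor_bases = numeric(), breadth = numeric())
  if (nrow(anc) == 0L) return(empty)
  clen <- nchar(unname(ctg))
  chains <- anc |>
    group_by(.data$query, .data$reference, .data$strand) |>
    dplyr::group_modify(function(df, key) chain_anchors_all(df, key$strand)) |>
    ungroup()
  chains |>
    mutate(contig = names(ctg)[.data$query],
           reference = names(ref)[.data$reference],
           strand = ifelse(.data$strand > 0, "+", "-"),
           breadth = .data$anchor_bases / clen[.data$query]) |>
    select("contig", "reference", "strand", "contig_start", "contig_end",
           "ref_start", "ref_end", "n_anchors", "anchor_bases", "breadth") |>
    arrange(.data$contig, desc(.data$breadth))
}

# colinear chains of anchors by total anchored bases (weighted LIS),
# extracted greedily: best chain first, then the best chain among the
# remaining anchors, and so on -- a contig wrapping a circular origin
# yields its two abutting chains this way
chain_anchors_all <- function(df, strand, max_chains = 25L) {
  o <- order(df$query_start, df$ref_start)
  qs <- df$query_start[o]; qe <- df$query_end[o]
  rs <- df$ref_start[o]; re <- df$ref_end[o]
  len <- df$length[o]
  out <- list()
  remaining <- seq_along(qs)
  while (length(remaining) && length(out) < max_chains) {
    n <- length(remaining)
    q1 <- qs[remaining]; q2 <- qe[remaining]
    r1 <- rs[remaining]; r2 <- re[remaining]
    ln <- len[remaining]
    best <- ln; prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        ok_q <- q1[i] >= q2[j]
        ok_r <- if (strand > 0) r1[i] >= r2[j] else r2[i] <= r1[j]
        if (ok_q && ok_r && best[j] + ln[i] > best[i]) {
          best[i] <- best[j] + ln[i]
          prev[i] <- j
        }
      }
    }
    end <- which.max(best)
    idx <- integer(0); cur <- end
    while (!is.na(cur)) { idx <- c(cur, idx); cur <- prev[cur] }
    out[[length(out) + 1L]] <- tibble(
      contig_start = q1[idx[1]], contig_end = q2[idx[length(idx)]],
      ref_start = min(r1[idx]), ref_end = max(r2[idx]),
      n_anchors = length(idx), anchor_bases = best[end])
    remaining <- remaining[-idx]
  }
  bind_rows(out)
}

as_named_sequences <- function(x, prefix) {
  if (inherits(x, "dbg_assembly")) return(setNames(x$contigs$sequence, x$contigs$name))
  if (inherits(x, "DNAStringSet")) return(setNames(as.character(x), names(x)))
  if (is.data.frame(x)) {
    nm <- if ("name" %in% names(x)) x$name else if ("id" %in% names(x)) x$id
    else if ("genome" %in% names(x)) x$genome else NULL
    s <- setNames(as.character(x$sequence), nm)
    if (is.null(nm)) names(s) <- paste0(prefix, "_", seq_along(s))
    return(s)
  }
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x)) {
    r <- read_sequences(x)
    return(setNames(r$sequence, r$id))
  }
  s <- setNames(as.character(x), names(x))
  if (is.null(names(s))) names(s) <- paste0(prefix, "_", seq_along(s))
  s
}

#' Classify misassembled contigs
#'
#' A contig of at least `min_len` nucleotides passes when its best single
#' placement covers at least `breadth_cut` (default 98%) of its length,
#' or -- the circular-genome exemption -- when it places in exactly two
#' chains abutting the start and the end of one reference with combined
#' breadth at least `breadth_cut`. Everything else is misassembled.
#'
#' @param contigs,references Sequence inputs as in [align_contigs()].
#' @param min_len Evaluation floor (default 500 nt).
#' @param breadth_cut Required breadth (default 0.98).
#' @param anchor_min Anchor length floor.
#' @param end_slack Distance (nt) within which a placement counts as
#'   touching a reference end for the circular exemption (default
#'   `anchor_min`).
#' @return A `misassembly_report`: list with `verdicts` tibble (`contig`,
#'   `length`, `best_breadth`, `circular`, `misassembled`),
#'   `n_evaluated`, `n_misassembled`.
#' @export
classify_misassemblies <- function(contigs, references, min_len = 500L,
                                   breadth_cut = 0.98, anchor_min = 31L,
                                   end_slack = NULL) {
  if (is.null(end_slack)) end_slack <- anchor_min
  ctg <- as_named_sequences(contigs, "contig")
  ctg <- ctg[nchar(ctg) >= min_len]
  ref <- as_named_sequences(references, "ref")
  rlen <- setNames(nchar(ref), names(ref))
  if (length(ctg) == 0L) {
    return(structure(list(verdicts = tibble(contig = character(),
                                            length = integer(),
                                            best_breadth = numeric(),
                                            circular = logical(),
                                            misassembled = logical()),
                          n_evaluated = 0L, n_misassembled = 0L),
                     class = "misassembly_report"))
  }
  pl <- align_contigs(ctg, ref, anchor_min = anchor_min)
  verdicts <- purrr::map_dfr(names(ctg), function(nm) {
    mine <- pl[pl$contig == nm, ]
    len <- nchar(ctg[[nm]])
    best <- if (nrow(mine)) max(mine$breadth) else 0
    circ <- FALSE
    if (best < breadth_cut && nrow(mine) == 2L &&
        length(unique(mine$reference)) == 1L) {
      L <- rlen[[mine$reference[1]]]
      touches_start <- mine$ref_start <= end_slack
      touches_end <- mine$ref_end >= L - end_slack
      wraps <- (touches_start[1] && touches_end[2]) ||
        (touches_start[2] && touches_end[1])
      combined <- sum(mine$anchor_bases) / len
      circ <- wraps && combined >= breadth_cut
    }
    tibble(contig = nm, length = len, best_breadth = best, circular = circ,
           misassembled = best < breadth_cut && !circ)
  })
  structure(list(verdicts = verdicts, n_evaluated = nrow(verdicts),
                 n_misassembled = sum(verdicts$misassembled)),
            class = "misassembly_report")
}

#' @export
print.misassembly_report <- function(x, ...) {
  cat("misassembly evaluation: ", x$n_misassembled, " / ", x$n_evaluated,
      " contigs misassembled", sep = "")
  if (x$n_evaluated > 0) {
    cat(" (", sprintf("%.2f%%", 100 * x$n_misassembled / x$n_evaluated), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.misassembly_report <- function(x, ...) x$verdicts

#' @exportS3Method generics::glance
glance.misassembly_report <- function(x, ...) {
  tibble(n_evaluated = x$n_evaluated, n_misassembled = x$n_misassembled,
         rate = if (x$n_evaluated > 0) x$n_misassembled / x$n_evaluated else NA_real_)
}

#' Breadth of assembly per reference genome
#'
#' The fraction of each reference covered by the union of all placement
#' intervals of the contigs -- overlapping placements count once.
#'
#' @param references,contigs Sequence inputs as in [align_contigs()].
#' @param anchor_min Anchor length floor.
#' @param placements Optionally precomputed [align_contigs()] output.
#' @return Tibble with `reference`, `length`, `covered`, `breadth`.
#' @export
genome_breadth <- function(references, contigs, anchor_min = 31L,
                           placements = NULL) {
  ref <- as_named_sequences(references, "ref")
  if (is.null(placements)) {
    placements <- align_contigs(contigs, ref, anchor_min = anchor_min)
  }
  purrr::map_dfr(names(ref), function(nm) {
    mine <- placements[placements$reference == nm, ]
    L <- nchar(ref[[nm]])
    covered <- if (nrow(mine) == 0L) 0 else {
      ir <- IRanges::reduce(IRanges::IRanges(start = mine$ref_start + 1,
                                             end = mine$ref_end))
      sum(IRanges::width(ir))
    }
    tibble(reference = nm, length = L, covered = covered,
           breadth = covered / L)
  })
}

#' Standard assembly statistics
#'
#' Computed over sequences of at least `floor` nucleotides. N50 is the
#' largest length L such that sequences of length >= L sum to at least
#' half the total.
#'
#' @param sequences Character vector / tibble / FASTA path / assembly.
#' @param floor Reporting floor in nt (default 100).
#' @return One-row tibble: `count`, `total`, `average`, `n50`, `longest`.
#' @export
assembly_stats <- function(sequences, floor = 100L) {
  s <- as_sequence_vector(sequences)
  lens <- sort(nchar(s)[nchar(s) >= floor], decreasing = TRUE)
  if (length(lens) == 0L) {
    return(tibble(count = 0L, total = 0, average = 0, n50 = 0, longest = 0))
  }
  half <- sum(lens) / 2
  n50 <- lens[which(cumsum(lens) >= half)[1]]
  tibble(count = length(lens), total = sum(lens),
         average = mean(lens), n50 = n50, longest = lens[1])
}

#' Plot per-genome assembly breadth
#'
#' @param breadth Output of [genome_breadth()].
#' @param threshold Reference line (default 0.95).
#' @return A ggplot object.
#' @export
plot_genome_breadth <- function(breadth, threshold = 0.95) {
  ggplot2::ggplot(breadth, ggplot2::aes(x = stats::reorder(.data$reference,
                                                           .data$breadth),
                                        y = .data$breadth)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "breadth of coverage") +
    ggplot2::theme_minimal()
}
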