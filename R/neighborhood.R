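# Operon prediction, divergon detection and neighborhood extraction.
#
# "Co-transcription" is operationalised purely as co-directionality plus an
# intergenic-distance rule (default 100 nt): the data carry no promoter
# model, so shared-promoter membership is approximated by proximity.
# Overlapping genes (negative distance) always satisfy the rule — overlap
# is stronger evidence of co-transcription than a short gap.

#' Intergenic distance between two genes
#'
#' Distance in nt between the end of the left gene and the start of the
#' right gene under 0-based half-open coordinates: `g2_start - g1_end`.
#' Negative for overlapping genes, 0 for book-ended genes.
#'
#' @param genes Gene tibble (two or more rows used pairwise), or `NULL`
#'   when `g1`/`g2` are given.
#' @param g1,g2 `gene_id`s of the left and right gene (must share a
#'   contig; `g1` must not start after `g2`).
#' @return Integer distance in nt.
#' @examples
#' g <- tibble::tibble(gene_id = c("a", "b"), contig_id = "c",
#'                     start = c(100L, 250L), end = c(200L, 350L),
#'                     strand = "+")
#' intergenic_distance(g, "a", "b")  # 50
#' @export
intergenic_distance <- function(genes, g1, g2) {
  assert_genes_df(genes)
  a <- genes[genes$gene_id == g1, ]
  b <- genes[genes$gene_id == g2, ]
  if (nrow(a) != 1 || nrow(b) != 1) stop("unknown gene id", call. = FALSE)
  if (a$contig_id != b$contig_id) {
    stop("genes lie on different contigs: ", a$contig_id, " vs ", b$contig_id,
         call. = FALSE)
  }
  if (a$start > b$start) stop("g1 must not start after g2", call. = FALSE)
  as.integer(b$start - a$end)
}

#' Predict operons by strand and intergenic distance
#'
#' Partitions the genes of every contig into maximal runs of co-directional
#' genes whose consecutive intergenic distances do not exceed `max_gap`
#' (default 100 nt). Every gene lands in exactly one operon; single genes
#' form singleton operons. Within an operon, genes are listed 5' to 3'
#' (reversed genomic order on the minus strand). On a circular contig a
#' run may wrap the origin: if the first and last runs are co-directional
#' and the wrap gap passes the rule they are merged and reported once,
#' anchored at the 5'-most gene. Operon ids are assigned in genomic order.
#'
#' @param genes Gene tibble ([read_genbank()] / [generate_genome()]).
#' @param max_gap Maximum intergenic distance (nt) within an operon.
#' @return Tibble with one row per operon: `operon_id`, `contig_id`,
#'   `strand`, `gene_ids` (list column, 5' to 3'), `n_genes`, `start`,
#'   `end`, `wraps_origin`.
#' @examples
#' gnm <- generate_genome(genome_plan(seed = 1, n_background_genes = 6,
#'   elements = list(operon_element(c("A", "B", "C"), c(20, 40)))))
#' predict_operons(gnm$genes)
#' @export
predict_operons <- function(genes, max_gap = 100) {
  assert_genes_df(genes)
  out <- list()
  for (cid in unique(genes$contig_id)) {
    g <- dplyr::arrange(dplyr::filter(genes, .data$contig_id == cid), .data$start)
    n <- nrow(g)
    if (n == 0) next
    # cut before gene i+1 iff strand changes or gap exceeds the rule
    cut <- rep(TRUE, n)  # cut[i]: boundary before gene i; cut[1] handled by wrap
    if (n > 1) {
      gap <- g$start[-1] - g$end[-n]
      cut[2:n] <- g$strand[-1] != g$strand[-n] | gap > max_gap
    }
    run_id <- cumsum(cut)
    runs <- split(seq_len(n), run_id)
    circ <- "circular" %in% names(g) && isTRUE(g$circular[1]) &&
      "contig_length" %in% names(g) && !is.na(g$contig_length[1])
    wrapped <- FALSE
    if (circ && length(runs) > 1) {
      first <- runs[[1]]
      last <- runs[[length(runs)]]
      wrap_gap <- g$contig_length[1] - g$end[max(last)] + g$start[min(first)]
      if (g$strand[min(first)] == g$strand[max(last)] && wrap_gap <= max_gap) {
        runs[[1]] <- c(last, first)  # genomic order across the origin
        runs[[length(runs)]] <- NULL
        wrapped <- TRUE
      }
    }
    ops <- purrr::imap(runs, function(idx, k) {
      strand <- g$strand[idx[1]]
      ids <- g$gene_id[idx]
      if (strand == "-") ids <- rev(ids)
      tibble(
        contig_id = cid, strand = strand, gene_ids = list(ids),
        n_genes = length(idx),
        start = min(g$start[idx]), end = max(g$end[idx]),
        wraps_origin = wrapped && k == "1"
      )
    })
    ops <- dplyr::bind_rows(ops)
    ops <- dplyr::arrange(ops, .data$start)
    out[[cid]] <- ops
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(operon_id = character(), contig_id = character(),
                  strand = character(), gene_ids = list(), n_genes = integer(),
                  start = integer(), end = integer(), wraps_origin = logical()))
  }
  res$operon_id <- pad_id("op", seq_len(nrow(res)))
  dplyr::relocate(res, "operon_id")
}

#' Find head-to-head (divergon) gene pairs
#'
#' Reports every pair of genomically adjacent genes with strand pattern
#' (-, +): both 5' ends face each other across the intergenic region, the
#' arrangement compatible with a shared bidirectional promoter. The head
#' gap is the distance between the facing gene boundaries and must be
#' non-negative and at most `max_head_gap`.
#'
#' @param genes Gene tibble.
#' @param max_head_gap Maximum distance (nt) between the facing 5' ends.
#' @return Tibble: `contig_id`, `left_gene_id`, `right_gene_id`, `head_gap`.
#' @export
find_divergons <- function(genes, max_head_gap = 300) {
  assert_genes_df(genes)
  out <- list()
  for (cid in unique(genes$contig_id)) {
    g <- dplyr::arrange(dplyr::filter(genes, .data$contig_id == cid), .data$start)
    n <- nrow(g)
    if (n < 2) next
    i <- seq_len(n - 1)
    ok <- g$strand[i] == "-" & g$strand[i + 1] == "+"
    gap <- g$start[i + 1] - g$end[i]
    keep <- ok & gap >= 0 & gap <= max_head_gap
    if (any(keep)) {
      out[[cid]] <- tibble(
        contig_id = cid,
        left_gene_id = g$gene_id[i][keep],
        right_gene_id = g$gene_id[i + 1][keep],
        head_gap = as.integer(gap[keep])
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(contig_id = character(), left_gene_id = character(),
                  right_gene_id = character(), head_gap = integer())
  }
  res
}

#' Extract the gene neighborhood around an anchor gene
#'
#' Returns up to `k` genes on each side of the anchor in genomic order,
#' truncated at contig ends on linear contigs and wrapped around the
#' origin on circular ones.
#'
#' @param genes Gene tibble.
#' @param anchor_gene_id The anchor's `gene_id`.
#' @param k Number of genes to take on each side.
#' @return Gene tibble of at most `2k + 1` rows, anchor included, in
#'   window order.
#' @export
neighborhood <- function(genes, anchor_gene_id, k = 5) {
  assert_genes_df(genes)
  hit <- genes[genes$gene_id == anchor_gene_id, ]
  if (nrow(hit) != 1) stop("unknown anchor gene: ", anchor_gene_id, call. = FALSE)
  g <- dplyr::arrange(dplyr::filter(genes, .data$contig_id == hit$contig_id),
                      .data$start)
  n <- nrow(g)
  i <- which(g$gene_id == anchor_gene_id)
  circ <- "circular" %in% names(g) && isTRUE(g$circular[1])
  if (circ && n > 1) {
    # window order: k genes upstream (wrapped), anchor, k downstream; a
    # window longer than the contig never repeats a gene
    idx <- ((i - 1 + (-k:k)) %% n) + 1
    idx <- idx[!duplicated(idx)]
  } else {
    idx <- max(1, i - k):min(n, i + k)
  }
  g[idx, ]
}
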