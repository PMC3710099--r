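# Single-linkage homology clustering of neighbor proteins.
#
# Stands in for score-density clustering of neighbor sets: global pairwise
# alignment under a fixed, documented scoring scheme (match +1, mismatch
# -1, gap open -5, gap extend -1 per gapped position; X matches nothing),
# thresholded on identity and coverage, then single linkage. The scoring
# scheme is deliberately matrix-free so results are bit-reproducible;
# substitution-matrix support would be an extension point.

align_sub_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- c(AA20, "X")
      mm <- matrix(-1L, length(letters), length(letters),
                   dimnames = list(letters, letters))
      diag(mm) <- 1L
      mm["X", "X"] <- -1L  # X is never identical, not even to X
      m <<- mm
    }
    m
  }
})

# identity/coverage from two gapped strings of equal width.
# identity: identical columns / columns excluding terminal-gap columns.
# coverage: residues of the shorter sequence inside the terminal-trimmed
# region / full length of the shorter sequence.
alignment_stats <- function(a, b, len_short) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  resid <- ca != "-" & cb != "-"
  both <- which(ca != "-" | cb != "-")
  # terminal gap columns: positions before the first / after the last
  # column where both rows carry a residue
  core <- which(resid)
  if (length(core) == 0) {
    return(list(identity = 0, coverage = 0))
  }
  span <- core[1]:core[length(core)]
  ident <- sum(ca[span] == cb[span] & ca[span] != "-" & ca[span] != "X")
  identity <- ident / length(span)
  short_resid <- sum((if (sum(ca != "-") <= sum(cb != "-")) ca else cb)[span] != "-")
  list(identity = identity, coverage = short_resid / len_short)
}

#' Global pairwise identity and coverage
#'
#' Aligns two protein sequences globally (match +1, mismatch -1, gap
#' opening -5, each gapped position a further -1; X never counts as a
#' match) and reports the fraction of identical columns over the
#' alignment excluding terminal-gap columns, and the coverage of the
#' shorter sequence within that region.
#'
#' @param seq_a,seq_b Protein sequences (non-empty).
#' @param id_a,id_b Optional sequence identifiers for the output row.
#' @return One-row tibble: `id_a`, `id_b`, `score`, `identity`, `coverage`.
#' @examples
#' pairwise_identity("AAAA", "AATA")$identity  # 0.75
#' @export
pairwise_identity <- function(seq_a, seq_b, id_a = "a", id_b = "b") {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seq_a), seq_b,
    substitutionMatrix = align_sub_matrix(),
    gapOpening = 5, gapExtension = 1, type = "global"
  )
  st <- alignment_stats(as.character(Biostrings::alignedPattern(pa)),
                        as.character(Biostrings::alignedSubject(pa)),
                        min(nchar(seq_a), nchar(seq_b)))
  tibble(id_a = id_a, id_b = id_b, score = Biostrings::score(pa),
         identity = st$identity, coverage = st$coverage)
}

# all-vs-all pair scores for a protein set, with the lossless length-ratio
# prefilter: a pair whose shorter/longer length ratio is below the
# coverage threshold can never pass coverage (<= short residues / short
# length is 1, but aligned short residues <= short length and the span is
# >= long length residues...), so it is skipped before alignment.
pair_scores <- function(proteins, coverage_threshold = 0) {
  n <- nrow(proteins)
  rows <- list()
  for (i in seq_len(max(0, n - 1))) {
    js <- (i + 1):n
    li <- nchar(proteins$seq[i])
    lj <- nchar(proteins$seq[js])
    ratio <- pmin(li, lj) / pmax(li, lj)
    js <- js[ratio >= coverage_threshold]
    if (length(js) == 0) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(proteins$seq[js]), proteins$seq[i],
      substitutionMatrix = align_sub_matrix(),
      gapOpening = 5, gapExtension = 1, type = "global"
    )
    ap <- as.character(Biostrings::alignedPattern(pa))
    as_ <- as.character(Biostrings::alignedSubject(pa))
    stats <- purrr::pmap(list(ap, as_, pmin(nchar(proteins$seq[js]), nchar(proteins$seq[i]))),
                         alignment_stats)
    rows[[length(rows) + 1]] <- tibble(
      id_a = proteins$protein_id[i], id_b = proteins$protein_id[js],
      score = Biostrings::score(pa),
      identity = purrr::map_dbl(stats, "identity"),
      coverage = purrr::map_dbl(stats, "coverage")
    )
  }
  if (length(rows) == 0) {
    return(tibble(id_a = character(), id_b = character(), score = numeric(),
                  identity = numeric(), coverage = numeric()))
  }
  dplyr::bind_rows(rows)
}

# iterative union-find with path halving
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Single-linkage clustering of proteins by identity and coverage
#'
#' Two proteins share a cluster iff they are connected by a chain of pairs
#' each passing both the identity and the coverage threshold (single
#' linkage, i.e. connected components of the thresholded pair graph).
#' Output is deterministic: clusters are numbered by their smallest member
#' id, members listed in input order. A lossless length-ratio prefilter
#' skips pairs that cannot reach the coverage threshold.
#'
#' @param proteins Tibble with `protein_id` and `seq`, or a named
#'   character vector of sequences.
#' @param identity_threshold Minimum pairwise identity (fraction).
#' @param coverage_threshold Minimum coverage of the shorter sequence.
#' @return A `hepn_clusters` object: tibble (`protein_id`, `cluster_id`)
#'   with the thresholds and the pair table as attributes. Use [tidy()] /
#'   [glance()] for the pair table and summary.
#' @examples
#' p <- tibble::tibble(protein_id = c("a", "b", "c"),
#'                     seq = c("MKVLAWNE", "MKVLAWNE", "GGGGPPPP"))
#' cluster_proteins(p)
#' @export
cluster_proteins <- function(proteins, identity_threshold = 0.3,
                             coverage_threshold = 0.7) {
  if (is.character(proteins)) {
    proteins <- tibble(protein_id = names(proteins) %||%
                         pad_id("p", seq_along(proteins)),
                       seq = unname(proteins))
  }
  stopifnot(all(c("protein_id", "seq") %in% names(proteins)))
  if (nrow(proteins) == 0) stop("need at least one sequence", call. = FALSE)
  if (any(!nzchar(proteins$seq))) stop("empty sequence", call. = FALSE)
  ps <- pair_scores(proteins, coverage_threshold)
  pass <- ps[ps$identity >= identity_threshold & ps$coverage >= coverage_threshold, ]
  n <- nrow(proteins)
  parent <- uf_new(n)
  idx <- setNames(seq_len(n), proteins$protein_id)
  for (r in seq_len(nrow(pass))) {
    a <- uf_find(parent, idx[[pass$id_a[r]]])
    b <- uf_find(parent, idx[[pass$id_b[r]]])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  # number clusters by smallest member id (lexicographic)
  reps <- vapply(split(proteins$protein_id, root), function(ids) min(ids), character(1))
  ord <- rank(reps, ties.method = "first")
  cluster_of <- setNames(ord, names(reps))
  out <- tibble(
    protein_id = proteins$protein_id,
    cluster_id = pad_id("C", unname(cluster_of[as.character(root)]), 3)
  )
  structure(out,
            class = c("hepn_clusters", class(out)),
            identity_threshold = identity_threshold,
            coverage_threshold = coverage_threshold,
            pairs = ps)
}

#' @export
print.hepn_clusters <- function(x, ...) {
  cat(sprintf("Single-linkage protein clusters (identity >= %.2f, coverage >= %.2f)\n",
              attr(x, "identity_threshold"), attr(x, "coverage_threshold")))
  cat(sprintf("%d proteins in %d clusters\n\n",
              nrow(x), dplyr::n_distinct(x$cluster_id)))
  NextMethod()
}

#' Annotate clusters with a consensus architecture label
#'
#' Labels each cluster with the architecture string shared by a plurality
#' of its members; ties break to the lexicographically smaller string.
#' Members without an architecture count as `"unknown"`.
#'
#' @param clusters `hepn_clusters` (or tibble with `protein_id`,
#'   `cluster_id`).
#' @param architectures Tibble with `protein_id` and `architecture`.
#' @return Tibble: `cluster_id`, `label`, `fraction` (plurality fraction),
#'   `n_members`.
#' @export
annotate_clusters <- function(clusters, architectures) {
  stopifnot(all(c("protein_id", "cluster_id") %in% names(clusters)))
  joined <- dplyr::left_join(as_tibble(clusters)[c("protein_id", "cluster_id")],
                             architectures[c("protein_id", "architecture")],
                             by = "protein_id")
  joined$architecture[is.na(joined$architecture)] <- "unknown"
  joined |>
    dplyr::count(.data$cluster_id, .data$architecture, name = "n") |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$architecture, .by_group = TRUE) |>
    dplyr::summarise(label = .data$architecture[1],
                     fraction = .data$n[1] / sum(.data$n),
                     n_members = sum(.data$n)) |>
    dplyr::arrange(.data$cluster_id)
}

#' @rdname cluster_proteins
#' @param x A `hepn_clusters` object.
#' @param ... Unused.
#' @method tidy hepn_clusters
#' @export
tidy.hepn_clusters <- function(x, ...) {
  attr(x, "pairs")
}

#' @rdname cluster_proteins
#' @method glance hepn_clusters
#' @export
glance.hepn_clusters <- function(x, ...) {
  tibble(
    n_proteins = nrow(x),
    n_clusters = dplyr::n_distinct(x$cluster_id),
    n_singletons = sum(table(x$cluster_id) == 1),
    identity_threshold = attr(x, "identity_threshold"),
    coverage_threshold = attr(x, "coverage_threshold")
  )
}
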