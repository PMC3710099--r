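# Phyletic patterns (family-by-taxon copy numbers) and lineage-specific
# expansions.
#
# A taxon here is a genome/assembly identifier; higher-rank rollups are a
# user-supplied taxon-to-lineage map, never a taxonomy download. The LSE
# rule flags taxa whose copy number is both large in absolute terms and a
# multiple of the background median — the pattern separating, e.g., a
# 46-copy expansion from the typical one-or-two copies per genome.

#' Build a family-by-taxon copy-number matrix
#'
#' Exact tallies of gene-to-family assignments per taxon; rows (families)
#' and columns (taxa) ordered lexicographically, so output is
#' permutation-invariant.
#'
#' @param assignments Tibble with `gene_id`, `family`, `taxon` (each gene
#'   assigned to at most one family; rows with `NA` family are dropped).
#' @return A `phyletic_matrix`: tibble with a `family` column and one
#'   integer column per taxon.
#' @examples
#' a <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                     family = c("F", "F", "G"), taxon = "T1")
#' build_matrix(a)
#' @export
build_matrix <- function(assignments) {
  stopifnot(all(c("gene_id", "family", "taxon") %in% names(assignments)))
  a <- dplyr::filter(as_tibble(assignments), !is.na(.data$family))
  if (anyDuplicated(a$gene_id)) {
    stop("each gene may be assigned to at most one family", call. = FALSE)
  }
  if (nrow(a) == 0) {
    out <- tibble(family = character())
    return(structure(out, class = c("phyletic_matrix", class(out))))
  }
  wide <- a |>
    dplyr::count(.data$family, .data$taxon) |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "n",
                       values_fill = 0L, names_sort = TRUE) |>
    dplyr::arrange(.data$family)
  structure(wide, class = c("phyletic_matrix", class(wide)))
}

phyletic_counts <- function(mat) {
  stopifnot("family" %in% names(mat))
  m <- as.matrix(mat[setdiff(names(mat), "family")])
  rownames(m) <- mat$family
  storage.mode(m) <- "integer"
  m
}

#' Presence/absence projection of a phyletic matrix
#'
#' @param mat A `phyletic_matrix`.
#' @return Same shape with logical presence values.
#' @export
presence_absence <- function(mat) {
  out <- mat
  taxa <- setdiff(names(mat), "family")
  out[taxa] <- lapply(mat[taxa], function(x) x > 0)
  out
}

#' Detect lineage-specific expansions
#'
#' Flags (family, taxon) cells whose copy number is at least `min_copies`
#' and at least `min_fold` times the median copy number of the same family
#' over all *other* taxa (a background median of 0 satisfies the fold
#' rule). The thresholds are deliberate, documented defaults: massive
#' expansions run to dozens of copies against a background of one or two.
#'
#' @param mat A `phyletic_matrix` with at least two taxa.
#' @param min_copies Minimum copy number (default 10).
#' @param min_fold Minimum ratio to the background median (default 5).
#' @return Tibble: `family`, `taxon`, `copy_count`, `background_median`.
#' @export
detect_lse <- function(mat, min_copies = 10, min_fold = 5) {
  m <- phyletic_counts(mat)
  if (ncol(m) < 2) {
    stop("need at least two taxa to define an expansion background",
         call. = FALSE)
  }
  rows <- list()
  for (f in rownames(m)) {
    for (t in colnames(m)) {
      cc <- m[f, t]
      bg <- median(m[f, setdiff(colnames(m), t)])
      if (cc >= min_copies && (bg == 0 || cc >= min_fold * bg)) {
        rows[[length(rows) + 1]] <- tibble(
          family = f, taxon = t, copy_count = as.integer(cc),
          background_median = bg
        )
      }
    }
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    res <- tibble(family = character(), taxon = character(),
                  copy_count = integer(), background_median = numeric())
  }
  dplyr::arrange(res, .data$family, .data$taxon)
}

#' Plot a phyletic matrix as a heatmap
#'
#' @param mat A `phyletic_matrix`.
#' @param log_scale Colour copy numbers on log1p scale.
#' @return A ggplot object.
#' @export
plot_phyletics <- function(mat, log_scale = TRUE) {
  long <- tidyr::pivot_longer(mat, -"family", names_to = "taxon",
                              values_to = "copies")
  if (log_scale) long$fill <- log1p(long$copies) else long$fill <- long$copies
  ggplot2::ggplot(long, ggplot2::aes(.data$taxon, .data$family,
                                     fill = .data$fill)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$copies), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (log_scale) "log1p(copies)" else "copies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
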