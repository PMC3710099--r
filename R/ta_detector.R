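# Toxin-antitoxin dyad detection and defense-category calls for operons.
#
# Type-II TA modules are two co-transcribed genes; the canonical
# arrangement puts the antitoxin 5' of the toxin so the neutralising
# partner is translated first. In MNT-HEPN dyads the MNT (antitoxin)
# nearly always sits 5'. Detection is strict about the two-gene rule:
# larger defense operons go through classify_context() instead.

#' Detect candidate toxin-antitoxin gene dyads
#'
#' Scans every two-gene operon. A dyad is called when one gene carries a
#' domain from the toxin set and the other a domain from the antitoxin
#' set. Orientation is `canonical` when the antitoxin-carrying gene is 5'
#' within the operon's own strand frame (not genomic left/right), else
#' `inverted`. Genes carrying domains from both sets are skipped with the
#' `ambiguous` flag rather than guessed.
#'
#' @param operons Operon tibble from [predict_operons()].
#' @param archs Tibble `protein_id`, `architecture` ([architectures()]).
#' @param genes Gene tibble (used for the intergenic gap).
#' @param toxin_domains,antitoxin_domains Domain role sets.
#' @return Tibble: `operon_id`, `gene_5p`, `gene_3p`, `antitoxin_gene`,
#'   `toxin_gene`, `orientation`, `gap_nt`.
#' @examples
#' gnm <- generate_genome(genome_plan(seed = 7, n_background_genes = 5,
#'   elements = list(ta_dyad(gap_nt = 30))))
#' lib <- domain_library(sentinel_detector("MNT", sentinel_for("MNT")),
#'                       sentinel_detector("HEPN", sentinel_for("HEPN")))
#' ops <- predict_operons(gnm$genes)
#' detect_ta_dyads(ops, architectures(gnm$genes, lib), gnm$genes)
#' @export
detect_ta_dyads <- function(operons, archs, genes,
                            toxin_domains = "HEPN",
                            antitoxin_domains = "MNT") {
  assert_genes_df(genes)
  arch_of <- setNames(archs$architecture, archs$protein_id)
  gene_tab <- setNames(seq_len(nrow(genes)), genes$gene_id)
  rows <- list()
  two <- operons[operons$n_genes == 2, ]
  for (i in seq_len(nrow(two))) {
    ids <- two$gene_ids[[i]]       # already 5' -> 3'
    doms <- purrr::map(ids, function(g) {
      a <- arch_of[g]
      if (is.na(a) || a == "unknown") character() else strsplit(a, "+", fixed = TRUE)[[1]]
    })
    is_tox <- purrr::map_lgl(doms, ~ any(.x %in% toxin_domains))
    is_anti <- purrr::map_lgl(doms, ~ any(.x %in% antitoxin_domains))
    if (any(is_tox & is_anti)) next  # fusion gene: not a dyad partner
    if (sum(is_tox) != 1 || sum(is_anti) != 1 || which(is_tox) == which(is_anti)) next
    anti_gene <- ids[which(is_anti)]
    tox_gene <- ids[which(is_tox)]
    g5 <- genes[gene_tab[[ids[1]]], ]
    g3 <- genes[gene_tab[[ids[2]]], ]
    left <- if (g5$start <= g3$start) g5 else g3
    right <- if (g5$start <= g3$start) g3 else g5
    rows[[length(rows) + 1]] <- tibble(
      operon_id = two$operon_id[i],
      gene_5p = ids[1], gene_3p = ids[2],
      antitoxin_gene = anti_gene, toxin_gene = tox_gene,
      orientation = if (anti_gene == ids[1]) "canonical" else "inverted",
      gap_nt = as.integer(right$start - left$end)
    )
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    res <- tibble(operon_id = character(), gene_5p = character(),
                  gene_3p = character(), antitoxin_gene = character(),
                  toxin_gene = character(), orientation = character(),
                  gap_nt = integer())
  }
  res
}

#' Default defense-category rules
#'
#' A curated, editable mapping from domain names to defense-system
#' categories (restriction-modification, CRISPR-Cas, abortive infection,
#' toxin-antitoxin, phage-growth limitation, tellurite-resistance-like).
#' This table is curation, not computation: edit or replace it for your
#' own domain vocabulary.
#'
#' @return Tibble: `domain`, `category`.
#' @export
default_category_rules <- function() {
  path <- system.file("extdata", "category_rules.tsv", package = "hepnscape")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Classify operon contexts into defense categories
#'
#' Assigns each operon the category supported by the majority of its
#' rule-matched domains; operons with no matched domain fall to
#' `"other"`. Ties break to the lexicographically smaller category and
#' are flagged.
#'
#' @param operons Operon tibble.
#' @param archs Tibble `protein_id`, `architecture`.
#' @param rules Tibble `domain`, `category`
#'   (default [default_category_rules()]).
#' @return Tibble: `operon_id`, `category`, `evidence` (comma-joined
#'   matched domains), `tie`.
#' @export
classify_context <- function(operons, archs, rules = default_category_rules()) {
  arch_of <- setNames(archs$architecture, archs$protein_id)
  cat_of <- setNames(rules$category, rules$domain)
  purrr::map_dfr(seq_len(nrow(operons)), function(i) {
    ids <- operons$gene_ids[[i]]
    doms <- unlist(purrr::map(ids, function(g) {
      a <- arch_of[g]
      if (is.na(a) || a == "unknown") character() else strsplit(a, "+", fixed = TRUE)[[1]]
    }))
    matched <- doms[doms %in% names(cat_of)]
    if (length(matched) == 0) {
      return(tibble(operon_id = operons$operon_id[i], category = "other",
                    evidence = "", tie = FALSE))
    }
    tab <- sort(table(unname(cat_of[matched])), decreasing = TRUE)
    winners <- names(tab)[tab == max(tab)]
    tibble(operon_id = operons$operon_id[i],
           category = sort(winners)[1],
           evidence = paste(sort(unique(matched)), collapse = ","),
           tie = length(winners) > 1)
  })
}
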