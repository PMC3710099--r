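# Synthetic genomes with planted structure and machine-readable truth.
#
# Planted "domains" are realised as fixed sentinel subsequences (18-mers
# over an alphabet free of R and H) so that the architecture module can
# find them with exact detectors and the motif scanner sees no spurious
# Rx4-6H sites. No evolutionary simulation is attempted.

# run code under a seed without disturbing the caller's RNG stream
with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# residues that can never create an Rx4-6H site
SENTINEL_ALPHABET <- setdiff(AA20, c("R", "H"))

#' Deterministic sentinel subsequence for a domain label
#'
#' Maps a domain name to a fixed 18-residue subsequence over an alphabet
#' containing neither R nor H, so planted domains are exactly detectable
#' and cannot fabricate active-site motifs. The mapping is a pure function
#' of the label (a small linear congruential generator seeded from the
#' label's character codes), stable across sessions.
#'
#' @param label Domain name (e.g. `"HEPN"`, `"MNT"`).
#' @param width Sentinel length in residues (default 18).
#' @return A protein subsequence of length `width`.
#' @examples
#' sentinel_for("HEPN")
#' @export
sentinel_for <- function(label, width = 18) {
  state <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 2147483647
  if (state == 0) state <- 1
  out <- character(width)
  for (i in seq_len(width)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- SENTINEL_ALPHABET[(state %% length(SENTINEL_ALPHABET)) + 1]
  }
  paste(out, collapse = "")
}

#' Planted-element constructors for genome plans
#'
#' Building blocks for [genome_plan()]. `ta_dyad()` plants a two-gene
#' toxin-antitoxin module with the antitoxin 5' of the toxin (the canonical
#' type-II arrangement); `operon_element()` plants a co-directional gene
#' run with the given intergenic gaps; `divergon_element()` plants a
#' head-to-head pair (strands -,+) sharing a candidate bidirectional
#' promoter region; `fusion_element()` plants a single multidomain protein.
#'
#' @param antitoxin_label,toxin_label Domain names for the two dyad genes.
#' @param gap_nt Intergenic distance between the dyad genes (nt; may be
#'   negative down to -50 for overlapping genes).
#' @param strand `"+"` or `"-"` for co-directional elements.
#' @param labels Character vector of domain names, one per operon gene
#'   (5' to 3').
#' @param gaps_nt Integer vector of `length(labels) - 1` intergenic gaps.
#' @param left_label,right_label Domain names of the divergon genes
#'   (genomic left gene on `-`, right gene on `+`).
#' @param head_gap_nt Distance between the facing 5' ends (nt, >= 0).
#' @param domain_labels Domains of the fusion protein, N to C.
#' @return An element spec (a list) consumed by [genome_plan()].
#' @name planted_elements
NULL

#' @rdname planted_elements
#' @export
ta_dyad <- function(antitoxin_label = "MNT", toxin_label = "HEPN",
                    gap_nt = 30, strand = "+") {
  structure(list(type = "ta_dyad", antitoxin_label = antitoxin_label,
                 toxin_label = toxin_label, gap_nt = as.integer(gap_nt),
                 strand = strand),
            class = "hepn_element")
}

#' @rdname planted_elements
#' @export
operon_element <- function(labels, gaps_nt, strand = "+") {
  if (length(gaps_nt) != length(labels) - 1) {
    stop("need length(labels) - 1 gaps", call. = FALSE)
  }
  structure(list(type = "operon", labels = labels,
                 gaps_nt = as.integer(gaps_nt), strand = strand),
            class = "hepn_element")
}

#' @rdname planted_elements
#' @export
divergon_element <- function(left_label = "REase", right_label = "Methylase",
                             head_gap_nt = 150) {
  if (head_gap_nt < 0) stop("head_gap_nt must be >= 0", call. = FALSE)
  structure(list(type = "divergon", left_label = left_label,
                 right_label = right_label,
                 head_gap_nt = as.integer(head_gap_nt)),
            class = "hepn_element")
}

#' @rdname planted_elements
#' @export
fusion_element <- function(domain_labels = c("MNT", "HEPN")) {
  if (length(domain_labels) < 2) stop("a fusion needs >= 2 domains", call. = FALSE)
  structure(list(type = "fusion", domain_labels = domain_labels),
            class = "hepn_element")
}

#' Describe a synthetic genome to generate
#'
#' A plan fixes everything [generate_genome()] needs: the seed (which fully
#' determines the output), the number of background genes, the planted
#' elements, and the background intergenic-gap model. Background gaps are
#' drawn from a two-component mixture (short gaps and long gaps straddling
#' the 100-nt operon criterion) so operon prediction is non-trivially
#' exercised; planted elements are separated from their neighbours by gaps
#' drawn from the long component only (> 100 nt), so planted operon
#' boundaries are unambiguous.
#'
#' @param seed Integer seed; identical plans + seeds give identical output.
#' @param n_background_genes Number of unplanted single genes.
#' @param elements List of element specs from [ta_dyad()],
#'   [operon_element()], [divergon_element()], [fusion_element()].
#' @param gap_small,gap_large Ranges (nt) of the short and long background
#'   gap components; `gap_large` must lie above 100 nt.
#' @param p_small Mixture weight of the short component.
#' @param gene_length_range Gene length range in nt (rounded to codons).
#' @param contig_id Contig name.
#' @param circular Mark the contig circular.
#' @return A `genome_plan` object.
#' @examples
#' plan <- genome_plan(seed = 1, n_background_genes = 8,
#'                     elements = list(ta_dyad(gap_nt = 30)))
#' gnm <- generate_genome(plan)
#' gnm$truth
#' @export
genome_plan <- function(seed, n_background_genes = 30, elements = list(),
                        gap_small = c(5, 80), gap_large = c(150, 400),
                        p_small = 0.35, gene_length_range = c(300, 900),
                        contig_id = "ctg1", circular = FALSE) {
  stopifnot(length(gap_small) == 2, length(gap_large) == 2,
            length(gene_length_range) == 2)
  if (gap_large[1] <= 100) stop("gap_large must lie above 100 nt", call. = FALSE)
  for (el in elements) {
    if (!inherits(el, "hepn_element")) stop("elements must be built with the element constructors", call. = FALSE)
    gaps <- switch(el$type,
                   ta_dyad = el$gap_nt,
                   operon = el$gaps_nt,
                   divergon = el$head_gap_nt,
                   fusion = integer())
    if (any(gaps < -50) || any(gaps > 5000)) {
      stop("element gaps must lie in [-50, 5000] nt", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed),
                 n_background_genes = as.integer(n_background_genes),
                 elements = elements, gap_small = gap_small,
                 gap_large = gap_large, p_small = p_small,
                 gene_length_range = as.integer(gene_length_range),
                 contig_id = contig_id, circular = circular),
            class = "genome_plan")
}

# protein for one gene: leading M, optional sentinel domains, optional
# planted Rx4H site when the gene carries a HEPN domain; filler is R/H-free
build_protein <- function(domains, aa_len, plant_rxh = FALSE) {
  filler <- function(n) {
    if (n <= 0) return("")
    paste(sample(SENTINEL_ALPHABET, n, replace = TRUE), collapse = "")
  }
  pieces <- "M"
  dom_truth <- tibble(domain = character(), start = integer(), end = integer())
  pos <- 1L
  for (d in domains) {
    lead <- 6L
    pieces <- c(pieces, filler(lead))
    pos <- pos + lead
    s <- sentinel_for(d)
    dom_truth <- dplyr::bind_rows(dom_truth, tibble(
      domain = d, start = pos, end = pos + nchar(s)
    ))
    pieces <- c(pieces, s)
    pos <- pos + nchar(s)
  }
  motif <- NULL
  if (plant_rxh) {
    lead <- 4L
    pieces <- c(pieces, filler(lead))
    pos <- pos + lead
    spacer <- 4L
    site <- paste0("R", "N", filler(spacer - 1L), "H")
    motif <- list(r_pos = pos, spacer = spacer, h_pos = pos + spacer + 1L)
    pieces <- c(pieces, site)
    pos <- pos + spacer + 2L
  }
  rest <- aa_len - pos
  if (rest < 0) stop("internal: protein shorter than planted content", call. = FALSE)
  pieces <- c(pieces, filler(rest))
  list(seq = paste(pieces, collapse = ""), domains = dom_truth, motif = motif)
}

#' Generate a synthetic annotated contig with truth labels
#'
#' Lays the plan's planted elements and background genes along one contig
#' in a seeded random order, draws background intergenic gaps from the
#' plan's mixture, separates planted elements from their neighbours by
#' long (> 100 nt) gaps, and synthesises a protein for every gene: a
#' sentinel subsequence per planted domain, and a single Rx4H active-site
#' motif in every HEPN-carrying protein. The returned truth table records,
#' per gene, its role, planted element, domain content and motif
#' coordinates.
#'
#' @param plan A [genome_plan()].
#' @return An object of class `hepn_genome`: a list with `genes` (tibble as
#'   from [read_genbank()]) and `truth` (tibble with `gene_id`, `role`,
#'   `element_id`, `element_type`, `domains`, `motif_r_pos`,
#'   `motif_spacer`).
#' @export
generate_genome <- function(plan) {
  stopifnot(inherits(plan, "genome_plan"))
  with_seed_(plan$seed, {
    units <- list()
    for (i in seq_along(plan$elements)) {
      el <- plan$elements[[i]]
      eid <- pad_id("el", i, 3)
      units[[length(units) + 1]] <- element_genes(el, eid)
    }
    for (i in seq_len(plan$n_background_genes)) {
      units[[length(units) + 1]] <- tibble(
        role = "background", element_id = NA_character_,
        element_type = "background",
        domains = list(character()),
        strand = sample(c("+", "-"), 1),
        gap_before = NA_integer_   # within-unit gap; NA for unit head
      )
    }
    if (length(units) == 0) stop("plan has no genes", call. = FALSE)
    units <- units[sample(length(units))]

    rows <- dplyr::bind_rows(units, .id = "unit")
    n <- nrow(rows)
    draw_bg_gap <- function() {
      if (runif(1) < plan$p_small) {
        sample(plan$gap_small[1]:plan$gap_small[2], 1)
      } else {
        sample(plan$gap_large[1]:plan$gap_large[2], 1)
      }
    }
    draw_long_gap <- function() sample(plan$gap_large[1]:plan$gap_large[2], 1)

    # gene lengths (codon multiples); bump HEPN/fusion genes so planted
    # content always fits
    lens <- sample(seq(plan$gene_length_range[1], plan$gene_length_range[2]), n,
                   replace = TRUE)
    lens <- as.integer((lens %/% 3) * 3)
    need_aa <- purrr::map_int(rows$domains, ~ 1L + length(.x) * 24L + 12L)
    lens <- pmax(lens, (need_aa + 1L) * 3L)

    start <- integer(n); end <- integer(n)
    cursor <- as.integer(sample(100:400, 1))
    prev_unit <- ""
    prev_planted <- FALSE
    for (i in seq_len(n)) {
      planted <- rows$element_type[i] != "background"
      if (i > 1) {
        gap <- if (!is.na(rows$gap_before[i]) && rows$unit[i] == prev_unit) {
          rows$gap_before[i]          # planted within-element gap, verbatim
        } else if (planted || prev_planted) {
          draw_long_gap()             # keep planted elements isolated
        } else {
          draw_bg_gap()
        }
        cursor <- as.integer(end[i - 1] + gap)
      }
      start[i] <- cursor
      end[i] <- as.integer(cursor + lens[i])
      if (i > 1 && start[i] <= start[i - 1]) {
        stop("infeasible plan: planted spans overlap beyond the -50 nt limit",
             call. = FALSE)
      }
      prev_unit <- rows$unit[i]
      prev_planted <- planted
    }

    prot <- purrr::pmap(list(rows$domains, lens, rows$role), function(d, L, role) {
      build_protein(d, aa_len = L %/% 3 - 1L, plant_rxh = "HEPN" %in% d)
    })

    gene_id <- pad_id("g", seq_len(n))
    contig_length <- as.integer(end[n] + sample(100:300, 1))
    genes <- tibble(
      gene_id = gene_id, contig_id = plan$contig_id,
      start = start, end = end, strand = rows$strand,
      product = ifelse(rows$element_type == "background", "hypothetical protein",
                       purrr::map_chr(rows$domains, paste, collapse = "+")),
      protein_seq = purrr::map_chr(prot, "seq"),
      contig_length = contig_length, circular = plan$circular
    )
    truth <- tibble(
      gene_id = gene_id, contig_id = plan$contig_id,
      role = rows$role, element_id = rows$element_id,
      element_type = rows$element_type,
      domains = purrr::map_chr(rows$domains, paste, collapse = ","),
      motif_r_pos = purrr::map_int(prot, ~ if (is.null(.x$motif)) NA_integer_ else .x$motif$r_pos),
      motif_spacer = purrr::map_int(prot, ~ if (is.null(.x$motif)) NA_integer_ else .x$motif$spacer),
      start = start, end = end, strand = rows$strand
    )
    structure(list(genes = genes, truth = truth, plan = plan),
              class = "hepn_genome")
  })
}

# expand one element spec into per-gene rows (gap_before is the planted
# within-element gap; NA on the element's first gene)
element_genes <- function(el, eid) {
  switch(el$type,
    ta_dyad = {
      # antitoxin 5' of toxin: on '-' the 5' gene is genomic-right
      roles <- c("antitoxin", "toxin")
      doms <- list(el$antitoxin_label, el$toxin_label)
      if (el$strand == "-") { roles <- rev(roles); doms <- rev(doms) }
      tibble(role = roles, element_id = eid, element_type = "ta_dyad",
             domains = doms, strand = el$strand,
             gap_before = c(NA_integer_, el$gap_nt))
    },
    operon = {
      doms <- as.list(el$labels)
      if (el$strand == "-") doms <- rev(doms)
      tibble(role = "operon_member", element_id = eid, element_type = "operon",
             domains = doms, strand = el$strand,
             gap_before = c(NA_integer_, if (el$strand == "-") rev(el$gaps_nt) else el$gaps_nt))
    },
    divergon = {
      tibble(role = c("divergon_left", "divergon_right"), element_id = eid,
             element_type = "divergon",
             domains = list(el$left_label, el$right_label),
             strand = c("-", "+"),
             gap_before = c(NA_integer_, el$head_gap_nt))
    },
    fusion = {
      tibble(role = "fusion", element_id = eid, element_type = "fusion",
             domains = list(el$domain_labels), strand = sample(c("+", "-"), 1),
             gap_before = NA_integer_)
    },
    stop("unknown element type: ", el$type, call. = FALSE)
  )
}

#' Write a synthetic genome to disk
#'
#' Emits the GenBank flat file, the protein FASTA and the truth TSV for a
#' generated genome. Output is byte-deterministic for a fixed plan + seed.
#'
#' @param genome A `hepn_genome` from [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "hepn_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genbank(genome$genes, file.path(dir, "genome.gbk"))
  write_fasta(tibble(name = genome$genes$gene_id, seq = genome$genes$protein_seq),
              file.path(dir, "proteins.faa"))
  write_table(genome$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Plant a single Rx4-6H motif in a random protein sequence
#'
#' Generates a protein whose background is drawn from residues that cannot
#' form an arginine or histidine, then writes exactly one
#' R-x(spacer)-H site at a recorded 0-based position. Optionally the
#' residue after the R is drawn from the preferred polar set {N, D, H}, and
#' an E-x3-[KR] element is planted N-terminal to the site.
#'
#' @param length Total protein length (>= spacer + 10).
#' @param spacer Number of residues between R and H (4-6).
#' @param polar_after_r If `TRUE`, the residue after R comes from {N, D};
#'   otherwise from the non-polar background.
#' @param with_upstream_exkr Also plant an E-x3-\[KR\] element upstream.
#' @param seed Integer seed.
#' @return List with `seq` and `truth`, a one-row tibble (`r_pos`,
#'   `spacer`, `h_pos`, `polar_after_r`, `upstream_exkr_pos`; positions
#'   0-based).
#' @examples
#' plant_motif(40, spacer = 6, seed = 1)$truth
#' @export
plant_motif <- function(length, spacer = 4, polar_after_r = TRUE,
                        with_upstream_exkr = FALSE, seed = 1) {
  if (!(spacer %in% 4:6)) stop("spacer must be 4, 5 or 6", call. = FALSE)
  if (length < spacer + 10) {
    stop("length must be >= spacer + 10", call. = FALSE)
  }
  with_seed_(seed, {
    chars <- sample(SENTINEL_ALPHABET, length, replace = TRUE)
    lo <- if (with_upstream_exkr) 5L else 0L
    hi <- length - spacer - 2L
    r_pos <- if (lo >= hi) lo else sample(lo:hi, 1)
    h_pos <- r_pos + spacer + 1L
    chars[r_pos + 1L] <- "R"
    chars[h_pos + 1L] <- "H"
    after <- if (polar_after_r) {
      sample(c("N", "D"), 1)
    } else {
      sample(setdiff(SENTINEL_ALPHABET, residue_classes()$p), 1)
    }
    chars[r_pos + 2L] <- after
    exkr_pos <- NA_integer_
    if (with_upstream_exkr) {
      slots <- 0:(r_pos - 5L)
      exkr_pos <- slots[sample.int(length(slots), 1)]
      chars[exkr_pos + 1L] <- "E"
      chars[exkr_pos + 5L] <- sample(c("K"), 1)  # K only: R would seed a decoy
    }
    list(
      seq = paste(chars, collapse = ""),
      truth = tibble(r_pos = r_pos, spacer = as.integer(spacer), h_pos = h_pos,
                     polar_after_r = polar_after_r,
                     upstream_exkr_pos = exkr_pos)
    )
  })
}

#' Generate a synthetic protein family alignment from a column profile
#'
#' Builds an ungapped alignment column by column from a conservation
#' profile. Each profile entry is one of: a fixed residue (`"R"`), a
#' residue class (`"h"`, `"p"`, `"s"` as in [residue_classes()]), `"*"`
#' (uniform over the 20 residues), or a partially conserved column
#' `"R:0.83"` (the residue with the given frequency, the rest uniform over
#' the other residues).
#'
#' @param n_seqs Number of rows.
#' @param profile Character vector, one entry per column.
#' @param seed Integer seed.
#' @return Alignment tibble (`name`, `seq`).
#' @examples
#' generate_protein_family(3, c("R", "h", "*", "H:0.8"), seed = 1)
#' @export
generate_protein_family <- function(n_seqs, profile, seed = 1) {
  classes <- residue_classes()
  with_seed_(seed, {
    cols <- purrr::map(profile, function(p) {
      if (p %in% c("h", "p", "s")) {
        sample(classes[[p]], n_seqs, replace = TRUE)
      } else if (p %in% c("*", "random")) {
        sample(AA20, n_seqs, replace = TRUE)
      } else if (grepl("^[A-Z]:[0-9.]+$", p)) {
        res <- sub(":.*", "", p)
        f <- as.numeric(sub(".*:", "", p))
        ifelse(runif(n_seqs) < f, res, sample(setdiff(AA20, res), n_seqs, replace = TRUE))
      } else if (p %in% AA20) {
        rep(p, n_seqs)
      } else {
        stop("unknown profile entry: '", p, "'", call. = FALSE)
      }
    })
    m <- do.call(cbind, cols)
    tibble(name = pad_id("seq", seq_len(n_seqs)),
           seq = apply(m, 1, paste, collapse = ""))
  })
}
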