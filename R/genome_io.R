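# GenBank / FASTA / TSV input-output.
#
# Internal gene model: one row per CDS with 0-based half-open coordinates.
# GenBank flat files use 1-based inclusive coordinates; conversion happens
# here and nowhere else. Compound (join) locations collapse to their outer
# span: introns play no role in prokaryotic neighborhood analysis.

#' Read an annotated genome from a GenBank flat file
#'
#' Parses the CDS features of each record into a tidy gene table. GenBank
#' 1-based inclusive locations are converted to the package's 0-based
#' half-open convention; `complement(...)` locations get strand `-`;
#' `join(...)` locations collapse to the outermost span. Non-CDS features
#' (genes, RNAs, pseudogene annotations without CDS) are ignored. A CDS
#' without a `/translation` qualifier is retained with an empty
#' `protein_seq` and a warning. Ambiguous amino acids other than X are
#' mapped to X with a warning. The `circular` flag is taken from the LOCUS
#' line (default linear).
#'
#' @param path Path to a GenBank flat file (one or more records).
#' @return A tibble with one row per CDS: `gene_id`, `contig_id`, `start`,
#'   `end`, `strand`, `product`, `protein_seq`, `contig_length`, `circular`.
#'   Rows are sorted by contig then start.
#' @seealso [write_genbank()] for the inverse, [generate_genome()] for
#'   synthetic fixtures.
#' @examples
#' gnm <- generate_genome(genome_plan(seed = 1, n_background_genes = 4))
#' f <- tempfile(fileext = ".gbk")
#' write_genbank(gnm$genes, f)
#' read_genbank(f)
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//", lines)
  if (length(ends) == 0) {
    if (length(lines) == 0 || !any(grepl("^LOCUS", lines))) {
      stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
    }
    ends <- length(lines)
  }
  starts <- c(1L, head(ends, -1) + 1L)
  recs <- purrr::map2(starts, ends, function(s, e) {
    block <- lines[s:e]
    block <- block[nzchar(trimws(block)) | seq_along(block) == 1]
    if (!any(grepl("^LOCUS", block))) return(NULL)
    parse_genbank_record(block)
  })
  recs <- purrr::compact(recs)
  if (length(recs) == 0) {
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  }
  out <- dplyr::bind_rows(recs)
  out <- dplyr::arrange(out, .data$contig_id, .data$start)
  if (anyDuplicated(out$gene_id)) {
    dup <- out$gene_id[duplicated(out$gene_id)]
    out$gene_id <- make.unique(out$gene_id, sep = "_")
    warning("duplicated gene ids made unique: ",
            paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  out
}

# Parse one GenBank record (character vector LOCUS..//) to a gene tibble.
parse_genbank_record <- function(block) {
  locus_line <- block[grepl("^LOCUS", block)][1]
  toks <- strsplit(trimws(sub("^LOCUS", "", locus_line)), "\\s+")[[1]]
  contig_id <- toks[1]
  bp_idx <- which(toks == "bp")
  contig_length <- if (length(bp_idx) == 1 && bp_idx > 1) {
    suppressWarnings(as.integer(toks[bp_idx - 1]))
  } else {
    NA_integer_
  }
  circular <- any(grepl("\\bcircular\\b", locus_line, ignore.case = TRUE))

  fstart <- grep("^FEATURES", block)
  if (length(fstart) == 0) {
    return(tibble(
      gene_id = character(), contig_id = character(),
      start = integer(), end = integer(), strand = character(),
      product = character(), protein_seq = character(),
      contig_length = integer(), circular = logical()
    ))
  }
  fend <- grep("^(ORIGIN|CONTIG|//)", block)
  fend <- fend[fend > fstart][1]
  if (is.na(fend)) fend <- length(block) + 1L
  feat_lines <- block[(fstart + 1L):(fend - 1L)]
  if (length(feat_lines) == 0) feat_lines <- character()

  # A feature header starts with exactly 5 spaces then a key; everything
  # else (21-space indent) continues the previous feature.
  is_head <- grepl("^ {5}\\S", feat_lines)
  if (!any(is_head)) {
    return(tibble(
      gene_id = character(), contig_id = character(),
      start = integer(), end = integer(), strand = character(),
      product = character(), protein_seq = character(),
      contig_length = integer(), circular = logical()
    ))
  }
  grp <- cumsum(is_head)
  feats <- split(feat_lines[grp > 0], grp[grp > 0])

  genes <- purrr::imap(feats, function(fl, i) {
    head_toks <- strsplit(trimws(fl[1]), "\\s+")[[1]]
    key <- head_toks[1]
    if (key != "CDS") return(NULL)
    body <- trimws(fl[-1])
    # the location may continue onto lines before the first qualifier
    qual_start <- which(startsWith(body, "/"))[1]
    loc <- paste0(head_toks[-1], collapse = "")
    if (length(body) > 0) {
      n_loc_cont <- if (is.na(qual_start)) length(body) else qual_start - 1L
      if (n_loc_cont > 0) loc <- paste0(loc, paste0(body[seq_len(n_loc_cont)], collapse = ""))
      body <- if (is.na(qual_start)) character() else body[qual_start:length(body)]
    }
    pos <- parse_genbank_location(loc, contig_id)
    quals <- parse_genbank_qualifiers(body)
    gene_id <- quals[["locus_tag"]] %||% quals[["protein_id"]] %||%
      quals[["gene"]] %||% paste0(contig_id, "_cds", i)
    prot <- quals[["translation"]]
    if (is.null(prot)) {
      warning(sprintf("CDS %s on %s has no /translation; kept with empty protein_seq",
                      gene_id, contig_id), call. = FALSE)
      prot <- ""
    } else {
      prot <- normalize_protein(gsub("\\s", "", prot), id = gene_id)
    }
    tibble(
      gene_id = gene_id,
      contig_id = contig_id,
      start = pos$start, end = pos$end, strand = pos$strand,
      product = quals[["product"]] %||% "",
      protein_seq = prot
    )
  })
  out <- dplyr::bind_rows(purrr::compact(genes))
  if (nrow(out) == 0) {
    out <- tibble(
      gene_id = character(), contig_id = character(),
      start = integer(), end = integer(), strand = character(),
      product = character(), protein_seq = character()
    )
  }
  out$contig_length <- contig_length
  out$circular <- circular
  if (!is.na(contig_length) && nrow(out) > 0 && any(out$end > contig_length)) {
    stop(sprintf("malformed record %s: CDS end beyond contig length", contig_id),
         call. = FALSE)
  }
  out
}

# "complement(join(<10..300,400..>500))" -> 0-based half-open outer span.
parse_genbank_location <- function(loc, contig_id) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
  if (length(nums) < 2) {
    stop(sprintf("malformed record %s: cannot parse location '%s'", contig_id, loc),
         call. = FALSE)
  }
  nums <- as.numeric(nums)
  lo <- min(nums)
  hi <- max(nums)
  if (lo < 1 || hi < lo) {
    stop(sprintf("malformed record %s: bad coordinates in '%s'", contig_id, loc),
         call. = FALSE)
  }
  list(start = as.integer(lo - 1), end = as.integer(hi), strand = strand)
}

# qualifier lines (already trimmed) -> named list; multi-line quoted values
# (notably /translation) are concatenated without separators.
parse_genbank_qualifiers <- function(body) {
  quals <- list()
  cur_name <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_name)) {
      v <- gsub("^\"|\"$", "", cur_val)
      quals[[cur_name]] <<- v
    }
  }
  for (ln in body) {
    if (startsWith(ln, "/")) {
      flush()
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0) {
        cur_name <- substring(ln, 2, eq - 1)
        cur_val <- substring(ln, eq + 1)
      } else {
        cur_name <- substring(ln, 2)
        cur_val <- "TRUE"
      }
    } else if (!is.null(cur_name)) {
      sep <- if (cur_name %in% c("translation")) "" else " "
      cur_val <- paste(cur_val, ln, sep = sep)
    }
  }
  flush()
  quals
}

#' Write a gene table as a GenBank flat file
#'
#' Emits one record per contig with a CDS feature per gene, converting the
#' internal 0-based half-open coordinates back to GenBank 1-based inclusive
#' form. Round-trips with [read_genbank()] on all coordinates, strands,
#' products and translations.
#'
#' @param genes Gene tibble as returned by [read_genbank()] or
#'   [generate_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genes, path) {
  assert_genes_df(genes)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cid in unique(genes$contig_id)) {
    g <- dplyr::arrange(dplyr::filter(genes, .data$contig_id == cid), .data$start)
    len <- if ("contig_length" %in% names(g) && !is.na(g$contig_length[1])) {
      g$contig_length[1]
    } else {
      max(g$end) + 100L
    }
    circ <- if ("circular" %in% names(g)) isTRUE(g$circular[1]) else FALSE
    topo <- if (circ) "circular" else "linear"
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s BCT 01-JAN-2000",
                       cid, len, topo), con)
    writeLines("DEFINITION  synthetic contig.", con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", len), con)
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", g$gene_id[i]), con)
      prod <- if ("product" %in% names(g)) g$product[i] else ""
      if (nzchar(prod)) {
        writeLines(sprintf("                     /product=\"%s\"", prod), con)
      }
      ps <- if ("protein_seq" %in% names(g)) g$protein_seq[i] else ""
      if (nzchar(ps)) {
        at <- seq(1, nchar(ps), 44)
        chunks <- substring(ps, at, pmin(at + 43, nchar(ps)))
        tl <- paste0("                     ", chunks)
        tl[1] <- paste0("                     /translation=\"", chunks[1])
        tl[length(tl)] <- paste0(tl[length(tl)], "\"")
        writeLines(tl, con)
      }
    }
    writeLines("ORIGIN", con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file ('-' as gap).
#' @return A tibble with columns `name` and `seq`; all `seq` values have
#'   equal width.
#' @export
read_alignment <- function(path) {
  ss <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("cannot read FASTA: ", conditionMessage(e),
                                          call. = FALSE))
  if (length(ss) == 0) stop("empty alignment file: ", path, call. = FALSE)
  widths <- Biostrings::width(ss)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment rows; widths: ", paste(widths, collapse = ", "),
         call. = FALSE)
  }
  tibble(name = names(ss), seq = unname(as.character(ss)))
}

#' Read a protein set from FASTA (no width validation)
#'
#' @param path FASTA file path.
#' @return Tibble with `name` and `seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  tibble(name = names(ss), seq = unname(as.character(ss)))
}

#' Write an alignment (or protein set) as FASTA
#'
#' @param aln Tibble with columns `name` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  if (!all(c("name", "seq") %in% names(aln))) {
    stop("need columns 'name' and 'seq'", call. = FALSE)
  }
  ss <- Biostrings::AAStringSet(setNames(aln$seq, aln$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write records as a deterministic TSV
#'
#' Writes a data frame as TSV with a header, stable column order and rows
#' sorted by the first column, so that repeated runs are byte-identical.
#'
#' @param records A data frame; list columns are collapsed with commas.
#' @param path Output path.
#' @param sort_by Column used for the deterministic row order (default the
#'   first column).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, sort_by = NULL) {
  records <- as_tibble(records)
  records <- dplyr::mutate(records, dplyr::across(
    dplyr::where(is.list), ~ purrr::map_chr(.x, paste, collapse = ",")
  ))
  if (nrow(records) > 0) {
    key <- sort_by %||% names(records)[1]
    records <- dplyr::arrange(records, .data[[key]])
  }
  readr::write_tsv(records, path)
  invisible(path)
}
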