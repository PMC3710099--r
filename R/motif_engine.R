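# Rx4-6H active-site motif scanning, alignment conservation, consensus
# lines, and active/inactive classification of HEPN-like domains.
#
# The catalytic signature is an arginine followed, after a 4-6 residue
# spacer, by a histidine. The residue immediately after the R is typically
# polar (preferentially N, D or H). A second conserved acidic element,
# E-x3-[KR], often occurs N-terminal to the site and is treated as
# supporting evidence, never as a requirement. Families that lose the
# canonical histidine may still be active through a conserved H N-terminal
# to a conserved basic residue; families with no conserved charged or
# polar positions at all are called inactive RNA-binding versions.

#' Scan a protein for Rx4-6H active-site motifs
#'
#' Reports every position matching R-x(4..6)-H, overlapping hits included.
#' For each hit: whether the residue after the R belongs to the preferred
#' polar set {N, D, H} (`polar_preferred`) or the wider polar class
#' (`polar_after_r`), and the position of the nearest upstream E-x3-[KR]
#' element if one exists. All positions are 0-based.
#'
#' @param seq Ungapped protein sequence. Gapped input is rejected; degap
#'   rows and use [classify_active_site()] for alignment-level scanning.
#' @param min_spacer,max_spacer Allowed spacer lengths (defaults 4 and 6).
#' @return Tibble: `r_pos`, `spacer`, `h_pos`, `polar_after_r`,
#'   `polar_preferred`, `upstream_exkr_pos` (NA when absent).
#' @examples
#' scan_rxh("AAARNPQGHAA")  # one hit at r_pos 3
#' @export
scan_rxh <- function(seq, min_spacer = 4, max_spacer = 6) {
  if (grepl("-", seq, fixed = TRUE)) {
    stop("gapped sequence: degap rows, or use classify_active_site() for alignments",
         call. = FALSE)
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  classes <- residue_classes()
  r_idx <- which(chars == "R") - 1L  # 0-based
  hits <- list()
  for (r in r_idx) {
    for (sp in min_spacer:max_spacer) {
      h <- r + sp + 1L
      if (h <= n - 1L && chars[h + 1L] == "H") {
        after <- if (r + 2L <= n) chars[r + 2L] else ""
        hits[[length(hits) + 1]] <- tibble(
          r_pos = r, spacer = as.integer(sp), h_pos = h,
          polar_after_r = after %in% classes$p,
          polar_preferred = after %in% classes$polar_after_r_preferred
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(r_pos = integer(), spacer = integer(), h_pos = integer(),
                  polar_after_r = logical(), polar_preferred = logical(),
                  upstream_exkr_pos = integer()))
  }
  out <- dplyr::bind_rows(hits)
  # nearest E-x3-[KR] strictly N-terminal to each hit's arginine
  e_idx <- which(chars == "E") - 1L
  e_idx <- e_idx[e_idx + 4L <= n - 1L]
  e_idx <- e_idx[chars[e_idx + 5L] %in% classes$basic]
  out$upstream_exkr_pos <- purrr::map_int(out$r_pos, function(r) {
    ok <- e_idx[e_idx + 4L < r]
    if (length(ok) == 0) NA_integer_ else max(ok)
  })
  dplyr::arrange(out, .data$r_pos, .data$spacer)
}

# alignment tibble -> residue matrix (rows x columns)
aln_matrix <- function(aln) {
  stopifnot(all(c("name", "seq") %in% names(aln)), nrow(aln) >= 1)
  w <- nchar(aln$seq)
  if (length(unique(w)) != 1) {
    stop("ragged alignment rows; widths: ", paste(w, collapse = ", "),
         call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(aln$seq), ""))
  rownames(m) <- aln$name
  m
}

#' Per-column conservation of an alignment
#'
#' For each requested column, the most frequent non-gap residue and its
#' fraction among non-gap rows. Ties break to the lexicographically
#' smallest residue. A gap-only column yields `("-", 0)`.
#'
#' @param aln Alignment tibble (`name`, `seq`).
#' @param columns 1-based column indices (default all).
#' @return Tibble: `column`, `top_residue`, `fraction`, `n_nongap`.
#' @export
column_conservation <- function(aln, columns = NULL) {
  m <- aln_matrix(aln)
  columns <- columns %||% seq_len(ncol(m))
  if (any(columns < 1 | columns > ncol(m))) {
    stop("column index out of range 1..", ncol(m), call. = FALSE)
  }
  purrr::map_dfr(columns, function(j) {
    col <- m[, j]
    col <- col[col != "-" & col != "."]
    if (length(col) == 0) {
      return(tibble(column = j, top_residue = "-", fraction = 0, n_nongap = 0L))
    }
    tab <- table(col)
    top <- sort(names(tab)[tab == max(tab)])[1]
    tibble(column = j, top_residue = top,
           fraction = unname(tab[top]) / length(col),
           n_nongap = length(col))
  })
}

#' Consensus line of an alignment
#'
#' One character per column: the residue letter if a single residue
#' reaches `threshold` (fraction of all rows), else `'h'`, `'p'` or `'s'`
#' if the hydrophobic, polar or small class reaches it (precedence
#' h > p > s), else `'.'`. Gaps count in the denominator, so gap-heavy
#' columns fall through to `'.'`.
#'
#' @param aln Alignment tibble.
#' @param threshold Consensus threshold (default 0.7).
#' @return A string of width `ncol(alignment)`.
#' @examples
#' a <- tibble::tibble(name = c("s1", "s2"), seq = c("LRD", "IRE"))
#' consensus_line(a)  # "hRp"
#' @export
consensus_line <- function(aln, threshold = 0.7) {
  m <- aln_matrix(aln)
  classes <- residue_classes()
  n <- nrow(m)
  out <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col != "-" & col != "."]
    if (length(res) == 0) return(".")
    tab <- table(res)
    top <- sort(names(tab)[tab == max(tab)])[1]
    if (tab[top] / n >= threshold) return(top)
    for (cl in c("h", "p", "s")) {
      if (sum(res %in% classes[[cl]]) / n >= threshold) return(cl)
    }
    "."
  }, character(1))
  paste(out, collapse = "")
}

#' Classify a HEPN-like family as active or inactive
#'
#' Works on a family alignment (or a single sequence, treated as a one-row
#' alignment). Each row is degapped and scanned with [scan_rxh()]; hit
#' positions are mapped back to alignment columns, and an (R column,
#' H column) pair carried by at least `conservation` of the non-empty rows
#' makes the family `active_canonical`. Failing that, a conserved H column
#' N-terminal to a conserved basic (K/R) column makes it
#' `active_alternative`. A family with no conserved R/H/E/K/D column at
#' all is `inactive_binding`; partially conserved charged positions that
#' satisfy neither active rule also fall to `inactive_binding`, with the
#' evidence recording what was seen.
#'
#' @param aln Alignment tibble (`name`, `seq`) or a single sequence.
#' @param conservation Column-conservation threshold for calling a
#'   position conserved (default 0.8).
#' @param min_spacer,max_spacer Spacer range passed to [scan_rxh()].
#' @return An `activity_call` object: list with `call` (one of
#'   `active_canonical`, `active_alternative`, `inactive_binding`) and
#'   `evidence` (tibble of criteria with satisfied/failed status).
#' @export
classify_active_site <- function(aln, conservation = 0.8,
                                 min_spacer = 4, max_spacer = 6) {
  if (is.character(aln)) aln <- tibble(name = "seq1", seq = aln)
  m <- aln_matrix(aln)
  nongap_rows <- which(rowSums(m != "-" & m != ".") > 0)
  if (length(nongap_rows) == 0 || ncol(m) == 0) {
    stop("empty region: alignment has no residues", call. = FALSE)
  }
  n_eff <- length(nongap_rows)
  classes <- residue_classes()
  evidence <- tibble(criterion = character(), status = character(),
                     detail = character())
  note <- function(criterion, status, detail = "") {
    evidence <<- dplyr::bind_rows(evidence,
                                  tibble(criterion = criterion, status = status,
                                         detail = detail))
  }

  # per-row motif scan mapped to columns
  site_cols <- list()
  for (i in nongap_rows) {
    row <- m[i, ]
    resid <- which(row != "-" & row != ".")
    if (length(resid) == 0) next
    hits <- scan_rxh(paste(row[resid], collapse = ""), min_spacer, max_spacer)
    if (nrow(hits) > 0) {
      site_cols[[length(site_cols) + 1]] <- tibble(
        row = i,
        r_col = resid[hits$r_pos + 1L],
        h_col = resid[hits$h_pos + 1L]
      )
    }
  }
  canonical <- FALSE
  if (length(site_cols) > 0) {
    sc <- dplyr::bind_rows(site_cols)
    tall <- dplyr::distinct(sc) |>
      dplyr::count(.data$r_col, .data$h_col) |>
      dplyr::arrange(dplyr::desc(.data$n), .data$r_col)
    best <- tall[1, ]
    frac <- best$n / n_eff
    if (frac >= conservation) {
      canonical <- TRUE
      note("canonical_rxh", "satisfied",
           sprintf("R col %d / H col %d in %.0f%% of rows",
                   best$r_col, best$h_col, 100 * frac))
    } else {
      note("canonical_rxh", "failed",
           sprintf("best site in %.0f%% of rows (need %.0f%%)",
                   100 * frac, 100 * conservation))
    }
  } else {
    note("canonical_rxh", "failed", "no Rx4-6H site in any row")
  }

  cons <- column_conservation(aln)
  conserved <- cons[cons$fraction >= conservation & cons$n_nongap > 0, ]
  if (canonical) {
    return(new_activity_call("active_canonical", evidence))
  }

  # alternative site: conserved H N-terminal to a conserved basic column
  h_cols <- conserved$column[conserved$top_residue == "H"]
  basic_cols <- conserved$column[conserved$top_residue %in% classes$basic]
  alt <- length(h_cols) > 0 && length(basic_cols) > 0 &&
    min(h_cols) < max(basic_cols)
  if (alt) {
    note("alternative_site", "satisfied",
         sprintf("conserved H col %d N-terminal to basic col %d",
                 min(h_cols), max(basic_cols[basic_cols > min(h_cols)])))
    return(new_activity_call("active_alternative", evidence))
  }
  note("alternative_site", "failed",
       "no conserved H column N-terminal to a conserved basic column")

  charged <- conserved$column[conserved$top_residue %in% c("R", "H", "E", "K", "D")]
  if (length(charged) == 0) {
    note("charged_polar_columns", "failed",
         "no conserved R/H/E/K/D column in the region")
  } else {
    note("charged_polar_columns", "satisfied",
         paste("conserved charged columns:", paste(charged, collapse = ",")))
  }
  new_activity_call("inactive_binding", evidence)
}

new_activity_call <- function(call, evidence) {
  structure(list(call = call, evidence = evidence), class = "activity_call")
}

#' @export
print.activity_call <- function(x, ...) {
  cat("Activity call:", x$call, "\n")
  for (i in seq_len(nrow(x$evidence))) {
    cat(sprintf("  [%s] %s: %s\n", x$evidence$status[i],
                x$evidence$criterion[i], x$evidence$detail[i]))
  }
  invisible(x)
}

#' @rdname classify_active_site
#' @param x An `activity_call`.
#' @param ... Unused.
#' @method tidy activity_call
#' @export
tidy.activity_call <- function(x, ...) {
  dplyr::mutate(x$evidence, call = x$call, .before = 1)
}
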