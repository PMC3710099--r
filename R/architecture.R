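# Domain annotation and architecture strings.
#
# The library supports three detector kinds — exact sentinel subsequences
# (the synthetic genomes are built from these), motif regular expressions,
# and simple position-weight matrices scored as summed per-position
# log-odds over a sliding window — plus an import path for domain
# intervals produced by an external profile search the user runs. Real
# profile/HMM searching is deliberately outside this package.

#' Build a domain library
#'
#' Bundles detector specs created with [sentinel_detector()],
#' [pattern_detector()] and [pwm_detector()] into a library for
#' [annotate_protein()].
#'
#' @param ... Detector specs.
#' @return A `domain_library` object (tibble: `name`, `type`, `detector`).
#' @examples
#' lib <- domain_library(sentinel_detector("HEPN", sentinel_for("HEPN")),
#'                       pattern_detector("RxH-site", "R.{4,6}H"))
#' @export
domain_library <- function(...) {
  specs <- list(...)
  if (length(specs) == 1 && is.list(specs[[1]]) && !inherits(specs[[1]], "domain_detector")) {
    specs <- specs[[1]]
  }
  if (length(specs) == 0) stop("empty library", call. = FALSE)
  for (s in specs) {
    if (!inherits(s, "domain_detector")) {
      stop("library entries must be detector specs", call. = FALSE)
    }
  }
  names_ <- purrr::map_chr(specs, "name")
  if (anyDuplicated(names_)) stop("duplicate domain names in library", call. = FALSE)
  structure(tibble(name = names_,
                   type = purrr::map_chr(specs, "type"),
                   detector = specs),
            class = c("domain_library", class(tibble())))
}

#' Domain detector constructors
#'
#' `sentinel_detector()` finds exact occurrences of a fixed subsequence
#' (score = match length). `pattern_detector()` finds matches of a regular
#' expression over the residue alphabet (score = match length).
#' `pwm_detector()` slides a log-odds position-weight matrix along the
#' sequence and reports windows scoring at least `cutoff` (score = summed
#' log-odds).
#'
#' @param name Domain name.
#' @param seq Sentinel subsequence (exact match).
#' @param pattern Regular expression.
#' @param pwm Numeric matrix, rows named by the 20 residues (and
#'   optionally `X`), one column per motif position, log-odds entries.
#' @param cutoff Minimum window score to report.
#' @return A `domain_detector` spec.
#' @name domain_detectors
NULL

#' @rdname domain_detectors
#' @export
sentinel_detector <- function(name, seq) {
  stopifnot(nzchar(seq))
  structure(list(name = name, type = "sentinel", seq = toupper(seq)),
            class = "domain_detector")
}

#' @rdname domain_detectors
#' @export
pattern_detector <- function(name, pattern) {
  structure(list(name = name, type = "pattern", pattern = pattern),
            class = "domain_detector")
}

#' @rdname domain_detectors
#' @export
pwm_detector <- function(name, pwm, cutoff) {
  stopifnot(is.matrix(pwm), !is.null(rownames(pwm)))
  missing_rows <- setdiff(AA20, rownames(pwm))
  if (length(missing_rows) > 0) {
    stop("PWM must have one row per standard residue; missing: ",
         paste(missing_rows, collapse = ","), call. = FALSE)
  }
  structure(list(name = name, type = "pwm", pwm = pwm, cutoff = cutoff),
            class = "domain_detector")
}

#' Load a domain library from a YAML config
#'
#' The file holds a list of entries, each with `name`, `type`
#' (`sentinel` / `pattern` / `pwm`) and the detector fields (`seq`,
#' `pattern`, or `matrix` as a residue-keyed map of per-position values
#' plus `cutoff`).
#'
#' @param path YAML file path.
#' @return A `domain_library`.
#' @export
read_domain_library <- function(path) {
  cfg <- yaml::read_yaml(path)
  specs <- purrr::map(cfg, function(e) {
    switch(e$type,
      sentinel = sentinel_detector(e$name, e$seq),
      pattern = pattern_detector(e$name, e$pattern),
      pwm = {
        m <- do.call(rbind, e$matrix)
        rownames(m) <- names(e$matrix)
        pwm_detector(e$name, m, e$cutoff)
      },
      stop("unknown detector type: ", e$type, call. = FALSE)
    )
  })
  domain_library(specs)
}

# all raw hits of one detector on one sequence: tibble(start, end, score),
# 0-based half-open residue intervals
detector_hits <- function(det, seq) {
  n <- nchar(seq)
  if (det$type == "sentinel") {
    w <- nchar(det$seq)
    pos <- gregexpr(det$seq, seq, fixed = TRUE)[[1]]
    if (pos[1] == -1) return(NULL)
    tibble(start = as.integer(pos - 1), end = as.integer(pos - 1 + w),
           score = as.numeric(w))
  } else if (det$type == "pattern") {
    mm <- gregexpr(det$pattern, seq, perl = TRUE)[[1]]
    if (mm[1] == -1) return(NULL)
    len <- attr(mm, "match.length")
    tibble(start = as.integer(mm - 1), end = as.integer(mm - 1 + len),
           score = as.numeric(len))
  } else if (det$type == "pwm") {
    w <- ncol(det$pwm)
    if (n < w) return(NULL)
    chars <- strsplit(seq, "")[[1]]
    scores <- vapply(0:(n - w), function(s) {
      ri <- match(chars[(s + 1):(s + w)], rownames(det$pwm))
      if (anyNA(ri)) return(-Inf)
      sum(det$pwm[cbind(ri, seq_len(w))])
    }, numeric(1))
    keep <- which(scores >= det$cutoff)
    if (length(keep) == 0) return(NULL)
    tibble(start = as.integer(keep - 1), end = as.integer(keep - 1 + w),
           score = scores[keep])
  } else {
    stop("unknown detector type: ", det$type, call. = FALSE)
  }
}

#' Annotate a protein with domain intervals
#'
#' Runs every detector in the library, then resolves overlaps greedily:
#' hits are accepted in order of descending score, then ascending start,
#' then domain name; a hit overlapping an accepted one is dropped (not
#' trimmed). The result is therefore independent of library order.
#'
#' @param seq Protein sequence.
#' @param library A [domain_library()].
#' @param protein_id Identifier attached to the output rows.
#' @return Tibble: `protein_id`, `domain`, `start`, `end` (0-based
#'   half-open), `score`, sorted by `start`.
#' @export
annotate_protein <- function(seq, library, protein_id = "protein") {
  if (!inherits(library, "domain_library") || nrow(library) == 0) {
    stop("empty or invalid domain library", call. = FALSE)
  }
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  seq <- toupper(seq)
  hits <- purrr::map2(library$detector, library$name, function(det, nm) {
    h <- detector_hits(det, seq)
    if (is.null(h)) return(NULL)
    h$domain <- nm
    h
  })
  hits <- dplyr::bind_rows(purrr::compact(hits))
  if (nrow(hits) == 0) {
    return(tibble(protein_id = character(), domain = character(),
                  start = integer(), end = integer(), score = numeric()))
  }
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$start, .data$domain)
  taken <- rep(FALSE, nchar(seq))
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    span <- (hits$start[i] + 1):hits$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  out <- hits[keep, ]
  out$protein_id <- protein_id
  dplyr::arrange(out[c("protein_id", "domain", "start", "end", "score")],
                 .data$start)
}

#' Annotate a set of proteins
#'
#' @param proteins Tibble with `protein_id` and `seq` (a gene table works:
#'   `gene_id`/`protein_seq` are accepted as synonyms).
#' @inheritParams annotate_protein
#' @return Row-bound [annotate_protein()] results.
#' @export
annotate_proteins <- function(proteins, library) {
  proteins <- normalize_protein_table(proteins)
  purrr::map2_dfr(proteins$seq, proteins$protein_id, function(s, id) {
    if (!nzchar(s)) return(NULL)
    annotate_protein(s, library, protein_id = id)
  })
}

normalize_protein_table <- function(proteins) {
  p <- as_tibble(proteins)
  if (!"protein_id" %in% names(p) && "gene_id" %in% names(p)) {
    p$protein_id <- p$gene_id
  }
  if (!"seq" %in% names(p) && "protein_seq" %in% names(p)) {
    p$seq <- p$protein_seq
  }
  stopifnot(all(c("protein_id", "seq") %in% names(p)))
  p
}

#' Architecture string of one protein's annotations
#'
#' @param annotations Tibble of domain annotations for a single protein
#'   (from [annotate_protein()] or [read_domain_tsv()]).
#' @return The '+'-joined domain names in N-to-C order; `"unknown"` when
#'   empty.
#' @examples
#' architecture_string(tibble::tibble(domain = c("HEPN", "MNT"),
#'                                    start = c(120L, 10L),
#'                                    end = c(230L, 100L)))
#' @export
architecture_string <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0) return("unknown")
  paste(annotations$domain[order(annotations$start)], collapse = "+")
}

#' Architecture strings for a protein set
#'
#' @inheritParams annotate_proteins
#' @return Tibble: `protein_id`, `architecture` (`"unknown"` for proteins
#'   with no detected domain).
#' @export
architectures <- function(proteins, library) {
  proteins <- normalize_protein_table(proteins)
  ann <- annotate_proteins(proteins, library)
  arch <- ann |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(architecture = architecture_string(dplyr::pick(dplyr::everything())))
  dplyr::left_join(proteins["protein_id"], arch, by = "protein_id") |>
    dplyr::mutate(architecture = dplyr::coalesce(.data$architecture, "unknown"))
}

#' Consecutive (fused) domain pairs of an architecture
#'
#' Adjacent-only pairs: `"A+B+C"` yields (A,B) and (B,C) but never (A,C).
#' Repeats form self-pairs: `"A+A"` yields (A,A).
#'
#' @param architecture Architecture string (or annotations tibble).
#' @return Tibble: `from`, `to` (N-to-C order); empty for single-domain
#'   or unknown architectures.
#' @export
fusion_pairs <- function(architecture) {
  if (is.data.frame(architecture)) architecture <- architecture_string(architecture)
  if (identical(architecture, "unknown") || !nzchar(architecture)) {
    return(tibble(from = character(), to = character()))
  }
  doms <- strsplit(architecture, "+", fixed = TRUE)[[1]]
  if (length(doms) < 2) return(tibble(from = character(), to = character()))
  tibble(from = doms[-length(doms)], to = doms[-1])
}

#' Import externally produced domain annotations
#'
#' Reads a TSV of domain intervals (e.g. from a profile search run outside
#' this package) with columns `protein_id`, `domain`, `start`, `end`
#' (0-based half-open) and optional `score`.
#'
#' @param path TSV path.
#' @return Annotation tibble compatible with [architecture_string()].
#' @export
read_domain_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("protein_id", "domain", "start", "end")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("domain TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"score" %in% names(d)) d$score <- NA_real_
  if (any(d$start < 0 | d$end <= d$start)) {
    stop("domain intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  as_tibble(d[c("protein_id", "domain", "start", "end", "score")])
}
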