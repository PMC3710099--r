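# Shared constants and small internal helpers.

# The 20 standard residues; X is the only ambiguity code kept internally.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Residue classes used for consensus annotation
#'
#' The three classes used to annotate alignment consensus lines
#' ('h' hydrophobic, 'p' polar, 's' small), plus the preferred set of polar
#' residues seen immediately after the catalytic arginine of the Rx4-6H
#' motif and the basic residues used when looking for alternative
#' active-site arrangements. Classes overlap (H is both hydrophobic and
#' polar; T is hydrophobic, polar and small).
#'
#' @return Named list of character vectors: `h`, `p`, `s`,
#'   `polar_after_r_preferred`, `basic`.
#' @examples
#' residue_classes()$h
#' @export
residue_classes <- function() {
  list(
    h = strsplit("WFYMLIVACTH", "")[[1]],
    p = strsplit("EDKRNQHTS", "")[[1]],
    s = strsplit("ACDGNPSTV", "")[[1]],
    polar_after_r_preferred = c("N", "D", "H"),
    basic = c("K", "R")
  )
}

# Validate and normalise a protein sequence: uppercase, non-standard
# residues (B, Z, J, U, O, *, .) mapped to X with a warning.
normalize_protein <- function(seq, id = "<seq>") {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  bad <- !(chars %in% c(AA20, "X"))
  if (any(bad)) {
    warning(sprintf("%s: %d non-standard residue(s) (%s) mapped to X",
                    id, sum(bad), paste(unique(chars[bad]), collapse = ",")),
            call. = FALSE)
    chars[bad] <- "X"
    seq <- paste(chars, collapse = "")
  }
  seq
}

assert_genes_df <- function(genes) {
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) {
    stop("gene table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("gene_id values must be unique", call. = FALSE)
  }
  if (any(genes$start < 0) || any(genes$end <= genes$start)) {
    stop("gene intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  invisible(genes)
}

# deterministic integer id strings: zero-padded with a prefix
pad_id <- function(prefix, i, width = 4) {
  sprintf(paste0(prefix, "%0", width, "d"), i)
}
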