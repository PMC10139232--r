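#  In-silico multiplex PCR: IUPAC-degenerate primer binding-site search on
#  both strands with a protected 3' window, amplicon prediction with dye
#  channel assignment, and per-primer/per-template mismatch reports.

# 16 x 16 logical lookup: does primer base p (IUPAC) accept template base t?
# Template ambiguity codes other than N are expanded too; template N matches
# nothing except primer N (conservative: unknown sequence never counts as a
# primer match).
.iupac_match_matrix <- local({
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  sets <- strsplit(unname(Biostrings::IUPAC_CODE_MAP), "")
  names(sets) <- codes
  m <- matrix(FALSE, length(codes), length(codes),
              dimnames = list(primer = codes, template = codes))
  for (p in codes) {
    for (t in codes) {
      if (t == "N") {
        m[p, t] <- p == "N"
      } else {
        m[p, t] <- all(sets[[t]] %in% sets[[p]])
      }
    }
  }
  m
})

.seq_chars <- function(x) {
  x <- toupper(as.character(x))
  strsplit(x, "", fixed = TRUE)[[1]]
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.as_template_list <- function(templates) {
  if (methods::is(templates, "DNAStringSet")) {
    stats::setNames(as.character(templates), names(templates))
  } else if (methods::is(templates, "DNAString")) {
    c(template = as.character(templates))
  } else if (is.character(templates)) {
    if (is.null(names(templates))) {
      names(templates) <- if (length(templates) == 1L) "template" else
        paste0("template", seq_along(templates))
    }
    templates
  } else {
    stop("templates must be a character vector or a Biostrings DNAStringSet",
         call. = FALSE)
  }
}

#' Read FASTA template sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' character vector usable by the in-silico PCR functions.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_templates <- function(path) {
  .as_template_list(Biostrings::readDNAStringSet(path))
}

# mismatch profile of `pattern` (IUPAC) against every offset of `template`;
# returns an integer matrix [offset, primer position] is implicit: we only
# need counts and the protected-window check, both vectorized over offsets
.scan_one_strand <- function(pattern_chars, tmpl_chars, max_mismatches,
                             protected) {
  L <- length(pattern_chars)
  N <- length(tmpl_chars) - L + 1L
  if (N < 1L) return(NULL)
  mism <- matrix(FALSE, N, L)
  for (j in seq_len(L)) {
    mism[, j] <- !.iupac_match_matrix[pattern_chars[j],
                                      tmpl_chars[j:(j + N - 1L)]]
  }
  counts <- rowSums(mism)
  ok <- counts <= max_mismatches
  if (length(protected)) {
    ok <- ok & rowSums(mism[, protected, drop = FALSE]) == 0L
  }
  hits <- which(ok)
  if (!length(hits)) return(NULL)
  list(start = hits - 1L, mismatches = counts[hits],
       positions = lapply(hits, function(i) which(mism[i, ])))
}

#' Find primer binding sites on a template
#'
#' Scans both strands. IUPAC degeneracy codes in the primer match their base
#' sets (Y accepts C or T, ...); a template N is never accepted by anything
#' but a primer N. No mismatch is tolerated in the `protect_3prime` terminal
#' bases at the primer's 3' end — polymerase extension is most sensitive
#' there, which is how the assay's S5-specific SFB primer rejects the S5'
#' point mutant.
#'
#' Coordinates are 0-based half-open on the forward strand; mismatch
#' positions are 1-based from the primer's 5' end.
#'
#' @param primer a primer name from the panel, a row of `panel$primers`, or a
#'   list/data.frame with `name` and `sequence`.
#' @param template a sequence (character or `DNAString`), or a named vector /
#'   `DNAStringSet` of length 1.
#' @param max_mismatches maximum mismatches outside the protected window
#'   (default 2).
#' @param protect_3prime number of 3'-terminal bases with zero tolerance
#'   (default 3).
#' @param panel optional panel used to resolve a primer given by name.
#' @return data.frame of binding sites: `primer`, `template`, `strand`
#'   (`forward`/`reverse`), `start`, `end`, `mismatches`,
#'   `mismatch_positions` (comma-joined, 1-based from 5').
#' @export
find_binding_sites <- function(primer, template, max_mismatches = 2,
                               protect_3prime = 3, panel = NULL) {
  stopifnot(max_mismatches >= 0, protect_3prime >= 0)
  pr <- .resolve_primer(primer, panel)
  tmpl <- .as_template_list(template)
  stopifnot(length(tmpl) == 1L)
  tmpl_chars <- .seq_chars(tmpl[[1]])
  if (!length(tmpl_chars)) stop("empty template", call. = FALSE)
  p_chars <- .seq_chars(pr$sequence)
  L <- length(p_chars)
  out <- list()
  # forward strand: primer read as-is; 3' end = last positions
  protected <- if (protect_3prime > 0)
    seq.int(max(1L, L - protect_3prime + 1L), L) else integer(0)
  fwd <- .scan_one_strand(p_chars, tmpl_chars, max_mismatches, protected)
  if (!is.null(fwd)) {
    out[[1L]] <- data.frame(
      primer = pr$name, template = names(tmpl), strand = "forward",
      start = fwd$start, end = fwd$start + L, mismatches = fwd$mismatches,
      mismatch_positions = vapply(fwd$positions, paste, character(1),
                                  collapse = ","),
      stringsAsFactors = FALSE)
  }
  # reverse strand: compare the primer's reverse complement on the forward
  # strand; pattern position j corresponds to primer position L - j + 1
  rc_chars <- .seq_chars(.revcomp(pr$sequence))
  protected_rc <- if (protect_3prime > 0) seq_len(min(protect_3prime, L)) else
    integer(0)
  rev <- .scan_one_strand(rc_chars, tmpl_chars, max_mismatches, protected_rc)
  if (!is.null(rev)) {
    out[[length(out) + 1L]] <- data.frame(
      primer = pr$name, template = names(tmpl), strand = "reverse",
      start = rev$start, end = rev$start + L, mismatches = rev$mismatches,
      mismatch_positions = vapply(rev$positions, function(p)
        paste(sort(L - p + 1L), collapse = ","), character(1)),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(primer = character(0), template = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      mismatch_positions = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.resolve_primer <- function(primer, panel = NULL) {
  if (is.character(primer) && length(primer) == 1L) {
    if (is.null(panel)) panel <- load_default_panel()
    row <- panel$primers[panel$primers$name == primer, , drop = FALSE]
    if (nrow(row) == 0L) {
      # bare sequence
      return(list(name = "primer", sequence = primer, label = NA_character_))
    }
    return(list(name = row$name, sequence = row$sequence, label = row$label))
  }
  list(name = primer$name %||% "primer", sequence = primer$sequence,
       label = primer$label %||% NA_character_)
}

#' Predict multiplex PCR amplicons on a template
#'
#' Pairs every forward-strand binding site with every downstream
#' reverse-strand site within `max_len`. The amplicon length spans primer to
#' primer (both footprints included), matching how the assay's expected
#' fragment sizes are computed from sequence. The dye channel is the labeled
#' primer's channel when exactly one of the two primers is labeled.
#'
#' @param primers a data.frame like `panel$primers` (name, sequence, label),
#'   or a character vector of panel primer names.
#' @param template a single sequence (character or `DNAString`).
#' @param max_len maximum amplicon length in nt (default 1000).
#' @inheritParams find_binding_sites
#' @return data.frame of amplicons: `fwd_primer`, `rev_primer`, `start`,
#'   `end`, `length`, `channel`, `fwd_mismatches`, `rev_mismatches`, sorted
#'   by template position then length.
#' @export
predict_amplicons <- function(primers, template, max_len = 1000,
                              max_mismatches = 2, protect_3prime = 3,
                              panel = NULL) {
  stopifnot(max_len > 0)
  if (is.character(primers)) {
    if (is.null(panel)) panel <- load_default_panel()
    primers <- panel$primers[panel$primers$name %in% primers, , drop = FALSE]
  }
  sites <- do.call(rbind, lapply(seq_len(nrow(primers)), function(i) {
    s <- find_binding_sites(primers[i, ], template,
                            max_mismatches = max_mismatches,
                            protect_3prime = protect_3prime, panel = panel)
    s$label <- rep(primers$label[i], nrow(s))
    s
  }))
  empty <- data.frame(fwd_primer = character(0), rev_primer = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), channel = character(0),
                      fwd_mismatches = integer(0), rev_mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(sites) || nrow(sites) == 0L) return(empty)
  fwd <- sites[sites$strand == "forward", , drop = FALSE]
  rev <- sites[sites$strand == "reverse", , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      if (rev$start[j] < fwd$end[i]) next
      len <- rev$end[j] - fwd$start[i]
      if (len > max_len) next
      labels <- c(fwd$label[i], rev$label[j])
      labeled <- labels[!is.na(labels)]
      rows[[length(rows) + 1L]] <- data.frame(
        fwd_primer = fwd$primer[i], rev_primer = rev$primer[j],
        start = fwd$start[i], end = rev$end[j], length = len,
        channel = if (length(labeled) == 1L) labeled else NA_character_,
        fwd_mismatches = fwd$mismatches[i],
        rev_mismatches = rev$mismatches[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binding-site mismatch report over primers x templates
#'
#' For every primer/template pair, the best (fewest-mismatch) binding site
#' under the thresholds, or a `no_site` flag predicting amplification
#' failure — the pattern by which an S-allele with multiple mutations under
#' a universal primer escapes the multiplex.
#'
#' @param primers a data.frame like `panel$primers`, or panel primer names.
#' @param templates named character vector or `DNAStringSet`.
#' @inheritParams find_binding_sites
#' @return data.frame: `primer`, `template`, `no_site`, `mismatches`,
#'   `mismatch_positions`, `strand`, `start`.
#' @export
binding_report <- function(primers, templates, max_mismatches = 2,
                           protect_3prime = 3, panel = NULL) {
  if (is.character(primers)) {
    if (is.null(panel)) panel <- load_default_panel()
    primers <- panel$primers[panel$primers$name %in% primers, , drop = FALSE]
  }
  tmpl <- .as_template_list(templates)
  rows <- list()
  for (i in seq_len(nrow(primers))) {
    for (t in names(tmpl)) {
      s <- find_binding_sites(primers[i, ], tmpl[t],
                              max_mismatches = max_mismatches,
                              protect_3prime = protect_3prime, panel = panel)
      rows[[length(rows) + 1L]] <- if (nrow(s) == 0L) {
        data.frame(primer = primers$name[i], template = t, no_site = TRUE,
                   mismatches = NA_integer_,
                   mismatch_positions = NA_character_,
                   strand = NA_character_, start = NA_integer_,
                   stringsAsFactors = FALSE)
      } else {
        best <- s[which.min(s$mismatches), , drop = FALSE]
        data.frame(primer = primers$name[i], template = t, no_site = FALSE,
                   mismatches = best$mismatches,
                   mismatch_positions = best$mismatch_positions,
                   strand = best$strand, start = best$start,
                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
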