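#' Dye channels of the four-colour capillary assay
#'
#' The multiplex runs four fluorophores in one capillary: 6-FAM (blue, `B`,
#' universal S-RNase detection and SC discrimination), VIC (green, `G`, MGST
#' alleles), NED (yellow, `Y`, the PaveIF-1A internal control) and PET (red,
#' `R`, allele-specific confirmation fragments).
#'
#' @return A data.frame with columns `code` (B/G/Y/R), `dye_name` and `colour`.
#' @export
#' @examples
#' dye_channels()
dye_channels <- function() {
  data.frame(
    code     = c("B", "G", "Y", "R"),
    dye_name = c("6-FAM", "VIC", "NED", "PET"),
    colour   = c("blue", "green", "yellow", "red"),
    stringsAsFactors = FALSE
  )
}

# case-insensitive lookup table: dye strings seen in exports -> channel code
.dye_aliases <- local({
  ch <- list(
    B = c("b", "blue", "6-fam", "fam", "6fam"),
    G = c("g", "green", "vic"),
    Y = c("y", "yellow", "black", "ned"),
    R = c("r", "red", "pet")
  )
  stats::setNames(rep(names(ch), lengths(ch)), unlist(ch))
})

#' Normalize a dye label to a channel code
#'
#' Accepts channel letters (`"B"`), dye names (`"6-FAM"`, `"VIC"`, `"NED"`,
#' `"PET"`), and colour words (`"blue"`, ... ; `"black"` maps to the yellow
#' channel, as NED traces are conventionally drawn black). Case-insensitive.
#'
#' @param dye character vector of dye labels.
#' @return character vector of channel codes (`B`, `G`, `Y`, `R`).
#' @export
normalize_dye <- function(dye) {
  key <- tolower(trimws(as.character(dye)))
  out <- .dye_aliases[key]
  bad <- is.na(out) | !nzchar(key)
  if (any(bad)) {
    stop("unknown dye label(s): ", paste(unique(dye[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

# canonical ordering used to sort S-allele pairs in a genotype call
.canonical_allele_order <- c(
  "S1", "S2", "S3", "S3p", "S4", "S4p", "S5", "S5p", "S6", "S7", "S9", "S10",
  "S12", "S13", "S14/S23", "S16", "S21/S25", "S22", "S24", "S28", "S29",
  "S30", "S31", "S34", "S38", "S54", "MGSTwt", "MGSTins", "MGSTdel",
  "PaveIF-1A", "S?"
)

order_alleles <- function(x) {
  idx <- match(x, .canonical_allele_order)
  idx[is.na(idx)] <- length(.canonical_allele_order) + 1L
  x[order(idx, x)]
}

#' Render allele labels for display
#'
#' Internally the self-compatible alleles use ASCII labels (`S3p`, `S4p`,
#' `S5p`); for display they are rendered with a prime (`S3'`).
#'
#' @param allele character vector of internal allele labels.
#' @return character vector of display labels.
#' @export
display_allele <- function(allele) {
  sub("^(S[0-9]+)p$", "\\1'", allele)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
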