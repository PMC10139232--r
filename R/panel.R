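#  Panel: the assay definition (primers, fragment bins, control, dosage
#  calibrations). The packaged default holds the published constants of the
#  one-tube sweet cherry S-allele/MGST assay.

.default_primers <- function() {
  p <- function(name, seq, label, conc, alleles, ref = "") {
    data.frame(name = name, sequence = seq, label = label,
               final_concentration = conc, recognized_alleles = alleles,
               reference = ref, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    p("PaConsI-CTTC-F", "CTTGTTCTTGCTTTTGCTTTCTTC", NA, 0.19,
      "S1;S2;S5;S6;S7;S12;S14;S16;S23;S25"),
    p("PaConsI-GTTC-F", "CTTGTTCTTGGTTTTGCTTTCTTC", NA, 0.33, "S3;S3p"),
    p("PaConsI-CTCC-F", "CTTGTTCTTGCTTTCGCTTTCTTC", NA, 0.18, "S4;S4p;S5p;S10"),
    p("PaConsI-CTTT-F", "CTTGTTCTTGCTTTTGTTTTCTTC", NA, 0.50, "S22;S24"),
    p("PaConsI-CGTC-F", "CTTGTTCTTGCTTGTGCTTTCTTC", NA, 0.22, "S9"),
    p("PaConsI-R2", "GCCATTGTTGCACAAATTGA", "B", 0.21, "all S-RNases",
      "published"),
    p("S-RNase-S1-In2-F", "TGGTCTCCCTAACATGACCC", NA, 0.175, "S1"),
    p("S-RNase-S2-In2-F", "TGAACGAAATCTCAACTCATAAATC", NA, 0.43, "S2"),
    p("S-RNase-S6+S24-In2-F", "TCATTTTGTTTTCCACCTACCC", NA, 0.18, "S6;S24"),
    p("S-RNase-S7-In2-F", "TCTGTCTGGTTGTTTTGCTGG", NA, 0.17, "S7"),
    p("S-RNase-S9+S22-In2-F", "TCTAATAATGGATCTGCTCATCTAATT", NA, 0.70,
      "S9;S22"),
    p("S-RNase-S12-In2-F", "GCTAACCCTTACATTTTGACCC", NA, 0.25, "S12"),
    p("S-RNase-S13-In2-F", "ATATGTCTGTCTATCTATCTGTTTTCTCA", NA, 0.40, "S13"),
    p("S-RNases-Ex3-R", "GTATCATTGCCACYTTCCACG", "R", 0.24, "most S-RNases"),
    p("PaSFB3-F", "CCACAATTTGAACGTCAGAAC", NA, 0.28, "S3", "published"),
    p("PaSFB3-short-R", "TCTGTGTTTTCTAAAGGATGGC", "B", 0.28, "S3"),
    p("PaSFB4+4'-F", "TCTAGCTTTTATTCTTGCGAGG", "B", 0.155, "S4;S4p"),
    p("PaSFB4+4'-R", "GATCTCCTATGCCCCTAGAGAA", NA, 0.155, "S4;S4p"),
    p("PaSFB-S5-F", "GCTTGGACAAAATTGACTTGTG", NA, 0.20, "S5"),
    p("PaSFB-S5+S5'-R", "GATCACAATCACCCAAAGGAGG", "B", 0.20, "S5;S5p"),
    p("S-RNase-S54-F", "CTCTCTTTGGTCTTCTTCTTGTGC", "R", 0.17, "S54"),
    p("S-RNase-S54-R", "GCTTGCTGATTGTAAATAAACTGC", NA, 0.17, "S54"),
    p("MGST-TE-in-F", "ATAAATGGGTCAGTGGTGGG", NA, 0.105, "MGSTins"),
    p("MGST-TE-out-F", "AAAGCCTTCAAGTGGGAAAG", NA, 0.105, "MGSTwt;MGSTdel"),
    p("MGST-TE-out-R", "TTGCTTACAGGTCATTACTTACACG", "G", 0.105,
      "MGSTwt;MGSTdel;MGSTins", "published"),
    p("PaveIF-1A-F", "GCCCAAGTGCTTCGTATGCT", "Y", 0.05, "PaveIF-1A",
      "published"),
    p("PaveIF-1A-R", "ATCACCGGCTGCAATCCA", NA, 0.05, "PaveIF-1A", "published")
  ))
}

.default_fragments <- function() {
  f <- function(id, channel, observed, expected, alleles, role,
                confirmatory_for = NA_character_, expected2 = NA_real_,
                provisional = FALSE) {
    data.frame(id = id, channel = channel, observed = observed,
               expected = expected, expected2 = expected2, alleles = alleles,
               role = role, confirmatory_for = confirmatory_for,
               provisional = provisional, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # blue (6-FAM): universal S-RNase intron-1 fragments + SC/SI SFB markers
    f("B83",  "B",  83,  90, "S5",      "sfb_marker", "S5"),
    f("B122", "B", 122, 125, "S3",      "sfb_marker", "S3"),
    f("B177", "B", 177, 181, "S4p",     "sfb_marker", "S4p"),
    f("B181", "B", 181, 184, "S4",      "sfb_marker", "S4"),
    f("B227", "B", 227, 233, "S3;S3p",  "universal_sRNase"),
    f("B323", "B", 323, 330, "S14/S23", "universal_sRNase"),
    f("B337", "B", 337, 343, "S2",      "universal_sRNase"),
    f("B338", "B", 338, 344, "S12",     "universal_sRNase"),
    f("B339", "B", 339, 340, "S7",      "universal_sRNase"),
    f("B350", "B", 350, 355, "S9",      "universal_sRNase"),
    f("B367", "B", 367, 374, "S21/S25", "universal_sRNase"),
    f("B373", "B", 373, 376, "S1",      "universal_sRNase", expected2 = 379),
    f("B384", "B", 384, 391, "S5p",     "universal_sRNase"),
    f("B385", "B", 385, 392, "S5",      "universal_sRNase"),
    f("B406", "B", 406, 412, "S16",     "universal_sRNase"),
    f("B415", "B", 415, 421, "S22",     "universal_sRNase"),
    f("B435", "B", 435, 442, "S6",      "universal_sRNase"),
    f("B443", "B", 443, 450, "S4;S4p",  "universal_sRNase"),
    # alleles published without a fragment-analysis size: provisional bins at
    # expected size + per-channel mobility offset (6-FAM runs ~5 nt short)
    f("B203", "B", 203, 208, "S31", "universal_sRNase", provisional = TRUE),
    f("B304", "B", 304, 309, "S38", "universal_sRNase", provisional = TRUE),
    f("B333", "B", 333, 338, "S29", "universal_sRNase", provisional = TRUE),
    f("B358", "B", 358, 363, "S10", "universal_sRNase", provisional = TRUE),
    f("B362", "B", 362, 367, "S28", "universal_sRNase", provisional = TRUE),
    f("B372", "B", 372, 377, "S34", "universal_sRNase", provisional = TRUE),
    f("B379", "B", 379, 384, "S30", "universal_sRNase", provisional = TRUE),
    f("B416", "B", 416, 421, "S24", "universal_sRNase", provisional = TRUE),
    # red (PET): allele-specific confirmation fragments
    f("R119", "R", 119, 121, "S13",    "specific_confirm"),
    f("R147", "R", 147, 148, "S12",    "specific_confirm", "S12",
      expected2 = 149),
    f("R172", "R", 172, 171, "S54",    "specific_confirm"),
    f("R223", "R", 223, 225, "S6;S24", "specific_confirm", "S6;S24"),
    f("R240", "R", 240, 240, "S1",     "specific_confirm", "S1"),
    f("R249", "R", 249, 250, "S7",     "specific_confirm", "S7"),
    f("R258", "R", 258, 260, "S22",    "specific_confirm", "S22",
      expected2 = 253),
    f("R266", "R", 266, 266, "S9",     "specific_confirm", "S9"),
    f("R302", "R", 302, 303, "S2",     "specific_confirm", "S2"),
    # green (VIC): MGST promoter alleles
    f("G132", "G", 132, 137, "MGSTdel", "mgst"),
    f("G140", "G", 140, 145, "MGSTwt",  "mgst"),
    f("G192", "G", 192, 197, "MGSTins", "mgst"),
    # yellow (NED): diploid single-copy internal control
    f("Y118", "Y", 118, 120, "PaveIF-1A", "control")
  ))
}

.default_calibrations <- function() {
  entry <- function(ratio_id, num, den, mean_homo, sd_homo, mean_het, sd_het,
                    p_value, informative, c_num_homo, c_den_homo, c_num_het,
                    c_den_het) {
    data.frame(ratio_id = ratio_id, num = num, den = den,
               mean_homo = mean_homo, sd_homo = sd_homo,
               mean_het = mean_het, sd_het = sd_het, p_value = p_value,
               informative = informative, c_num_homo = c_num_homo,
               c_den_homo = c_den_homo, c_num_het = c_num_het,
               c_den_het = c_den_het, stringsAsFactors = FALSE)
  }
  list(
    S3_only = list(
      scenario = "S3_only", trigger = "S3",
      homo_genotype = c("S3", "S3p"), het_genotype = c("S3", "S?"),
      provisional = FALSE,
      entries = rbind(
        entry("ctrl_sfb122",  "Y118", "B122", 1.75, 0.33, 1.65, 0.26,
              0.20, FALSE, 2, 1, 2, 1),
        entry("ctrl_rnase227", "Y118", "B227", 1.17, 0.21, 2.12, 0.25,
              2.08e-22, TRUE, 2, 2, 2, 1),
        entry("rnase227_sfb122", "B227", "B122", 1.50, 0.22, 0.78, 0.15,
              4.77e-19, TRUE, 2, 1, 1, 1)
      )
    ),
    S3p_only = list(
      scenario = "S3p_only", trigger = "S3p",
      homo_genotype = c("S3p", "S3p"), het_genotype = c("S3p", "S?"),
      provisional = FALSE,
      entries = rbind(
        entry("ctrl_rnase227", "Y118", "B227", 1.30, 0.16, 2.25, 0.22,
              3.48e-26, TRUE, 2, 2, 2, 1),
        entry("mgst_ctrl", "G140", "Y118", 1.14, 0.14, 1.10, 0.13,
              0.28, FALSE, 2, 2, 2, 2),
        entry("mgst_rnase227", "G140", "B227", 1.47, 0.16, 2.47, 0.27,
              6.19e-22, TRUE, 2, 2, 2, 1)
      )
    ),
    S4p_only = list(
      scenario = "S4p_only", trigger = "S4p",
      homo_genotype = c("S4p", "S4p"), het_genotype = c("S4p", "S?"),
      provisional = FALSE,
      entries = rbind(
        entry("ctrl_sfb177", "Y118", "B177", 0.53, 0.06, 1.04, 0.13,
              7.44e-22, TRUE, 2, 2, 2, 1),
        entry("ctrl_rnase443", "Y118", "B443", 0.66, 0.08, 1.34, 0.13,
              2.76e-28, TRUE, 2, 2, 2, 1),
        entry("rnase443_sfb177", "B443", "B177", 0.81, 0.05, 0.78, 0.05,
              0.052, FALSE, 2, 2, 1, 1)
      )
    ),
    # no published quantitation exists for an S5'-only genotype; the S3'
    # calibration shape is reused with the S5' S-RNase bin and marked
    # provisional (calls through it carry a QC warning)
    S5p_only = list(
      scenario = "S5p_only", trigger = "S5p",
      homo_genotype = c("S5p", "S5p"), het_genotype = c("S5p", "S?"),
      provisional = TRUE,
      entries = entry("ctrl_rnase384", "Y118", "B384", 1.30, 0.16, 2.25, 0.22,
                      NA_real_, TRUE, 2, 2, 2, 1)
    )
  )
}

#' Load the packaged default assay panel
#'
#' Builds the panel object holding the published constants of the one-tube
#' assay: the 27-primer multiplex (8 fluorescently labeled), the dye-channel
#' fragment bins keyed by *observed* fragment-analysis sizes (electrophoretic
#' mobility makes labeled fragments run 0-7 nt shorter than their sequence
#' length; expected sizes are retained for in-silico PCR), the PaveIF-1A
#' internal control bin, and the peak-height dosage calibrations used to
#' resolve the S3S3', S3'S3', S4'S4' and S5'S5' ambiguities. Alleles published
#' without a measured fragment-analysis size are given provisional bins at the
#' expected size plus the per-channel mobility offset and flagged as such.
#'
#' @return An object of class `cherry_panel`: a list with elements `primers`,
#'   `fragments`, `control_fragment`, `dye_offset_model`, `calibrations`,
#'   `bin_tolerance_default`, `efficiencies` (relative per-fragment
#'   amplification efficiencies fitted from the calibration tables, control
#'   fixed at 1) and `supported` (the allele labels fully supported by
#'   observed bins).
#' @export
#' @examples
#' panel <- load_default_panel()
#' nrow(panel$primers)                      # 27
#' sum(!is.na(panel$primers$label))         # 8 labeled
#' fragments_for_allele(panel, "S3")$id     # B122, B227
load_default_panel <- function() {
  fragments <- .default_fragments()
  panel <- structure(list(
    primers = .default_primers(),
    fragments = fragments,
    control_fragment = fragments[fragments$role == "control", , drop = FALSE],
    dye_offset_model = data.frame(
      channel = c("B", "G", "Y", "R"),
      offset  = c(-5, -5, -2, -1),
      window  = c(2, 2, 2, 1),
      stringsAsFactors = FALSE
    ),
    calibrations = .default_calibrations(),
    bin_tolerance_default = 0.45,
    supported = list(
      si = c("S1", "S2", "S3", "S4", "S5", "S6", "S7", "S9", "S12", "S13",
             "S14/S23", "S16", "S22", "S54"),
      sc = c("S3p", "S4p", "S5p"),
      mgst = c("MGSTwt", "MGSTins", "MGSTdel")
    )
  ), class = "cherry_panel")
  panel$efficiencies <- default_efficiencies(panel$calibrations)
  panel
}

split_alleles <- function(x) strsplit(x, ";", fixed = TRUE)

#' All allele labels known to a panel
#'
#' @param panel a `cherry_panel`.
#' @param supported if `TRUE`, only the S-alleles fully supported by observed
#'   (non-provisional) fragment bins: 14 self-incompatible classes plus the 3
#'   self-compatible alleles. `S14/S23` is a composite class (the two alleles
#'   share the universal fragment and were never resolved individually); the
#'   `S21/S25` bin is recognized when seen but is detect-only.
#' @param type one of `"s"`, `"mgst"`, `"all"`.
#' @return character vector of allele labels.
#' @export
panel_alleles <- function(panel, supported = FALSE, type = c("s", "mgst", "all")) {
  type <- match.arg(type)
  if (supported) {
    out <- switch(type,
                  s = c(panel$supported$si, panel$supported$sc),
                  mgst = panel$supported$mgst,
                  all = unlist(panel$supported, use.names = FALSE))
    return(order_alleles(out))
  }
  all <- unique(unlist(split_alleles(panel$fragments$alleles)))
  out <- switch(type,
                s = setdiff(all, c(panel$supported$mgst, "PaveIF-1A")),
                mgst = intersect(all, panel$supported$mgst),
                all = all)
  order_alleles(out)
}

#' Fragment bins indicating an allele
#'
#' @param panel a `cherry_panel`.
#' @param allele an allele label known to the panel (e.g. `"S3"`, `"S3p"`,
#'   `"MGSTwt"`).
#' @return The panel's fragment rows whose allele list contains `allele`, in
#'   ascending observed size.
#' @export
#' @examples
#' fragments_for_allele(load_default_panel(), "S13")  # the single R119 bin
fragments_for_allele <- function(panel, allele) {
  stopifnot(inherits(panel, "cherry_panel"), is.character(allele),
            length(allele) == 1L)
  known <- unique(unlist(split_alleles(panel$fragments$alleles)))
  if (!allele %in% known) {
    stop("unknown allele label: ", allele, call. = FALSE)
  }
  hit <- vapply(split_alleles(panel$fragments$alleles),
                function(a) allele %in% a, logical(1))
  out <- panel$fragments[hit, , drop = FALSE]
  out[order(out$observed), , drop = FALSE]
}

#' Alleles indicated by a peak position
#'
#' Looks up the unique fragment bin within `tolerance` of `size` in `channel`.
#'
#' @param panel a `cherry_panel`.
#' @param channel channel code (`B`, `G`, `Y`, `R`).
#' @param size fragment size in nt (must be positive).
#' @param tolerance bin half-width in nt; defaults to the panel's.
#' @return character vector of allele labels (empty if no bin is within
#'   tolerance).
#' @export
#' @examples
#' alleles_for_fragment(load_default_panel(), "B", 227)  # S3 and S3p
alleles_for_fragment <- function(panel, channel, size,
                                 tolerance = panel$bin_tolerance_default) {
  stopifnot(size > 0)
  frag <- panel$fragments[panel$fragments$channel == channel, , drop = FALSE]
  d <- abs(frag$observed - size)
  hit <- which(d <= tolerance)
  if (length(hit) == 0L) return(character(0))
  if (length(hit) > 1L) {
    stop(sprintf("size %.2f in channel %s falls within tolerance of bins %s",
                 size, channel, paste(frag$id[hit], collapse = ", ")),
         call. = FALSE)
  }
  split_alleles(frag$alleles[hit])[[1]]
}

#' Validate a panel against its structural invariants
#'
#' Checks the rules the caller relies on: positive sizes, observed sizes not
#' exceeding expected sizes by more than the 1 nt sizing slack (labeled
#' fragments run short, never meaningfully long), non-empty allele lists,
#' >= 1 nt separation between distinct bins of one channel, a bin tolerance
#' below half the minimum within-channel separation, and calibration entries
#' referencing known fragments with positive SDs.
#'
#' @param panel a `cherry_panel`.
#' @return character vector of violation messages; empty when the panel is
#'   valid. Violations are returned, not raised.
#' @export
validate_panel <- function(panel) {
  v <- character(0)
  fr <- panel$fragments
  if (any(fr$observed <= 0 | fr$expected <= 0, na.rm = TRUE)) {
    v <- c(v, "fragments: observed and expected sizes must be positive")
  }
  exp_hi <- pmax(fr$expected, ifelse(is.na(fr$expected2), fr$expected,
                                     fr$expected2))
  run_long <- which(!is.na(fr$observed) & fr$observed > exp_hi + 1)
  for (i in run_long) {
    v <- c(v, sprintf(
      "fragment %s: observed size %.1f exceeds expected %.1f by more than 1 nt",
      fr$id[i], fr$observed[i], exp_hi[i]))
  }
  if (any(!nzchar(fr$alleles))) {
    v <- c(v, "fragments: every bin must list at least one allele")
  }
  min_sep <- Inf
  for (ch in unique(fr$channel)) {
    s <- sort(fr$observed[fr$channel == ch])
    if (length(s) > 1L) {
      d <- diff(s)
      min_sep <- min(min_sep, d)
      for (j in which(d < 1)) {
        v <- c(v, sprintf(
          "channel %s: bins at %.2f and %.2f are separated by %.2f nt (< 1 nt)",
          ch, s[j], s[j + 1L], d[j]))
      }
    }
  }
  if (is.finite(min_sep) && panel$bin_tolerance_default >= min_sep / 2) {
    v <- c(v, sprintf(
      "bin_tolerance_default %.2f is not below half the minimum within-channel separation (%.2f/2)",
      panel$bin_tolerance_default, min_sep))
  }
  if (panel$bin_tolerance_default <= 0) {
    v <- c(v, "bin_tolerance_default must be positive")
  }
  if (any(panel$primers$final_concentration <= 0)) {
    v <- c(v, "primers: final concentrations must be positive")
  }
  iupac <- paste0("^[", paste(names(Biostrings::IUPAC_CODE_MAP), collapse = ""),
                  "]+$")
  bad_seq <- !grepl(iupac, toupper(panel$primers$sequence))
  for (n in panel$primers$name[bad_seq]) {
    v <- c(v, sprintf("primer %s: sequence contains non-IUPAC characters", n))
  }
  multi_label <- !is.na(panel$primers$label) &
    !panel$primers$label %in% dye_channels()$code
  for (n in panel$primers$name[multi_label]) {
    v <- c(v, sprintf("primer %s: label is not a known dye channel", n))
  }
  for (cal in panel$calibrations) {
    e <- cal$entries
    if (any(c(e$sd_homo, e$sd_het) <= 0)) {
      v <- c(v, sprintf("calibration %s: SDs must be positive", cal$scenario))
    }
    miss <- setdiff(unique(c(e$num, e$den)), fr$id)
    if (length(miss)) {
      v <- c(v, sprintf("calibration %s: unknown fragment id(s) %s",
                        cal$scenario, paste(miss, collapse = ", ")))
    }
    ctrl_num <- e$informative & e$num %in% fr$id[fr$role == "control"]
    bad <- ctrl_num & e$mean_het <= e$mean_homo
    for (r in e$ratio_id[bad]) {
      v <- c(v, sprintf(
        "calibration %s ratio %s: control-normalized heterozygous mean must exceed the two-copy mean",
        cal$scenario, r))
    }
  }
  v
}

#' @export
print.cherry_panel <- function(x, ...) {
  fr <- x$fragments
  cat("<cherry_panel>\n")
  cat(sprintf("  %d primers (%d dye-labeled), %d fragment bins (%d provisional)\n",
              nrow(x$primers), sum(!is.na(x$primers$label)), nrow(fr),
              sum(fr$provisional)))
  cat(sprintf("  control: %s (%s, observed %g nt)\n",
              x$control_fragment$alleles, x$control_fragment$channel,
              x$control_fragment$observed))
  cat(sprintf("  supported S-alleles: %s\n",
              paste(display_allele(panel_alleles(x, supported = TRUE)),
                    collapse = " ")))
  cat(sprintf("  bin tolerance: %.2f nt; %d dosage calibrations\n",
              x$bin_tolerance_default, length(x$calibrations)))
  invisible(x)
}

#' Serialize a panel to JSON
#'
#' The JSON mirrors the panel structure so users can extend the assay with new
#' alleles and load the result with [read_panel()].
#'
#' @param panel a `cherry_panel`.
#' @param path file path to write to.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  x <- unclass(panel)
  x$efficiencies <- as.list(x$efficiencies)
  jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a panel from JSON
#'
#' @param path file written by [write_panel()] (or hand-edited in the same
#'   shape).
#' @param validate if `TRUE` (default), stop when [validate_panel()] reports
#'   violations.
#' @return a `cherry_panel`.
#' @export
read_panel <- function(path, validate = TRUE) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (col in c("expected2", "confirmatory_for")) {
    if (is.logical(x$fragments[[col]])) {
      x$fragments[[col]] <- if (col == "expected2") NA_real_ else NA_character_
    }
  }
  if (is.logical(x$primers$label)) x$primers$label <- NA_character_
  x$calibrations <- lapply(x$calibrations, function(cal) {
    cal$homo_genotype <- as.character(cal$homo_genotype)
    cal$het_genotype <- as.character(cal$het_genotype)
    cal
  })
  x$efficiencies <- unlist(x$efficiencies)
  panel <- structure(x, class = "cherry_panel")
  if (validate) {
    v <- validate_panel(panel)
    if (length(v)) {
      stop("invalid panel:\n", paste(" -", v, collapse = "\n"), call. = FALSE)
    }
  }
  panel
}

#' Render the panel's primer and fragment tables as aligned text
#'
#' @param panel a `cherry_panel`.
#' @return character vector of lines (also printed when called interactively
#'   via `cat`).
#' @export
format_panel_tables <- function(panel) {
  pr <- panel$primers
  fr <- panel$fragments
  lines <- c(
    "== Primers ==",
    utils::capture.output(print(pr, row.names = FALSE)),
    "",
    "== Fragment bins (observed / expected, nt) ==",
    utils::capture.output(print(
      data.frame(id = fr$id, channel = fr$channel, observed = fr$observed,
                 expected = ifelse(is.na(fr$expected2), as.character(fr$expected),
                                   paste0(fr$expected, "/", fr$expected2)),
                 alleles = vapply(split_alleles(fr$alleles), function(a)
                   paste(display_allele(a), collapse = "; "), character(1)),
                 role = fr$role, provisional = fr$provisional),
      row.names = FALSE))
  )
  lines
}
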