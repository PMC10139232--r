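#  The genotype caller: peak-to-bin matching, allele inference with the
#  assay's confirmation rules, and genotype assembly with QC flags.

#' Match peaks of a run to panel fragment bins
#'
#' Each peak is assigned to the nearest same-channel bin within `tolerance`.
#' A peak equidistant (within tolerance) from two bins is never guessed at:
#' it stays unassigned and the ambiguity is recorded. When several peaks fall
#' in one bin the tallest is the match and the rest are kept as shoulder
#' peaks on the match (double-peaked amplicons from alternative PCR
#' chemistries are absorbed this way).
#'
#' @param run a [sample_run()].
#' @param panel a `cherry_panel`.
#' @param tolerance bin half-width in nt; must be positive and below half the
#'   minimum within-channel bin separation (0.45 nt by default, which
#'   resolves the 1-nt S5/S5' pair).
#' @return list with `matches` (data.frame: `fragment_id`, `channel`, `size`,
#'   `height`, `deviation`, `shoulders`), `unassigned` (peaks data.frame with
#'   an `ambiguous` flag) .
#' @export
bin_peaks <- function(run, panel, tolerance = panel$bin_tolerance_default) {
  fr <- panel$fragments
  min_sep <- min(unlist(lapply(split(fr$observed, fr$channel), function(s) {
    if (length(s) > 1L) diff(sort(s)) else Inf
  })))
  if (!is.finite(tolerance) || tolerance <= 0 || tolerance >= min_sep / 2) {
    stop(sprintf(
      "tolerance must be in (0, %.2f): half the minimum within-channel bin separation",
      min_sep / 2), call. = FALSE)
  }
  pk <- run$peaks
  n <- nrow(pk)
  bin_idx <- rep(NA_integer_, n)
  ambiguous <- rep(FALSE, n)
  for (i in seq_len(n)) {
    cand <- which(fr$channel == pk$channel[i])
    if (!length(cand)) next
    d <- abs(fr$observed[cand] - pk$size[i])
    within <- d <= tolerance
    if (!any(within)) next
    if (sum(within) > 1L && sum(d == min(d)) > 1L) {
      ambiguous[i] <- TRUE  # exact tie between two bins: never guess
      next
    }
    bin_idx[i] <- cand[which.min(d)]
  }
  matched <- which(!is.na(bin_idx))
  rows <- list()
  for (b in unique(bin_idx[matched])) {
    in_bin <- matched[bin_idx[matched] == b]
    main <- in_bin[which.max(pk$height[in_bin])]
    rows[[length(rows) + 1L]] <- data.frame(
      fragment_id = fr$id[b], channel = fr$channel[b], size = pk$size[main],
      height = pk$height[main], deviation = pk$size[main] - fr$observed[b],
      shoulders = length(in_bin) - 1L, stringsAsFactors = FALSE)
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fragment_id = character(0), channel = character(0),
               size = numeric(0), height = numeric(0), deviation = numeric(0),
               shoulders = integer(0), stringsAsFactors = FALSE)
  matches <- matches[order(match(matches$fragment_id, fr$id)), , drop = FALSE]
  rownames(matches) <- NULL
  un <- pk[is.na(bin_idx), , drop = FALSE]
  un$ambiguous <- ambiguous[is.na(bin_idx)]
  rownames(un) <- NULL
  list(matches = matches, unassigned = un)
}

.has <- function(ids, id) id %in% ids

# one AlleleCall row
.acall <- function(allele, status, fragments, note = "") {
  data.frame(allele = allele, status = status,
             fragments = paste(fragments, collapse = ";"), note = note,
             stringsAsFactors = FALSE)
}

#' Infer allele presence from matched fragments
#'
#' Applies the assay's interpretation matrix: control and MGST bins map
#' directly; the SC discrimination rules compare S-RNase and SFB fragments
#' (S3 = 122+227, S3' = 227 alone; S4 = 181+443, S4' = 177+443; S5 = 83+385,
#' S5' = 384 alone); alleles whose universal fragment is shared or nearly
#' shared (S1, S2, S6, S7, S9, S12, S22, S24) need their allele-specific red
#' confirmation fragment to be called `confirmed`, and are `unconfirmed` when
#' one of the two fragments is missing; S13 and S54 are called from their
#' single specific red fragment; remaining single-fragment bins give
#' `candidate` calls. An S3' call is never better than `candidate`: a true S3
#' with a failed SFB amplification is indistinguishable from S3'.
#'
#' @param matches the `matches` data.frame from [bin_peaks()].
#' @param panel a `cherry_panel`.
#' @return data.frame of allele calls: `allele`, `status` (`confirmed`,
#'   `candidate`, `unconfirmed`, `ambiguous`), `fragments`, `note`.
#' @export
infer_alleles <- function(matches, panel) {
  ids <- matches$fragment_id
  calls <- list()
  add <- function(...) calls[[length(calls) + 1L]] <<- .acall(...)

  # (a) control + MGST
  for (g in intersect(c("G132", "G140", "G192"), ids)) {
    allele <- panel$fragments$alleles[panel$fragments$id == g]
    add(allele, "confirmed", g)
  }
  if (.has(ids, "Y118")) add("PaveIF-1A", "confirmed", "Y118")

  # (b) S3 / S3': presence of the SFB 122 fragment separates them; 227 alone
  # is S3' but only ever as a candidate (SFB dropout would look identical)
  if (.has(ids, "B227")) {
    if (.has(ids, "B122")) {
      add("S3", "confirmed", c("B122", "B227"))
    } else {
      add("S3p", "candidate", "B227",
          "227 nt S-RNase fragment without the 122 nt SFB fragment; S3 with failed SFB amplification would look identical")
    }
  } else if (.has(ids, "B122")) {
    add("S3", "unconfirmed", "B122", "SFB fragment without the 227 nt S-RNase fragment")
  }

  # (c) S4 / S4': the 4-nt SFB deletion separates 177 (S4') from 181 (S4)
  if (.has(ids, "B443")) {
    got <- FALSE
    if (.has(ids, "B181")) { add("S4", "confirmed", c("B181", "B443")); got <- TRUE }
    if (.has(ids, "B177")) { add("S4p", "confirmed", c("B177", "B443")); got <- TRUE }
    if (!got) add("S4", "ambiguous", "B443",
                  "443 nt S-RNase fragment without an SFB fragment; S4 vs S4' unresolved")
  } else {
    if (.has(ids, "B181")) add("S4", "unconfirmed", "B181",
                               "S4 SFB fragment without the 443 nt S-RNase fragment")
    if (.has(ids, "B177")) add("S4p", "unconfirmed", "B177",
                               "S4' SFB fragment without the 443 nt S-RNase fragment")
  }

  # (d) S5 / S5': 1-nt S-RNase size difference plus the S5-specific SFB 83
  if (.has(ids, "B385")) {
    if (.has(ids, "B83")) add("S5", "confirmed", c("B83", "B385"))
    else add("S5", "unconfirmed", "B385",
             "385 nt S-RNase fragment without the 83 nt SFB confirmation")
  } else if (.has(ids, "B83")) {
    add("S5", "unconfirmed", "B83", "S5 SFB fragment without the 385 nt S-RNase fragment")
  }
  if (.has(ids, "B384")) add("S5p", "candidate", "B384")

  # (e) universal + specific-confirmation pairs
  confirm_pairs <- list(
    S1 = c("B373", "R240"), S2 = c("B337", "R302"), S7 = c("B339", "R249"),
    S9 = c("B350", "R266"), S12 = c("B338", "R147")
  )
  for (allele in names(confirm_pairs)) {
    pr <- confirm_pairs[[allele]]
    if (.has(ids, pr[1]) && .has(ids, pr[2])) add(allele, "confirmed", pr)
    else if (.has(ids, pr[1])) add(allele, "unconfirmed", pr[1],
                                   sprintf("universal fragment without the %s confirmation", pr[2]))
    else if (.has(ids, pr[2])) add(allele, "unconfirmed", pr[2],
                                   sprintf("confirmation fragment without the %s universal fragment", pr[1]))
  }

  # S6 / S24 share the red confirmation bin (both expected at 225 nt);
  # the blue fragment separates them (435 = S6; the 421-expected region
  # without the S22 red fragment = S24, on a provisional bin)
  r223 <- .has(ids, "R223")
  if (.has(ids, "B435")) {
    if (r223) add("S6", "confirmed", c("B435", "R223"))
    else add("S6", "unconfirmed", "B435", "universal fragment without the R223 confirmation")
  }
  if (.has(ids, "B416")) {
    if (r223) add("S24", "confirmed", c("B416", "R223"), "provisional blue bin")
    else add("S24", "unconfirmed", "B416", "provisional blue bin without the R223 confirmation")
  }
  if (.has(ids, "B415")) {
    if (.has(ids, "R258")) add("S22", "confirmed", c("B415", "R258"))
    else if (r223 && !.has(ids, "B435") && !.has(ids, "B416")) {
      add("S24", "candidate", c("B415", "R223"),
          "blue fragment in the S22 bin but red confirmation pattern favours S24 (observed S24 size not published)")
    } else {
      add("S22", "unconfirmed", "B415", "universal fragment without the R258 confirmation")
    }
  }
  if (r223 && !.has(ids, "B435") && !.has(ids, "B416") && !.has(ids, "B415")) {
    add("S6", "unconfirmed", "R223", "S6/S24 confirmation fragment without a matching universal fragment")
  }

  # (f) red-only specific alleles
  if (.has(ids, "R119")) add("S13", "confirmed", "R119")
  if (.has(ids, "R172")) add("S54", "confirmed", "R172")

  # (g) remaining single-fragment universal bins
  single <- c("S14/S23" = "B323", "S16" = "B406", "S21/S25" = "B367",
              "S10" = "B358", "S28" = "B362", "S29" = "B333", "S30" = "B379",
              "S31" = "B203", "S34" = "B372", "S38" = "B304")
  for (allele in names(single)) {
    id <- single[[allele]]
    if (.has(ids, id)) {
      prov <- panel$fragments$provisional[panel$fragments$id == id]
      add(allele, "candidate", id, if (prov) "provisional bin" else "")
    }
  }

  out <- if (length(calls)) do.call(rbind, calls) else
    .acall(character(0), character(0), character(0))[0, ]
  rownames(out) <- NULL
  out
}

.s_allele_calls <- function(allele_calls, panel) {
  s <- panel_alleles(panel, type = "s")
  allele_calls[allele_calls$allele %in% s &
                 allele_calls$status != "ambiguous", , drop = FALSE]
}

#' Assemble a genotype call from allele calls
#'
#' Two S-alleles are always expected. With exactly two detected they are
#' paired. With exactly one, the qualitative pattern cannot distinguish a
#' homozygote (or the S3S3' combination) from a heterozygote whose second
#' allele escapes the universal primers, so the peak-height dosage procedure
#' decides ([classify_single_allele_case()]); without the internal control
#' the dosage is impossible and the second allele is reported as `S?`. More
#' than two alleles raises a flag and all are reported. The MGST genotype is
#' the set of matched green bins; a single green bin is reported with
#' zygosity undetermined unless `mgst_dosage = TRUE`, in which case the
#' MGST/control height ratio classifies one versus two copies.
#'
#' @param allele_calls data.frame from [infer_alleles()].
#' @param run the [sample_run()] the calls came from.
#' @param panel a `cherry_panel`.
#' @param mgst_dosage classify MGST zygosity by dosage (default `FALSE`).
#' @param z_cut dosage indeterminacy cutoff (default 3).
#' @param tolerance bin tolerance in nt.
#' @return a `genotype_call`: list with `sample_id`, `s_genotype` (ordered
#'   pair), `mgst_genotype` (character multiset), `sc_interpretation`
#'   (`self_compatible`, `self_incompatible`, `partial_sc_associated`,
#'   `undetermined`), `allele_calls`, `dosage` (a `dosage_decision` or
#'   `NULL`), `qc` (filled by [qc_checks()]).
#' @export
assemble_genotype <- function(allele_calls, run, panel, mgst_dosage = FALSE,
                              z_cut = 3,
                              tolerance = panel$bin_tolerance_default) {
  sc_alleles <- c("S3p", "S4p", "S5p")
  s_calls <- .s_allele_calls(allele_calls, panel)
  s_found <- unique(s_calls$allele)
  dosage <- NULL
  qc_extra <- list()
  h <- .fragment_heights(run, panel, tolerance)
  has_ctrl <- panel$control_fragment$id %in% names(h)

  if (length(s_found) == 2L) {
    geno <- order_alleles(s_found)
  } else if (length(s_found) == 1L) {
    if (has_ctrl) {
      scenario <- if (s_found %in% c("S3", "S3p", "S4p", "S5p")) {
        names(which(vapply(panel$calibrations, function(cal)
          identical(cal$trigger, s_found), logical(1))))[1L]
      } else {
        paste0(s_found, "_only")
      }
      dosage <- classify_single_allele_case(run, scenario, panel = panel,
                                            z_cut = z_cut,
                                            tolerance = tolerance)
      geno <- dosage$resolved_genotype
    } else {
      geno <- order_alleles(c(s_found, "S?"))
    }
    if ("S?" %in% geno) {
      qc_extra$one <- "single S-allele detected; second allele unresolved"
    }
  } else if (length(s_found) == 0L) {
    geno <- c("S?", "S?")
    qc_extra$one <- "no S-allele detected"
  } else {
    geno <- order_alleles(s_found)
    qc_extra$many <- sprintf("%d S-alleles detected: %s", length(s_found),
                             paste(display_allele(geno), collapse = ", "))
  }

  mgst_bins <- intersect(c("G132", "G140", "G192"), names(h))
  mgst_map <- c(G132 = "MGSTdel", G140 = "MGSTwt", G192 = "MGSTins")
  mgst <- unname(mgst_map[mgst_bins])
  mgst_zygosity <- "determined"
  if (length(mgst) == 1L) {
    if (mgst_dosage && has_ctrl) {
      e_f <- .efficiency_of(panel, mgst_bins)
      v <- h[[mgst_bins]] / h[[panel$control_fragment$id]]
      z2 <- abs(v - e_f) / (.model_sd_frac * e_f)          # two copies
      z1 <- abs(v - e_f / 2) / (.model_sd_frac * e_f / 2)  # one copy
      if (min(z1, z2) > z_cut) {
        mgst_zygosity <- "undetermined"
      } else if (z2 <= z1) {
        mgst <- rep(mgst, 2L)
      } else {
        mgst_zygosity <- "hemizygous-like (one copy): second MGST allele not detected"
      }
    } else {
      mgst_zygosity <- "undetermined"
    }
  }

  sc <- if (any(geno %in% sc_alleles)) {
    "self_compatible"
  } else if ("S?" %in% geno ||
             (!is.null(dosage) && dosage$decision == "indeterminate")) {
    "undetermined"
  } else if ("MGSTins" %in% mgst) {
    "partial_sc_associated"
  } else {
    "self_incompatible"
  }

  call <- structure(list(
    sample_id = run$sample_id,
    s_genotype = geno,
    mgst_genotype = mgst,
    mgst_zygosity = mgst_zygosity,
    sc_interpretation = sc,
    allele_calls = allele_calls,
    dosage = dosage,
    qc = list()
  ), class = "genotype_call")
  attr(call, "qc_extra") <- qc_extra
  call
}

#' QC checks on a genotype call
#'
#' Emits the assay's reproducibility checks as flags: `NO_CONTROL` /
#' `CONTROL_LOW` (the PaveIF-1A internal positive control is absent or below
#' `control_floor` RFU), `ONE_S_ALLELE` / `TOO_MANY_S_ALLELES` (two S-alleles
#' are always expected), `UNASSIGNED_PEAKS` (peaks above `noise_floor` RFU
#' matching no bin), `UNCONFIRMED_ALLELE`, `PROVISIONAL_BIN` and
#' `AMBIGUOUS_BIN`.
#'
#' @param run a [sample_run()].
#' @param genotype a `genotype_call` from [assemble_genotype()].
#' @param panel a `cherry_panel`.
#' @param noise_floor RFU below which unassigned peaks are ignored (default
#'   50).
#' @param control_floor minimum acceptable control height in RFU (default
#'   100).
#' @param tolerance bin tolerance in nt.
#' @return data.frame of flags: `code`, `detail`.
#' @export
qc_checks <- function(run, genotype, panel, noise_floor = 50,
                      control_floor = 100,
                      tolerance = panel$bin_tolerance_default) {
  flags <- list()
  add <- function(code, detail) {
    flags[[length(flags) + 1L]] <<- data.frame(code = code, detail = detail,
                                               stringsAsFactors = FALSE)
  }
  b <- bin_peaks(run, panel, tolerance)
  ctrl <- panel$control_fragment$id
  ctrl_row <- b$matches[b$matches$fragment_id == ctrl, , drop = FALSE]
  if (nrow(ctrl_row) == 0L) {
    add("NO_CONTROL", "PaveIF-1A control fragment not detected; dosage normalization impossible")
  } else if (ctrl_row$height < control_floor) {
    add("CONTROL_LOW", sprintf("control height %g RFU below floor %g",
                               ctrl_row$height, control_floor))
  }
  qc_extra <- attr(genotype, "qc_extra") %||% list()
  if (!is.null(qc_extra$one)) add("ONE_S_ALLELE", qc_extra$one)
  if (!is.null(qc_extra$many)) add("TOO_MANY_S_ALLELES", qc_extra$many)
  loud <- b$unassigned[b$unassigned$height >= noise_floor, , drop = FALSE]
  amb <- loud[loud$ambiguous, , drop = FALSE]
  loud <- loud[!loud$ambiguous, , drop = FALSE]
  if (nrow(loud)) {
    add("UNASSIGNED_PEAKS", paste(sprintf("%s %.1f nt (%g RFU)", loud$channel,
                                          loud$size, loud$height),
                                  collapse = "; "))
  }
  for (i in seq_len(nrow(amb))) {
    add("AMBIGUOUS_BIN", sprintf(
      "%s peak at %.2f nt is equidistant from two bins; left unassigned",
      amb$channel[i], amb$size[i]))
  }
  ac <- genotype$allele_calls
  for (i in which(ac$status == "unconfirmed")) {
    add("UNCONFIRMED_ALLELE", sprintf("%s: %s", display_allele(ac$allele[i]),
                                      ac$note[i]))
  }
  prov_ids <- panel$fragments$id[panel$fragments$provisional]
  used_prov <- vapply(strsplit(ac$fragments, ";"), function(f)
    any(f %in% prov_ids), logical(1))
  for (i in which(used_prov)) {
    add("PROVISIONAL_BIN", sprintf(
      "%s called on a provisional bin (no published observed size)",
      display_allele(ac$allele[i])))
  }
  if (!is.null(genotype$dosage) &&
      any(grepl("^PROVISIONAL", genotype$dosage$notes))) {
    add("PROVISIONAL_BIN", "dosage used a provisional calibration")
  }
  if (length(flags)) do.call(rbind, flags) else
    data.frame(code = character(0), detail = character(0),
               stringsAsFactors = FALSE)
}

#' Call the genotype of one sample run
#'
#' Convenience pipeline: [bin_peaks()] (peaks below `noise_floor` RFU are
#' dropped first), [infer_alleles()], [assemble_genotype()], [qc_checks()].
#'
#' @inheritParams assemble_genotype
#' @inheritParams qc_checks
#' @return a `genotype_call` with `qc` filled in.
#' @export
#' @examples
#' panel <- load_default_panel()
#' run <- simulate_run(c("S1", "S4p"), c("MGSTwt", "MGSTwt"),
#'                     sim_params(cv = 0, size_sd = 0), panel, "Halka-like")
#' call_genotype(run, panel)
call_genotype <- function(run, panel, tolerance = panel$bin_tolerance_default,
                          noise_floor = 50, control_floor = 100,
                          mgst_dosage = FALSE, z_cut = 3) {
  quiet <- run
  quiet$peaks <- run$peaks[run$peaks$height >= noise_floor, , drop = FALSE]
  b <- bin_peaks(quiet, panel, tolerance)
  calls <- infer_alleles(b$matches, panel)
  geno <- assemble_genotype(calls, quiet, panel, mgst_dosage = mgst_dosage,
                            z_cut = z_cut, tolerance = tolerance)
  geno$qc <- qc_checks(run, geno, panel, noise_floor = noise_floor,
                       control_floor = control_floor, tolerance = tolerance)
  attr(geno, "qc_extra") <- NULL
  geno
}

#' Call genotypes for a list of runs
#'
#' @param runs list of [sample_run()] objects.
#' @param panel a `cherry_panel`.
#' @param ... passed to [call_genotype()].
#' @return list of `genotype_call` objects.
#' @export
call_genotypes <- function(runs, panel, ...) {
  lapply(runs, call_genotype, panel = panel, ...)
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> %s\n", x$sample_id))
  cat(sprintf("  S-genotype: %s%s\n",
              paste(display_allele(x$s_genotype), collapse = ""),
              if (!is.null(x$dosage)) sprintf(" (dosage: %s)",
                                              x$dosage$decision) else ""))
  cat(sprintf("  MGST: %s (%s)\n",
              if (length(x$mgst_genotype)) paste(x$mgst_genotype, collapse = "/")
              else "none", x$mgst_zygosity))
  cat(sprintf("  interpretation: %s\n", x$sc_interpretation))
  if (nrow(x$qc)) {
    cat("  QC:", paste(x$qc$code, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tabulate genotype calls
#'
#' One row per sample: the shape used for the TSV output of the `call`
#' command.
#'
#' @param calls list of `genotype_call` objects (a single call is accepted).
#' @return data.frame with columns `sample`, `S_allele_1`, `S_allele_2`,
#'   `MGST`, `sc_interpretation`, `flags`.
#' @export
genotype_table <- function(calls) {
  if (inherits(calls, "genotype_call")) calls <- list(calls)
  do.call(rbind, lapply(calls, function(x) {
    data.frame(
      sample = x$sample_id,
      S_allele_1 = display_allele(x$s_genotype[1]),
      S_allele_2 = display_allele(x$s_genotype[2]),
      MGST = if (length(x$mgst_genotype))
        paste(x$mgst_genotype, collapse = "/") else "",
      sc_interpretation = x$sc_interpretation,
      flags = paste(x$qc$code, collapse = ";"),
      stringsAsFactors = FALSE)
  }))
}

#' Full-evidence JSON report for genotype calls
#'
#' @param calls list of `genotype_call` objects.
#' @param path optional output path.
#' @return JSON string (invisibly when `path` is given).
#' @export
genotype_report <- function(calls, path = NULL) {
  if (inherits(calls, "genotype_call")) calls <- list(calls)
  payload <- lapply(calls, function(x) {
    out <- unclass(x)
    if (!is.null(out$dosage)) out$dosage <- unclass(out$dosage)
    out
  })
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
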