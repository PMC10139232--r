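#  Quantitative copy-number interpretation. The diploid single-copy PaveIF-1A
#  fragment calibrates the genome dose; the control-normalized height of an
#  S-fragment then indicates its copy number, which separates e.g. S3'S3'
#  (two copies of the 227 nt S-RNase fragment) from S3'Sx (one copy).

# relative sd assumed for model-derived (uncalibrated) ratio hypotheses
.model_sd_frac <- 0.15

# tallest peak height per matched fragment id for one run
.fragment_heights <- function(run, panel,
                              tolerance = panel$bin_tolerance_default) {
  b <- bin_peaks(run, panel, tolerance)
  m <- b$matches
  if (nrow(m) == 0L) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(m$height, m$fragment_id)
}

#' Peak-height ratio of two panel fragments in a run
#'
#' @param run a [sample_run()].
#' @param numerator,denominator panel fragment ids (e.g. `"Y118"`, `"B227"`).
#' @param panel a `cherry_panel`.
#' @param tolerance bin tolerance in nt.
#' @return the ratio of the two matched peak heights.
#' @export
#' @examples
#' panel <- load_default_panel()
#' run <- sample_run("x", c("Y", "B"), c(118, 227), c(1000, 855))
#' peak_ratio(run, "Y118", "B227", panel)  # 1.1696
peak_ratio <- function(run, numerator, denominator, panel,
                       tolerance = panel$bin_tolerance_default) {
  h <- .fragment_heights(run, panel, tolerance)
  for (id in c(numerator, denominator)) {
    if (!id %in% names(h)) {
      stop(sprintf("fragment %s not matched in run %s", id, run$sample_id),
           call. = FALSE)
    }
  }
  if (h[[denominator]] <= 0) {
    stop(sprintf("fragment %s has zero height in run %s", denominator,
                 run$sample_id), call. = FALSE)
  }
  unname(h[[numerator]] / h[[denominator]])
}

#' Fit per-fragment amplification response from dosage calibration tables
#'
#' Each calibration entry states the mean of a peak-height ratio in a
#' genotype group with known fragment copy numbers. Under the height model
#' `height = base * (copies * e_f)^gamma`, the log of each predicted mean is
#' linear in `gamma` and in `z_f = gamma * log(e_f)`, so all entries are fit
#' jointly by weighted least squares (weights `1/CV^2`, the delta-method
#' variance of a log mean). The control fragment's efficiency is fixed at 1.
#' `gamma < 1` captures the sub-linear copy-to-height response of a
#' saturating multiplex PCR; with `fit_exponent = FALSE` strict
#' proportionality (`gamma = 1`) is imposed.
#'
#' @param calibrations a panel's `calibrations` list (or a subset).
#' @param group which group means to fit: `"both"` (default), `"homo"` or
#'   `"het"`.
#' @param fit_exponent estimate `gamma` (default `FALSE`).
#' @param include_provisional include calibrations flagged provisional
#'   (default `FALSE`).
#' @return list with `efficiencies` (named vector, control = 1), `gamma`,
#'   and `predicted` (data.frame of fitted vs stated means).
#' @export
fit_peak_response <- function(calibrations, group = c("both", "homo", "het"),
                              fit_exponent = FALSE,
                              include_provisional = FALSE) {
  group <- match.arg(group)
  rows <- list()
  for (cal in calibrations) {
    if (isTRUE(cal$provisional) && !include_provisional) next
    e <- cal$entries
    for (i in seq_len(nrow(e))) {
      if (group %in% c("both", "homo")) {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = cal$scenario, ratio_id = e$ratio_id[i], group = "homo",
          num = e$num[i], den = e$den[i], mean = e$mean_homo[i],
          sd = e$sd_homo[i], c_num = e$c_num_homo[i], c_den = e$c_den_homo[i],
          stringsAsFactors = FALSE)
      }
      if (group %in% c("both", "het")) {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = cal$scenario, ratio_id = e$ratio_id[i], group = "het",
          num = e$num[i], den = e$den[i], mean = e$mean_het[i],
          sd = e$sd_het[i], c_num = e$c_num_het[i], c_den = e$c_den_het[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  d <- do.call(rbind, rows)
  ctrl_like <- "Y118"
  frags <- setdiff(unique(c(d$num, d$den)), ctrl_like)
  y <- log(d$mean)
  a <- log(d$c_num / d$c_den)
  X <- matrix(0, nrow(d), length(frags) + as.integer(fit_exponent),
              dimnames = list(NULL, c(frags, if (fit_exponent) ".gamma")))
  for (j in seq_along(frags)) {
    X[, j] <- (d$num == frags[j]) - (d$den == frags[j])
  }
  w <- (d$mean / d$sd)^2
  if (fit_exponent) {
    X[, ".gamma"] <- a
    fit <- stats::lm.wfit(X, y, w)
    gamma <- unname(fit$coefficients[".gamma"])
    z <- fit$coefficients[frags]
  } else {
    fit <- stats::lm.wfit(X, y - a, w)
    gamma <- 1
    z <- fit$coefficients[frags]
  }
  z[is.na(z)] <- 0
  eff <- exp(z / gamma)
  eff <- c(stats::setNames(1, ctrl_like), eff)
  pred <- exp(gamma * (a + log(vapply(seq_len(nrow(d)), function(i) {
    eff[[d$num[i]]] / eff[[d$den[i]]]
  }, numeric(1)))))
  list(efficiencies = eff, gamma = gamma,
       predicted = data.frame(d[, c("scenario", "ratio_id", "group", "mean")],
                              predicted = pred))
}

#' Relative per-fragment amplification efficiencies from the calibrations
#'
#' Strict-proportionality (`gamma = 1`) joint fit over both genotype groups
#' of every non-provisional calibration table; see [fit_peak_response()].
#' Every predicted group mean lands within 15% of the stated value.
#'
#' @param calibrations a panel's `calibrations` list.
#' @return named numeric vector of relative efficiencies, control = 1;
#'   fragments not constrained by any calibration are absent (treat as 1).
#' @export
default_efficiencies <- function(calibrations) {
  fit_peak_response(calibrations, group = "both", fit_exponent = FALSE)$efficiencies
}

.efficiency_of <- function(panel, id) {
  e <- panel$efficiencies
  if (!is.null(e) && id %in% names(e)) unname(e[[id]]) else 1
}

# calibration constructed for a single-allele case with no published table:
# control/fragment ratio expected at 1/e_f for two copies, 2/e_f for one
.generic_calibration <- function(panel, allele) {
  fr <- fragments_for_allele(panel, allele)
  fr <- fr[!is.na(fr$observed), , drop = FALSE]
  ctrl <- panel$control_fragment$id
  entries <- do.call(rbind, lapply(seq_len(nrow(fr)), function(i) {
    e_f <- .efficiency_of(panel, fr$id[i])
    m_homo <- 2 / (2 * e_f)
    m_het <- 2 / (1 * e_f)
    data.frame(ratio_id = paste0("ctrl_", tolower(fr$id[i])), num = ctrl,
               den = fr$id[i], mean_homo = m_homo,
               sd_homo = .model_sd_frac * m_homo, mean_het = m_het,
               sd_het = .model_sd_frac * m_het, p_value = NA_real_,
               informative = TRUE, c_num_homo = 2, c_den_homo = 2,
               c_num_het = 2, c_den_het = 1, stringsAsFactors = FALSE)
  }))
  list(scenario = paste0(allele, "_only"), trigger = allele,
       homo_genotype = c(allele, allele), het_genotype = c(allele, "S?"),
       provisional = any(fr$provisional), generic = TRUE, entries = entries)
}

# hypothesis table for a scenario: per-entry means/sds for each candidate
# genotype. The S3-only case carries a third, model-derived hypothesis
# (the true S3 homozygote), separated from S3S3' by the SFB-122 ratios.
.dosage_hypotheses <- function(cal, panel) {
  e <- cal$entries
  is_sc_homo <- any(cal$homo_genotype %in% c("S3p", "S4p", "S5p")) ||
    identical(cal$trigger, "S3")
  hyp <- list(
    list(name = "homo",
         decision = if (is_sc_homo) "homozygous_sc" else "homozygous_si",
         genotype = cal$homo_genotype,
         mean = e$mean_homo, sd = e$sd_homo, use = e$informative),
    list(name = "het", decision = "heterozygous",
         genotype = cal$het_genotype,
         mean = e$mean_het, sd = e$sd_het, use = e$informative)
  )
  if (identical(cal$trigger, "S3")) {
    # true S3 homozygote: control and both S3 fragments all at two copies,
    # so every ratio reduces to the efficiency quotient
    mean_alt <- vapply(seq_len(nrow(e)), function(i) {
      .efficiency_of(panel, e$num[i]) / .efficiency_of(panel, e$den[i])
    }, numeric(1))
    hyp[[3L]] <- list(name = "alt", decision = "homozygous_si",
                      genotype = c("S3", "S3"), mean = mean_alt,
                      sd = .model_sd_frac * mean_alt, use = rep(TRUE, nrow(e)))
    # ratios that separate the extra hypothesis become usable even when the
    # published two-group contrast flagged them non-informative
    sep <- abs(mean_alt - e$mean_homo) > pmax(e$sd_homo, hyp[[3L]]$sd) |
      abs(mean_alt - e$mean_het) > pmax(e$sd_het, hyp[[3L]]$sd)
    for (k in 1:2) hyp[[k]]$use <- hyp[[k]]$use | sep
    hyp[[3L]]$use <- hyp[[3L]]$use & (e$informative | sep)
  }
  hyp
}

#' Classify a single-detected-S-allele case by peak-height dosage
#'
#' When only one S-allele is detected the genotype is ambiguous: a hidden
#' second allele that escapes the universal primers (`S?`) would produce the
#' same qualitative pattern as a homozygous (or S3/S3'-masked) genotype. This
#' resolves the case quantitatively: each calibrated peak-height ratio is
#' compared to its group statistics as a z-score, z-scores are combined
#' across ratios by root mean square, and the hypothesis with the smallest
#' combined z wins; if every hypothesis is more than `z_cut` SDs away the
#' case is indeterminate.
#'
#' @param run a [sample_run()].
#' @param scenario `"S3_only"`, `"S3p_only"`, `"S4p_only"`, `"S5p_only"`, or
#'   any panel S-allele label suffixed `"_only"` (generic efficiency-model
#'   calibration).
#' @param calibration optional calibration (defaults to the panel's for the
#'   scenario, or a generic one).
#' @param panel a `cherry_panel`.
#' @param z_cut indeterminacy cutoff in combined SD units (default 3).
#' @param tolerance bin tolerance in nt.
#' @return a `dosage_decision`: list with `scenario`, `ratios` (data.frame of
#'   computed ratio values), per-hypothesis combined z (`z_homo`, `z_het`,
#'   optionally `z_alt`), `decision` (`homozygous_sc`, `homozygous_si`,
#'   `heterozygous` or `indeterminate`), `resolved_genotype` and `notes`.
#' @export
classify_single_allele_case <- function(run, scenario, calibration = NULL,
                                        panel, z_cut = 3,
                                        tolerance = panel$bin_tolerance_default) {
  if (is.null(calibration)) {
    calibration <- panel$calibrations[[scenario]]
    if (is.null(calibration)) {
      allele <- sub("_only$", "", scenario)
      calibration <- .generic_calibration(panel, allele)
    }
  }
  if (!identical(calibration$scenario, scenario)) {
    stop(sprintf("calibration is for scenario %s, not %s",
                 calibration$scenario, scenario), call. = FALSE)
  }
  h <- .fragment_heights(run, panel, tolerance)
  ctrl <- panel$control_fragment$id
  if (!ctrl %in% names(h) || h[[ctrl]] <= 0) {
    stop("control fragment absent: normalization impossible", call. = FALSE)
  }
  e <- calibration$entries
  notes <- character(0)
  value <- rep(NA_real_, nrow(e))
  mgst_ids <- c("G132", "G140", "G192")
  green <- intersect(mgst_ids, names(h))
  for (i in seq_len(nrow(e))) {
    uses_mgst <- intersect(c(e$num[i], e$den[i]), mgst_ids)
    if (length(uses_mgst) && !identical(green, uses_mgst)) {
      # MGST-normalized ratios assume a diploid single-allele MGST signal;
      # with a heterozygous MGST genotype the green peak is one copy only
      notes <- c(notes, sprintf(
        "ratio %s skipped: MGST signal is not a sole-allele diploid control",
        e$ratio_id[i]))
      next
    }
    if (e$num[i] %in% names(h) && e$den[i] %in% names(h) &&
        h[[e$den[i]]] > 0) {
      value[i] <- h[[e$num[i]]] / h[[e$den[i]]]
    } else {
      notes <- c(notes, sprintf("ratio %s skipped: fragment %s not matched",
                                e$ratio_id[i],
                                if (!e$num[i] %in% names(h)) e$num[i] else e$den[i]))
    }
  }
  hyp <- .dosage_hypotheses(calibration, panel)
  rms <- vapply(hyp, function(hh) {
    use <- hh$use & !is.na(value)
    if (!any(use)) return(NA_real_)
    sqrt(mean(((value[use] - hh$mean[use]) / hh$sd[use])^2))
  }, numeric(1))
  if (all(is.na(rms))) {
    stop("no calibrated ratio computable for scenario ", scenario,
         call. = FALSE)
  }
  best <- which.min(rms)
  if (min(rms, na.rm = TRUE) > z_cut) {
    decision <- "indeterminate"
    genotype <- c(calibration$trigger, "S?")
  } else {
    decision <- hyp[[best]]$decision
    genotype <- hyp[[best]]$genotype
  }
  if (isTRUE(calibration$provisional)) {
    notes <- c(notes, "PROVISIONAL: no published calibration for this scenario; group statistics borrowed from the analogous one-copy/two-copy contrast")
  }
  z <- stats::setNames(rms, vapply(hyp, `[[`, character(1), "name"))
  structure(list(
    scenario = scenario,
    ratios = data.frame(ratio_id = e$ratio_id, num = e$num, den = e$den,
                        value = value, stringsAsFactors = FALSE),
    z_homo = unname(z["homo"]), z_het = unname(z["het"]),
    z_alt = if ("alt" %in% names(z)) unname(z["alt"]) else NA_real_,
    decision = decision,
    resolved_genotype = order_alleles(genotype),
    notes = notes
  ), class = "dosage_decision")
}

#' @export
print.dosage_decision <- function(x, ...) {
  cat(sprintf("<dosage_decision> %s: %s -> (%s)\n", x$scenario, x$decision,
              paste(display_allele(x$resolved_genotype), collapse = ", ")))
  cat(sprintf("  z_homo = %.2f, z_het = %.2f\n", x$z_homo, x$z_het))
  print(x$ratios, row.names = FALSE)
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Two-sample comparison: F-test on variances, then t-test
#'
#' The classical two-step recipe: a two-sided F-test of equality of variances
#' decides between the pooled-variance t-test (variances not significantly
#' different at `alpha_f`) and Welch's t-test. When both groups are constant
#' the F-test is undefined and Welch is reported with a note.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param alpha_f significance level for the preliminary F-test (default
#'   0.05).
#' @return list with `f_stat`, `f_p`, `t_stat`, `df`, `t_p`, `variant`
#'   (`"pooled"` or `"welch"`) and `note`.
#' @export
#' @examples
#' f_then_t_test(c(1, 2, 3), c(1, 2, 3, 4))
f_then_t_test <- function(group_a, group_b, alpha_f = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  note <- ""
  if (va == 0 && vb == 0) {
    eq <- mean(group_a) == mean(group_b)
    return(list(f_stat = NA_real_, f_p = NA_real_,
                t_stat = if (eq) 0 else sign(mean(group_a) - mean(group_b)) * Inf,
                df = length(group_a) + length(group_b) - 2,
                t_p = if (eq) 1 else 0, variant = "welch",
                note = "both groups constant: F-test undefined, Welch fallback"))
  }
  if (va == 0 || vb == 0) {
    f <- list(statistic = c(F = if (vb == 0) Inf else 0), p.value = 0)
    note <- "one group constant: F-test degenerate, Welch used"
    variant <- "welch"
  } else {
    f <- stats::var.test(group_a, group_b)
    variant <- if (f$p.value >= alpha_f) "pooled" else "welch"
  }
  tt <- stats::t.test(group_a, group_b, var.equal = (variant == "pooled"))
  list(f_stat = unname(f$statistic), f_p = f$p.value,
       t_stat = unname(tt$statistic), df = unname(tt$parameter),
       t_p = tt$p.value, variant = variant, note = note)
}
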