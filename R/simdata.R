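#  Seeded simulator of sample peak tables under the copy-number height model
#  the dosage analysis assumes: every fragment implied by a genotype emits a
#  peak whose height is proportional to (copies * efficiency)^gamma with
#  multiplicative lognormal noise, and whose size scatters around the bin's
#  observed position.

#' Simulation parameters
#'
#' @param base_height expected height (RFU) of a single-copy, unit-efficiency
#'   fragment (default 1000).
#' @param cv coefficient of variation of the multiplicative lognormal height
#'   noise (default 0.15; 0 = deterministic heights).
#' @param size_sd SD in nt of the sizing scatter around the bin position
#'   (default 0.15; 0 = exact sizes).
#' @param dropout_p probability that a fragment fails to amplify (default 0).
#' @param double_peak_p probability of a +1 nt shadow peak next to a fragment
#'   (default 0), mimicking the double-peaked amplicons of blunt-end-deficient
#'   PCR chemistries.
#' @param double_peak_fraction height of the shadow relative to its parent
#'   (default 0.6).
#' @param efficiencies named vector of relative per-fragment amplification
#'   efficiencies (fragments not named amplify at 1). `NULL` (default) uses
#'   the panel's fitted efficiencies at simulation time.
#' @param response_exponent copy-to-height response exponent `gamma`
#'   (default 1 = strict proportionality; `< 1` emulates multiplex PCR
#'   saturation).
#' @param seed integer seed; every simulated run is fully reproducible from
#'   it.
#' @return a `sim_params` list.
#' @export
sim_params <- function(base_height = 1000, cv = 0.15, size_sd = 0.15,
                       dropout_p = 0, double_peak_p = 0,
                       double_peak_fraction = 0.6, efficiencies = NULL,
                       response_exponent = 1, seed = 1L) {
  stopifnot(base_height > 0, cv >= 0, cv < 1, size_sd >= 0,
            dropout_p >= 0, dropout_p < 1, double_peak_p >= 0,
            double_peak_p < 1, double_peak_fraction >= 0,
            response_exponent > 0)
  if (!is.null(efficiencies)) stopifnot(all(efficiencies > 0))
  structure(list(base_height = base_height, cv = cv, size_sd = size_sd,
                 dropout_p = dropout_p, double_peak_p = double_peak_p,
                 double_peak_fraction = double_peak_fraction,
                 efficiencies = efficiencies,
                 response_exponent = response_exponent,
                 seed = as.integer(seed)), class = "sim_params")
}

# fragment copy numbers implied by a genotype: union over allele copies of
# each allele's bins; the diploid control is always at 2 copies
.genotype_copies <- function(s_genotype, mgst_genotype, panel) {
  copies <- stats::setNames(numeric(0), character(0))
  bump <- function(ids, by = 1) {
    for (id in ids) {
      copies[id] <<- (if (id %in% names(copies)) copies[[id]] else 0) + by
    }
  }
  for (allele in s_genotype) {
    fr <- fragments_for_allele(panel, allele)   # errors on unknown labels
    bump(fr$id)
  }
  for (allele in mgst_genotype) {
    fr <- fragments_for_allele(panel, allele)
    bump(fr$id)
  }
  bump(panel$control_fragment$id, 2)
  copies
}

#' Simulate one sample run
#'
#' Every fragment implied by the genotype (copy number = number of allele
#' copies contributing it; control fixed at 2) emits a peak with
#' `height = base_height * (copies * e_f)^gamma * L`, `L` lognormal with unit
#' mean and coefficient of variation `cv`, and
#' `size = bin observed size + N(0, size_sd)`. Dropout and +1 nt double-peak
#' artifacts are applied after that. Fully reproducible from `params$seed`.
#'
#' @param s_genotype pair of S-allele labels (e.g. `c("S1", "S4p")`).
#' @param mgst_genotype MGST allele multiset (e.g. `c("MGSTwt", "MGSTwt")`).
#' @param params a [sim_params()].
#' @param panel a `cherry_panel`.
#' @param sample_id sample identifier.
#' @return a [sample_run()].
#' @export
#' @examples
#' panel <- load_default_panel()
#' simulate_run(c("S1", "S4p"), c("MGSTwt", "MGSTwt"),
#'              sim_params(cv = 0, size_sd = 0), panel, "Halka-like")
simulate_run <- function(s_genotype, mgst_genotype, params, panel,
                         sample_id = "sim") {
  stopifnot(inherits(params, "sim_params"))
  copies <- .genotype_copies(s_genotype, mgst_genotype, panel)
  eff <- params$efficiencies
  if (is.null(eff)) eff <- panel$efficiencies
  fr <- panel$fragments[match(names(copies), panel$fragments$id), ,
                        drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  n <- length(copies)
  e_f <- vapply(names(copies), function(id)
    if (id %in% names(eff)) unname(eff[[id]]) else 1, numeric(1))
  if (params$cv > 0) {
    s2 <- log(1 + params$cv^2)
    noise <- stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
  } else {
    noise <- rep(1, n)
  }
  height <- params$base_height * (copies * e_f)^params$response_exponent *
    noise
  size <- fr$observed + if (params$size_sd > 0)
    stats::rnorm(n, 0, params$size_sd) else 0
  keep <- if (params$dropout_p > 0)
    stats::runif(n) >= params$dropout_p else rep(TRUE, n)
  channel <- fr$channel
  if (params$double_peak_p > 0) {
    shadow <- stats::runif(n) < params$double_peak_p & keep
    channel <- c(channel[keep], channel[shadow])
    sz <- c(size[keep], size[shadow] + 1.0)
    ht <- c(height[keep], height[shadow] * params$double_peak_fraction)
  } else {
    sz <- size[keep]
    ht <- height[keep]
    channel <- channel[keep]
  }
  sample_run(sample_id, channel, sz, ht)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a cohort of runs over genotype groups
#'
#' Per-run seeds are derived deterministically from `params$seed` and the
#' group/replicate indices, so cohorts are reproducible and distinct master
#' seeds give distinct cohorts.
#'
#' @param group_spec list of groups, each a list with `s_genotype` and
#'   `mgst_genotype` (and optionally `label`).
#' @param n_per_group replicates per group (default 30, the group size of
#'   the assay's quantitative validation).
#' @param params a [sim_params()].
#' @param panel a `cherry_panel`.
#' @return list of [sample_run()]s with attribute `group` (integer vector).
#' @export
simulate_cohort <- function(group_spec, n_per_group, params, panel) {
  stopifnot(n_per_group >= 1)
  runs <- list()
  group <- integer(0)
  for (g in seq_along(group_spec)) {
    spec <- group_spec[[g]]
    label <- spec$label %||% paste(spec$s_genotype, collapse = "")
    for (i in seq_len(n_per_group)) {
      p <- params
      p$seed <- (params$seed + 7919L * (g - 1L) + i - 1L) %% .Machine$integer.max
      runs[[length(runs) + 1L]] <- simulate_run(
        spec$s_genotype, spec$mgst_genotype, p, panel,
        sample_id = sprintf("%s_%02d", label, i))
      group <- c(group, g)
    }
  }
  attr(runs, "group") <- group
  runs
}

#' Per-peak height CV calibrated to a dosage table's printed SDs
#'
#' A ratio of two independent lognormal heights with per-peak CV `c` has CV
#' about `sqrt(2) * c`, so the per-peak CV matching a table is the median
#' printed ratio CV divided by `sqrt(2)`.
#'
#' @param calibration one panel calibration (e.g.
#'   `panel$calibrations$S3p_only`).
#' @return per-peak CV.
#' @export
calibrated_cv <- function(calibration) {
  e <- calibration$entries
  cvs <- c(e$sd_homo / e$mean_homo, e$sd_het / e$mean_het)
  stats::median(cvs) / sqrt(2)
}

#' Simulate the copy-number dosage validation study for one scenario
#'
#' Reproduces the design of the assay's quantitative validation: two cohorts
#' of `n_per_group` samples — the masked genotype (e.g. S3'S3') versus the
#' heterozygote with a detectable second allele (S3S3' vs S1S3; S3'S3' vs
#' S3'S4; S4'S4' vs S3S4') — simulated with efficiencies and the
#' copy-response exponent fitted to that scenario's calibration table
#' ([fit_peak_response()] with `fit_exponent = TRUE`) and per-peak CV from
#' [calibrated_cv()].
#'
#' @param panel a `cherry_panel`.
#' @param scenario `"S3_only"`, `"S3p_only"` or `"S4p_only"`.
#' @param n_per_group samples per cohort (default 30).
#' @param seed master seed.
#' @return list with `runs` (cohort list, attribute `group`), `calibration`,
#'   `fit`, `genotypes` (list of the two group genotypes).
#' @export
simulate_dosage_study <- function(panel, scenario = c("S3_only", "S3p_only",
                                                      "S4p_only"),
                                  n_per_group = 30, seed = 1L) {
  scenario <- match.arg(scenario)
  cal <- panel$calibrations[[scenario]]
  fit <- fit_peak_response(list(cal), group = "both", fit_exponent = TRUE)
  partner <- c(S3_only = "S1", S3p_only = "S4", S4p_only = "S3")[[scenario]]
  homo <- cal$homo_genotype
  het <- c(setdiff(cal$het_genotype, "S?"), partner)
  groups <- list(
    list(s_genotype = homo, mgst_genotype = c("MGSTwt", "MGSTwt"),
         label = "homo"),
    list(s_genotype = het, mgst_genotype = c("MGSTwt", "MGSTwt"),
         label = "het")
  )
  params <- sim_params(cv = calibrated_cv(cal), size_sd = 0.05,
                       efficiencies = fit$efficiencies,
                       response_exponent = fit$gamma, seed = seed)
  runs <- simulate_cohort(groups, n_per_group, params, panel)
  list(runs = runs, calibration = cal, fit = fit,
       genotypes = list(homo = homo, het = het))
}

#' Evaluate a simulated dosage study
#'
#' Computes, per calibration ratio, the cohort group means and the two-group
#' F-then-t test, plus the per-sample classification accuracy of
#' [classify_single_allele_case()] (the masked cohort should classify
#' `homozygous_sc`, the heterozygous cohort `heterozygous`; indeterminate
#' counts as an error).
#'
#' @param study result of [simulate_dosage_study()].
#' @param panel a `cherry_panel`.
#' @return list with `ratio_stats` (data.frame: ratio_id, group means,
#'   calibration means, t-test p) and `accuracy`.
#' @export
evaluate_dosage_study <- function(study, panel) {
  cal <- study$calibration
  grp <- attr(study$runs, "group")
  e <- cal$entries
  values <- lapply(seq_len(nrow(e)), function(i) {
    vapply(study$runs, function(run)
      peak_ratio(run, e$num[i], e$den[i], panel), numeric(1))
  })
  ratio_stats <- do.call(rbind, lapply(seq_len(nrow(e)), function(i) {
    v <- values[[i]]
    tt <- f_then_t_test(v[grp == 1], v[grp == 2])
    data.frame(ratio_id = e$ratio_id[i],
               mean_homo_sim = mean(v[grp == 1]),
               mean_het_sim = mean(v[grp == 2]),
               mean_homo_cal = e$mean_homo[i], mean_het_cal = e$mean_het[i],
               p_value_sim = tt$t_p, p_value_cal = e$p_value[i],
               informative = e$informative[i], stringsAsFactors = FALSE)
  }))
  decisions <- vapply(study$runs, function(run)
    classify_single_allele_case(run, cal$scenario, panel = panel)$decision,
    character(1))
  expected <- ifelse(grp == 1, "homozygous_sc", "heterozygous")
  list(ratio_stats = ratio_stats,
       accuracy = mean(decisions == expected),
       decisions = decisions)
}
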