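test_that("bin_peaks matches peaks to nearest same-channel bin within tolerance", {
  panel <- test_panel()
  run <- make_run("b", "B", 226.8, 900, "Y", 118.05, 1000, "B", 300, 500)
  b <- bin_peaks(run, panel, tolerance = 0.45)
  expect_setequal(b$matches$fragment_id, c("B227", "Y118"))
  expect_equal(b$matches$deviation[b$matches$fragment_id == "B227"], -0.2)
  expect_equal(nrow(b$unassigned), 1L)
  expect_equal(b$unassigned$size, 300)

  # 384.4 goes to the S5' bin (384), not the S5 bin (385)
  b2 <- bin_peaks(make_run("c", "B", 384.4, 800), panel, 0.45)
  expect_equal(b2$matches$fragment_id, "B384")
  # both members of the 1-nt S5/S5' pair resolve side by side
  b3 <- bin_peaks(make_run("d", "B", 384.4, 800, "B", 385.1, 700), panel, 0.45)
  expect_setequal(b3$matches$fragment_id, c("B384", "B385"))

  expect_error(bin_peaks(run, panel, tolerance = 0.6), "tolerance")
  expect_error(bin_peaks(run, panel, tolerance = 0), "tolerance")
})

test_that("a peak midway between the S5'/S5 bins is never guessed at", {
  panel <- test_panel()
  # the tolerance precondition (< half the minimum bin separation) makes an
  # in-tolerance tie structurally impossible: the midpoint of the closest
  # pair sits exactly min_sep/2 away, outside any valid tolerance
  b <- bin_peaks(make_run("t", "B", 384.5, 900), panel, 0.5 - 1e-9)
  expect_equal(nrow(b$matches), 0L)
  expect_equal(nrow(b$unassigned), 1L)
  # asymmetric peaks still resolve to the strictly nearer bin
  b2 <- bin_peaks(make_run("t", "B", 384.52, 900), panel, 0.5 - 1e-9)
  expect_equal(b2$matches$fragment_id, "B385")
})

test_that("tallest peak in a bin wins; the rest become shoulders", {
  panel <- test_panel()
  b <- bin_peaks(make_run("s", "B", 227.0, 400, "B", 227.3, 900), panel, 0.45)
  expect_equal(nrow(b$matches), 1L)
  expect_equal(b$matches$height, 900)
  expect_equal(b$matches$shoulders, 1L)
})

test_that("bin_peaks agrees with the brute-force nearest-bin oracle", {
  panel <- test_panel()
  set.seed(42)
  n <- 400
  ch <- sample(c("B", "G", "Y", "R"), n, replace = TRUE)
  sz <- runif(n, 60, 460)
  for (i in seq_len(n)) {
    b <- bin_peaks(sample_run("o", ch[i], sz[i], 100), panel, 0.45)
    got <- if (nrow(b$matches)) b$matches$fragment_id else NA_character_
    expect_identical(got, oracle_bin(ch[i], sz[i], panel, 0.45))
  }
})

test_that("infer_alleles applies the SC discrimination rules", {
  panel <- test_panel()
  calls_of <- function(...) {
    b <- bin_peaks(make_run("x", ...), panel, 0.45)
    infer_alleles(b$matches, panel)
  }
  # both S3 fragments -> confirmed S3; 227 alone -> S3' candidate
  c1 <- calls_of("B", 122, 800, "B", 227, 900)
  expect_equal(c1$status[c1$allele == "S3"], "confirmed")
  c2 <- calls_of("B", 227, 900)
  expect_equal(c2$allele, "S3p")
  expect_equal(c2$status, "candidate")
  # S4' = 177 + 443; all three SFB variants -> S4 and S4'
  c3 <- calls_of("B", 177, 700, "B", 443, 900)
  expect_equal(c3$status[c3$allele == "S4p"], "confirmed")
  c4 <- calls_of("B", 177, 700, "B", 181, 650, "B", 443, 900)
  expect_setequal(c4$allele, c("S4", "S4p"))
  # S5' from 384 alone; S5 needs the 83 nt SFB corroboration
  c5 <- calls_of("B", 384, 800)
  expect_equal(c5$allele, "S5p")
  c6 <- calls_of("B", 385, 800)
  expect_equal(c6$status[c6$allele == "S5"], "unconfirmed")
  # S1 universal without its red confirmation is unconfirmed
  c7 <- calls_of("B", 373, 800)
  expect_equal(c7$status[c7$allele == "S1"], "unconfirmed")
  c8 <- calls_of("B", 373, 800, "R", 240, 700)
  expect_equal(c8$status[c8$allele == "S1"], "confirmed")
})

test_that("S6/S24/S22 disambiguation follows the blue and red fragments", {
  panel <- test_panel()
  calls_of <- function(...) {
    b <- bin_peaks(make_run("x", ...), panel, 0.45)
    infer_alleles(b$matches, panel)
  }
  expect_equal(calls_of("B", 435, 700, "R", 223, 600)$allele, "S6")
  c2 <- calls_of("B", 416, 700, "R", 223, 600)
  expect_equal(c2$allele, "S24")
  expect_equal(c2$status, "confirmed")
  expect_equal(calls_of("B", 415, 700, "R", 258, 600)$allele, "S22")
  # S22-bin blue peak with the S6/S24 red pattern favours S24
  c4 <- calls_of("B", 415, 700, "R", 223, 600)
  expect_equal(c4$allele, "S24")
  expect_equal(c4$status, "candidate")
})

test_that("the worked Halka-like example calls S1S4' MGSTwt self-compatible", {
  panel <- test_panel()
  run <- make_run("Halka", "B", 373, 900, "R", 240, 850, "B", 177, 800,
                  "B", 443, 880, "G", 140, 950, "Y", 118, 1000)
  x <- call_genotype(run, panel)
  expect_equal(x$s_genotype, c("S1", "S4p"))
  expect_equal(unique(x$mgst_genotype), "MGSTwt")
  expect_equal(x$sc_interpretation, "self_compatible")
  expect_equal(nrow(x$qc), 0L)
})

test_that("missing control disables dosage and flags NO_CONTROL", {
  panel <- test_panel()
  run <- make_run("noctrl", "B", 227, 900, "G", 140, 950)
  x <- call_genotype(run, panel)
  expect_true("NO_CONTROL" %in% x$qc$code)
  expect_null(x$dosage)
  expect_equal(x$s_genotype, c("S3p", "S?"))
  expect_true("ONE_S_ALLELE" %in% x$qc$code)
})

test_that("qc_checks emits the documented flags", {
  panel <- test_panel()
  # low control
  run <- simulate_run(c("S1", "S2"), c("MGSTwt", "MGSTwt"),
                      sim_params(cv = 0, size_sd = 0, base_height = 30),
                      panel, "low")
  x <- call_genotype(run, panel, noise_floor = 0, control_floor = 100)
  expect_true("CONTROL_LOW" %in% x$qc$code)
  # stray loud peak
  run2 <- make_run("stray", "Y", 118, 1000, "B", 373, 900, "R", 240, 900,
                   "B", 337, 900, "R", 302, 900, "B", 300, 500)
  x2 <- call_genotype(run2, panel)
  expect_true("UNASSIGNED_PEAKS" %in% x2$qc$code)
  # stray peak below the noise floor is ignored
  run3 <- make_run("quiet", "Y", 118, 1000, "B", 373, 900, "R", 240, 900,
                   "B", 337, 900, "R", 302, 900, "B", 300, 20)
  expect_false("UNASSIGNED_PEAKS" %in% call_genotype(run3, panel)$qc$code)
  # provisional bin flag
  run4 <- make_run("prov", "Y", 118, 1000, "B", 358, 900, "B", 373, 900,
                   "R", 240, 900)
  expect_true("PROVISIONAL_BIN" %in% call_genotype(run4, panel)$qc$code)
  # three S-alleles
  run5 <- make_run("tri", "Y", 118, 1000, "B", 373, 900, "R", 240, 900,
                   "B", 337, 900, "R", 302, 900, "B", 406, 900)
  expect_true("TOO_MANY_S_ALLELES" %in% call_genotype(run5, panel)$qc$code)
})

test_that("identical runs give identical genotype calls", {
  panel <- test_panel()
  run <- simulate_run(c("S3", "S9"), c("MGSTwt", "MGSTdel"),
                      sim_params(seed = 99), panel, "det")
  x1 <- call_genotype(run, panel, mgst_dosage = TRUE)
  x2 <- call_genotype(run, panel, mgst_dosage = TRUE)
  expect_identical(x1, x2)
})

test_that("genotype_table flattens calls to one row per sample", {
  panel <- test_panel()
  runs <- list(
    simulate_run(c("S1", "S4p"), c("MGSTwt", "MGSTwt"), noiseless(), panel, "a"),
    simulate_run(c("S3", "S6"), c("MGSTwt", "MGSTins"), noiseless(), panel, "b"))
  tab <- genotype_table(call_genotypes(runs, panel))
  expect_equal(tab$sample, c("a", "b"))
  expect_equal(tab$S_allele_2[1], "S4'")
  expect_equal(tab$sc_interpretation, c("self_compatible",
                                        "partial_sc_associated"))
  js <- genotype_report(call_genotypes(runs, panel))
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_length(parsed, 2L)
  expect_equal(parsed[[1]]$sample_id, "a")
})
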