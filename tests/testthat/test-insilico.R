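# naive per-offset sliding-window oracle for binding-site search
oracle_sites <- function(pseq, tmpl, max_mm, protect) {
  expand <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  match1 <- function(p, t) {
    if (t == "N") return(p == "N")
    all(expand[[t]] %in% expand[[p]])
  }
  scan <- function(pat, protected) {
    pat <- strsplit(pat, "")[[1]]
    tm <- strsplit(toupper(tmpl), "")[[1]]
    L <- length(pat)
    out <- list()
    for (s in seq_len(length(tm) - L + 1L)) {
      mm <- !mapply(match1, pat, tm[s:(s + L - 1L)])
      if (sum(mm) <= max_mm && !any(mm[protected])) {
        out[[length(out) + 1L]] <- c(start = s - 1L, mism = sum(mm))
      }
    }
    out
  }
  L <- nchar(pseq)
  fwd <- scan(toupper(pseq), if (protect > 0) (L - protect + 1L):L else integer(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pseq)))
  rev <- scan(rc, if (protect > 0) seq_len(protect) else integer(0))
  list(forward = fwd, reverse = rev)
}

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("exact binding sites are found with zero mismatches", {
  panel <- test_panel()
  gttc <- panel$primers$sequence[panel$primers$name == "PaConsI-GTTC-F"]
  tmpl <- paste0("AAAA", gttc, "TTTT")
  s <- find_binding_sites("PaConsI-GTTC-F", tmpl, panel = panel)
  expect_equal(nrow(s), 1L)
  expect_equal(s$strand, "forward")
  expect_equal(s$start, 4L)
  expect_equal(s$end, 4L + nchar(gttc))
  expect_equal(s$mismatches, 0L)
})

test_that("the CTTC primer sees the GTTC site variant with one mismatch at position 11", {
  panel <- test_panel()
  cttc <- panel$primers$sequence[panel$primers$name == "PaConsI-CTTC-F"]
  gttc <- panel$primers$sequence[panel$primers$name == "PaConsI-GTTC-F"]
  # the two published sequences differ at exactly primer position 11
  expect_equal(which(strsplit(cttc, "")[[1]] != strsplit(gttc, "")[[1]]), 11L)
  tmpl <- paste0("CCCC", gttc, "GGGG")
  s <- find_binding_sites(list(name = "CTTC", sequence = cttc), tmpl,
                          max_mismatches = 2)
  expect_equal(nrow(s), 1L)
  expect_equal(s$mismatches, 1L)
  expect_equal(s$mismatch_positions, "11")
})

test_that("IUPAC degeneracy in the primer accepts each expanded base", {
  panel <- test_panel()
  ex3 <- panel$primers$sequence[panel$primers$name == "S-RNases-Ex3-R"]
  expect_match(ex3, "Y")
  for (base in c("C", "T")) {
    site <- sub("Y", base, ex3)
    s <- find_binding_sites(list(name = "Ex3", sequence = ex3),
                            paste0("AA", site, "AA"), max_mismatches = 0)
    expect_equal(nrow(s), 1L)
    expect_equal(s$mismatches, 0L)
  }
  # template N is never matched by a non-N primer base
  sN <- find_binding_sites(list(name = "Ex3", sequence = ex3),
                           paste0("AA", sub("Y", "N", ex3), "AA"),
                           max_mismatches = 0)
  expect_equal(nrow(sN), 0L)
})

test_that("no mismatch is tolerated inside the protected 3' window", {
  primer <- "ACGTACGTACGTAGGG"
  tmpl <- paste0("TTTT", "ACGTACGTACGTAGGC", "TTTT")  # mismatch at 3' base
  s_protected <- find_binding_sites(list(name = "p", sequence = primer), tmpl,
                                    max_mismatches = 2, protect_3prime = 3)
  expect_equal(sum(s_protected$strand == "forward"), 0L)
  s_open <- find_binding_sites(list(name = "p", sequence = primer), tmpl,
                               max_mismatches = 2, protect_3prime = 0)
  expect_equal(sum(s_open$strand == "forward"), 1L)
})

test_that("a primer embedded on the minus strand is reported as a reverse site", {
  primer <- "GCCATTGTTGCACAAATTGA"
  tmpl <- paste0("AAAAA", rc(primer), "CCCCC")
  s <- find_binding_sites(list(name = "R2", sequence = primer), tmpl,
                          max_mismatches = 0)
  expect_equal(s$strand, "reverse")
  expect_equal(s$start, 5L)
  expect_equal(s$end, 5L + nchar(primer))
})

test_that("a primer longer than the template yields an empty result", {
  s <- find_binding_sites(list(name = "p", sequence = "ACGTACGTACGTACGT"),
                          "ACGT")
  expect_equal(nrow(s), 0L)
})

test_that("reverse-complementing the template mirrors every site", {
  panel <- test_panel()
  set.seed(11)
  tmpl <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  cttc <- panel$primers$sequence[panel$primers$name == "PaConsI-CTTC-F"]
  site <- sub("^C", "G", cttc)  # one planted near-site
  tmpl <- paste0(substr(tmpl, 1, 300), site, substr(tmpl, 301, 600))
  pr <- list(name = "p", sequence = cttc)
  s_fwd <- find_binding_sites(pr, tmpl, max_mismatches = 2, protect_3prime = 3)
  s_rc <- find_binding_sites(pr, rc(tmpl), max_mismatches = 2,
                             protect_3prime = 3)
  expect_equal(nrow(s_fwd), nrow(s_rc))
  n <- nchar(tmpl)
  mirrored <- data.frame(start = n - s_rc$end, end = n - s_rc$start,
                         strand = ifelse(s_rc$strand == "forward", "reverse",
                                         "forward"),
                         mismatches = s_rc$mismatches)
  o1 <- order(s_fwd$start, s_fwd$strand)
  o2 <- order(mirrored$start, mirrored$strand)
  expect_equal(s_fwd$start[o1], mirrored$start[o2])
  expect_equal(s_fwd$strand[o1], mirrored$strand[o2])
  expect_equal(s_fwd$mismatches[o1], mirrored$mismatches[o2])
})

test_that("site search agrees with the naive sliding-window oracle", {
  set.seed(23)
  for (rep in 1:3) {
    tmpl <- paste(sample(c("A", "C", "G", "T", "N"), 800, TRUE,
                         prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                  collapse = "")
    primer <- paste(sample(c("A", "C", "G", "T", "Y", "R"), 18, TRUE,
                           prob = c(0.22, 0.22, 0.22, 0.22, 0.06, 0.06)),
                    collapse = "")
    s <- find_binding_sites(list(name = "p", sequence = primer), tmpl,
                            max_mismatches = 3, protect_3prime = 2)
    ref <- oracle_sites(primer, tmpl, 3, 2)
    expect_equal(sort(s$start[s$strand == "forward"]),
                 sort(vapply(ref$forward, `[[`, numeric(1), "start")))
    expect_equal(sort(s$start[s$strand == "reverse"]),
                 sort(vapply(ref$reverse, `[[`, numeric(1), "start")))
  }
})

test_that("predict_amplicons reconstructs the S2-length fragment on a constructed template", {
  panel <- test_panel()
  cttc <- panel$primers[panel$primers$name == "PaConsI-CTTC-F", ]
  r2 <- panel$primers[panel$primers$name == "PaConsI-R2", ]
  # span from forward primer start to reverse primer end = 343 nt (the S2
  # expected length); spacer fills the middle
  spacer_len <- 343 - nchar(cttc$sequence) - nchar(r2$sequence)
  set.seed(3)
  spacer <- paste(sample(c("A", "C", "G", "T"), spacer_len, TRUE),
                  collapse = "")
  tmpl <- paste0("TTTTT", cttc$sequence, spacer, rc(r2$sequence), "AAAAA")
  amp <- predict_amplicons(rbind(cttc, r2), tmpl, max_len = 600,
                           max_mismatches = 0, panel = panel)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 343L)
  expect_equal(amp$channel, "B")  # the reverse primer carries the 6-FAM label
  expect_equal(amp$fwd_primer, "PaConsI-CTTC-F")

  # template lacking any reverse site -> no amplicon
  amp0 <- predict_amplicons(rbind(cttc, r2),
                            paste0("TTTTT", cttc$sequence, spacer, "AAAAA"),
                            max_len = 600, max_mismatches = 0, panel = panel)
  expect_equal(nrow(amp0), 0L)

  # two forward sites sharing one reverse site -> two amplicons
  tmpl2 <- paste0(cttc$sequence, "AAAA", cttc$sequence, spacer,
                  rc(r2$sequence))
  amp2 <- predict_amplicons(rbind(cttc, r2), tmpl2, max_len = 600,
                            max_mismatches = 0, panel = panel)
  expect_equal(nrow(amp2), 2L)
})

test_that("binding_report gives a diagonal of zero mismatches on own-site templates", {
  panel <- test_panel()
  fwd <- panel$primers[grepl("^PaConsI-[ACGT]{4}-F$", panel$primers$name), ]
  expect_equal(nrow(fwd), 5L)
  templates <- setNames(paste0("AAAAA", fwd$sequence, "CCCCC"), fwd$name)
  rep <- binding_report(fwd, templates, max_mismatches = 0)
  diag_rows <- rep[rep$primer == rep$template, ]
  expect_equal(nrow(diag_rows), 5L)
  expect_false(any(diag_rows$no_site))
  expect_true(all(diag_rows$mismatches == 0L))
  # a template with no site under the threshold is flagged
  rep2 <- binding_report(fwd[1, ], c(far = strrep("AG", 40)),
                         max_mismatches = 2)
  expect_true(rep2$no_site)
})

test_that("FASTA templates round-trip through read_templates", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1", "ACGTACGTAAGGTTCC", ">t2", "GGGGCCCCAAAATTTT"), path)
  tm <- read_templates(path)
  expect_equal(names(tm), c("t1", "t2"))
  expect_equal(unname(tm["t1"]), "ACGTACGTAAGGTTCC")
})
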