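# shared fixtures: the default panel is immutable, so build it once
.panel_cache <- new.env(parent = emptyenv())

test_panel <- function() {
  if (is.null(.panel_cache$panel)) .panel_cache$panel <- load_default_panel()
  .panel_cache$panel
}

# zero-noise simulation parameters: deterministic peaks exactly on the bins
noiseless <- function(seed = 1L) sim_params(cv = 0, size_sd = 0, seed = seed)

# quick run constructor from (channel, size, height) triplets
make_run <- function(id, ...) {
  pk <- matrix(c(...), ncol = 3, byrow = TRUE)
  sample_run(id, as.character(pk[, 1]), as.numeric(pk[, 2]),
             as.numeric(pk[, 3]))
}

# every supported MGST diploid genotype
mgst_genotypes <- function() {
  list(c("MGSTwt", "MGSTwt"), c("MGSTwt", "MGSTins"), c("MGSTwt", "MGSTdel"),
       c("MGSTins", "MGSTins"), c("MGSTins", "MGSTdel"),
       c("MGSTdel", "MGSTdel"))
}

# brute-force nearest-bin assignment used as the binning oracle
oracle_bin <- function(channel, size, panel, tolerance) {
  fr <- panel$fragments[panel$fragments$channel == channel, , drop = FALSE]
  if (nrow(fr) == 0L) return(NA_character_)
  d <- abs(fr$observed - size)
  if (min(d) > tolerance) return(NA_character_)
  if (sum(d == min(d)) > 1L) return(NA_character_)  # tie: never guess
  fr$id[which.min(d)]
}
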