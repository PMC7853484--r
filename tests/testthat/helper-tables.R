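# Generators for random valid tables, used by round-trip and invariance
# property tests. All values carry at most 4 decimals so the TSV writers'
# fixed 4-dp formatting is lossless.

random_grinding_table <- function(n_series = 3) {
  beads <- c(0.5, 1.4, 2.8, 5.0)
  do.call(rbind, lapply(seq_len(n_series), function(i) {
    data.frame(
      species_code = sprintf("SP%02d", i),
      bead_size_mm = sample(beads, 1),
      replicate_id = 1L,
      time_s = c(0, 30, 60, 120, 300, 600),
      intact_count = as.integer(c(sample(50:400, 1), sample(0:300, 5))),
      stringsAsFactors = FALSE
    )
  }))
}

random_read_counts <- function(n_species = 5, markers = c("ITS1", "ITS2_plant"),
                               treatments = c("0", "33", "67", "100"),
                               n_replicates = 3, max_reads = 5000) {
  sp <- sprintf("SP%02d", seq_len(n_species))
  grid <- expand.grid(marker = markers, treatment_code = treatments,
                      replicate = seq_len(n_replicates), species_code = sp,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$replicate <- as.integer(grid$replicate)
  grid$reads <- as.integer(sample(0:max_reads, nrow(grid), replace = TRUE))
  grid[order(grid$marker, grid$treatment_code, grid$replicate,
             grid$species_code), ]
}

random_composition <- function(S) {
  x <- stats::rgamma(S, shape = stats::runif(1, 0.2, 3))
  if (sum(x) == 0) x[1] <- 1
  x / sum(x)
}

# counts table for a single marker/treatment from a named reads vector
one_replicate_counts <- function(reads, treatment = "33", replicate = 1L,
                                 marker = "ITS1") {
  data.frame(marker = marker, treatment_code = treatment,
             replicate = as.integer(replicate),
             species_code = names(reads), reads = as.integer(reads),
             stringsAsFactors = FALSE)
}
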