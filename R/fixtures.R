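# Bundled reference tables of the mock-community experiment the package
# models: species morphology, per-species optimal bead size and time to
# 95% rupture, the per-marker species-retrieval grid, and the printed
# per-replicate cumulative deviation scores.

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "exine")
  if (!nzchar(p)) stop("bundled file not found: ", file, call. = FALSE)
  p
}

#' Reference species morphology
#'
#' Morphology of the 15 study species: pollen shape, size category
#' (small 10-25, medium 26-50, large 51-100 micrometres), aperture-number
#' range (open-ended upper bounds stored as `NA`) and collection source.
#'
#' @return data.frame in the `morphology` schema.
#' @examples
#' head(reference_morphology())
#' @export
reference_morphology <- function() {
  read_exine_table(.extdata("morphology.tsv"), "morphology")
}

#' Reference rupture times and optimal bead sizes
#'
#' Per-species optimal bead-mill bead size and the projected time to 95%
#' exine rupture under that bead.
#'
#' @return data.frame in the `rupture_times` schema.
#' @examples
#' summarize_t95(reference_rupture_times()$t95_s)
#' @export
reference_rupture_times <- function() {
  read_exine_table(.extdata("rupture_times.tsv"), "rupture_times")
}

#' Reference species-retrieval grid
#'
#' Which of the 14 mock-community species each marker/primer pairing
#' retrieved above the presence threshold (at least 5 reads in at least 2
#' of 3 replicates of at least one rupture treatment).
#'
#' @return data.frame in the `presence` schema.
#' @examples
#' retrieval_count(reference_retrieval(), "ITS1")
#' @export
reference_retrieval <- function() {
  read_exine_table(.extdata("retrieval_grid.tsv"), "presence")
}

#' Reference per-replicate deviation scores
#'
#' Cumulative deviation from the equimolar expected proportion for every
#' marker x rupture treatment x replicate of the reference experiment
#' (the rbcL2/rbcLaR pairing was dropped from this evaluation because it
#' retrieved too few species).
#'
#' @return data.frame in the `deviation` schema.
#' @examples
#' d <- reference_deviation_scores()
#' treatment_summary(d$D[d$marker == "ITS1" & d$treatment_code == "0"])
#' @export
reference_deviation_scores <- function() {
  read_exine_table(.extdata("deviation_replicates.tsv"), "deviation")
}
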