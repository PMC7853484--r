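# Seeded generators emulating the experiment's statistical structure:
# Poisson counting noise on hemocytometer grain counts over an exponential
# rupture decay, and multinomial read counts whose template weights combine
# rupture-dependent accessibility, a lysis leak for unruptured grains,
# over-milling degradation beyond a species' complete-rupture time, and
# species x marker amplification bias (bias 0 encodes total dropout, the
# maize case). One RNG stream per (species/unit, treatment, replicate) is
# derived deterministically from the global seed, so adding a species does
# not perturb the draws of the others.

#' Template accessibility of a partially ruptured pollen aliquot
#'
#' The fraction of a species' DNA available to extraction when a fraction
#' `r` of its grains is ruptured and intact grains leak a fraction
#' `lambda` of their contents through the lysis incubation:
#' `a = r + (1 - r) * lambda`.
#'
#' @param r rupture fraction in `[0, 1]`.
#' @param lambda lysis leak in `[0, 1]`.
#' @return accessibility in `[0, 1]`.
#' @examples
#' accessibility(0.33, 0.1)
#' @export
accessibility <- function(r, lambda) {
  stopifnot(all(r >= 0 & r <= 1), all(lambda >= 0 & lambda <= 1))
  r + (1 - r) * lambda
}

# deterministic sub-seed below 2^31 from a label and the global seed
.sub_seed <- function(seed, label) {
  h <- utils::head(utf8ToInt(label), 50)
  s <- as.double(seed %% 2147483647)
  for (x in h) s <- (s * 31 + x) %% 2147483629
  as.integer(s)
}

#' Simulate a grinding-trial intact-count series
#'
#' Expected intact count at time t is `baseline * exp(-k t)`; observed
#' counts are independent Poisson draws (hemocytometer counting noise)
#' and the time-zero count is forced to at least 1 so normalisation is
#' defined.
#'
#' @param k true rupture rate, per second.
#' @param baseline expected grain count at time zero (over 20 fields).
#' @param time_points milling durations in seconds; the published grid
#'   (0, 30, 60, 120, 300, 600) by default.
#' @param species_code,bead_size_mm,replicate_id labels for the output.
#' @param seed optional integer; when `NULL` the current RNG state is
#'   used (so callers can manage their own streams).
#' @return data.frame in the `grinding_counts` schema.
#' @examples
#' simulate_grinding_counts(k = 0.02, baseline = 200, seed = 1)
#' @export
simulate_grinding_counts <- function(k, baseline = 200,
                                     time_points = c(0, 30, 60, 120, 300, 600),
                                     species_code = "SIM",
                                     bead_size_mm = 1.4,
                                     replicate_id = 1L,
                                     seed = NULL) {
  stopifnot(k >= 0, baseline > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu <- baseline * exp(-k * time_points)
  counts <- stats::rpois(length(time_points), mu)
  counts[1] <- max(1L, counts[1])
  data.frame(species_code = species_code, bead_size_mm = bead_size_mm,
             replicate_id = as.integer(replicate_id),
             time_s = as.numeric(time_points),
             intact_count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Specification of a simulated mock-community experiment
#'
#' Bundles the per-species and design parameters consumed by
#' [simulate_community_reads()] and [simulate_experiment()]. Defaults
#' emulate the reference experiment: 14 species (codes from the published
#' community, maize `ZM` a total dropout at every marker), four markers
#' carried through to scoring, the six-treatment grid (rupture levels 0,
#' 33, 67, 100% at 1 h lysis; 2 h and 24 h lysis at 0% rupture), three
#' replicates, and species rupture rates derived from the published times
#' to 95% rupture (`k = log(20) / t95`).
#'
#' @param species data.frame with columns `species_code`, `k`
#'   (rupture rate per second) and `delta` (degradation rate per second of
#'   over-milling); built from the bundled reference when `NULL`.
#' @param n_species used only when `species` is `NULL`: take the first
#'   `n_species` reference species (14 = full community).
#' @param markers marker codes to simulate.
#' @param bias species x marker amplification bias matrix (rows species,
#'   columns markers); non-negative, 0 = total dropout. Default: 1 for
#'   every pair except 0 for `ZM` (the maize behaviour), and log-normal
#'   spread applied at simulation time is *not* added here -- bias is a
#'   fixed property of the spec so runs are reproducible.
#' @param lysis_leak named numeric vector of per-hour leak values for 1, 2
#'   and 24 hours. The default encodes a small leak at 1-2 h and collapse
#'   of usable template after 24 h of lysis (degradation outweighing
#'   leakage), matching the observed amplification failure.
#' @param depth sequencing depth per replicate (reads over the expected
#'   species).
#' @param baseline_grains expected grains per grinding assay.
#' @param overshoot fraction of the projected complete-rupture time by
#'   which the 100% treatment over-mills (excess collision exposure).
#' @param seed integer master seed.
#' @return An object of class `simulation_spec`.
#' @examples
#' spec <- simulation_spec(seed = 7)
#' spec$depth
#' @export
simulation_spec <- function(species = NULL, n_species = 14,
                            markers = c("rbcL_aF_r506", "ITS1",
                                        "ITS2_universal", "ITS2_plant"),
                            bias = NULL,
                            lysis_leak = c(`1` = 0.05, `2` = 0.08, `24` = 0.002),
                            depth = 10000L,
                            baseline_grains = 200,
                            overshoot = 1,
                            seed = 1L) {
  if (is.null(species)) {
    ref <- reference_rupture_times()
    # CS was excluded from the mock community; ZM (the dropout) stays in
    ref <- ref[ref$species_code != "CS", ]
    ref <- ref[seq_len(min(n_species, nrow(ref))), ]
    species <- data.frame(species_code = ref$species_code,
                          k = log(20) / ref$t95_s,
                          delta = 0,
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("species_code", "k") %in% names(species)))
  if (is.null(species$delta)) species$delta <- 0
  stopifnot(all(species$k >= 0), all(species$delta >= 0))
  if (is.null(bias)) {
    bias <- matrix(1, nrow = nrow(species), ncol = length(markers),
                   dimnames = list(species$species_code, markers))
    if ("ZM" %in% species$species_code) bias["ZM", ] <- 0
  }
  stopifnot(is.matrix(bias), all(bias >= 0),
            nrow(bias) == nrow(species), ncol(bias) == length(markers))
  stopifnot(all(c("1", "2", "24") %in% names(lysis_leak)),
            all(lysis_leak >= 0 & lysis_leak <= 1))
  structure(list(species = species, markers = markers, bias = bias,
                 lysis_leak = lysis_leak, depth = as.integer(depth),
                 baseline_grains = baseline_grains,
                 overshoot = overshoot,
                 design = treatment_design(),
                 n_replicates = 3L,
                 complete_quantile = 0.999,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("simulation spec: %d species, %d markers, depth %d, seed %d\n",
              nrow(x$species), length(x$markers), x$depth, x$seed))
  invisible(x)
}

# excess milling time of species s under a rupture-level treatment:
# treatments up to 95% stop at t_r <= t_complete (no excess); the 100%
# treatment mills past the projected complete-rupture time by `overshoot`.
.excess_mill_time <- function(spec, rupture_level) {
  k <- spec$species$k
  t_complete <- ifelse(k > 0, log(1 / (1 - spec$complete_quantile)) / k, Inf)
  if (rupture_level >= 100) spec$overshoot * t_complete else 0
}

#' Simulate a species-assigned read-count table
#'
#' For each marker x treatment x replicate, the template weight of species
#' s is `w_s = a_s * g_s * b_sm` where `a_s` is the rupture/lysis
#' [accessibility()] (`r` from the treatment's estimated rupture level),
#' `g_s = exp(-delta_s * excess milling time)` penalises collisions beyond
#' the species' projected complete-rupture time (only the 100% treatment
#' over-mills), and `b_sm` is the amplification bias. Reads are a single
#' multinomial draw of size `depth` with probabilities `w / sum(w)`.
#'
#' @param spec a [simulation_spec()].
#' @param treatments treatment codes to simulate; default the full design.
#' @param allow_empty if `FALSE` (default) a replicate whose weights are
#'   all zero is an error ("degenerate replicate"); if `TRUE` it yields
#'   zero reads for every species, which downstream scoring excludes as an
#'   empty replicate.
#' @return data.frame in the `read_counts` schema, reproducible for a
#'   given spec (same seed, byte-identical table).
#' @examples
#' counts <- simulate_community_reads(simulation_spec(n_species = 4, seed = 3))
#' head(counts)
#' @export
simulate_community_reads <- function(spec,
                                     treatments = spec$design$code,
                                     allow_empty = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"))
  des <- spec$design[spec$design$code %in% treatments, , drop = FALSE]
  sp <- spec$species
  rows <- list()
  for (m in spec$markers) {
    for (ti in seq_len(nrow(des))) {
      r <- des$rupture_level[ti] / 100
      lambda <- spec$lysis_leak[[as.character(des$lysis_hours[ti])]]
      g <- exp(-sp$delta * .excess_mill_time(spec, des$rupture_level[ti]))
      w <- accessibility(r, lambda) * g * spec$bias[, m]
      for (rep_ in seq_len(spec$n_replicates)) {
        reads <- integer(nrow(sp))
        if (spec$depth > 0) {
          if (sum(w) <= 0) {
            if (!allow_empty)
              stop(sprintf("degenerate replicate: all template weights are 0 (marker %s, treatment %s)",
                           m, des$code[ti]), call. = FALSE)
          } else {
            set.seed(.sub_seed(spec$seed,
                               paste(m, des$code[ti], rep_, sep = "|")))
            reads <- as.integer(stats::rmultinom(1, spec$depth, w / sum(w)))
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          marker = m, treatment_code = des$code[ti],
          replicate = rep_, species_code = sp$species_code,
          reads = reads, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full grinding experiment
#'
#' One grinding-count series per species x bead size, with the true rate
#' modulated by bead size (the species' `k` applies at its optimal bead;
#' other beads are slower by fixed factors), on the published time grid.
#' Streams are derived per (species, bead, replicate) from the master
#' seed.
#'
#' @param spec a [simulation_spec()].
#' @param beads bead sizes (mm) to simulate.
#' @param bead_factor named numeric vector of rate multipliers per bead
#'   size; the default makes mid-size beads fastest, mirroring the
#'   observed ranking.
#' @param n_replicates grinding replicates per series.
#' @return data.frame in the `grinding_counts` schema.
#' @export
simulate_experiment_grinding <- function(spec,
                                         beads = c(0.5, 1.4, 2.8, 5.0),
                                         bead_factor = c(`0.5` = 0.25,
                                                         `1.4` = 1,
                                                         `2.8` = 0.8,
                                                         `5` = 0.5),
                                         n_replicates = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  rows <- list()
  for (i in seq_len(nrow(spec$species))) {
    for (b in beads) {
      fac <- bead_factor[[as.character(b)]] %||% 1
      for (rep_ in seq_len(n_replicates)) {
        sc <- spec$species$species_code[i]
        set.seed(.sub_seed(spec$seed, paste("grind", sc, b, rep_, sep = "|")))
        rows[[length(rows) + 1L]] <- simulate_grinding_counts(
          k = spec$species$k[i] * fac, baseline = spec$baseline_grains,
          species_code = sc, bead_size_mm = b, replicate_id = rep_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
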