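# Mock-community evaluation of species-assigned read counts: presence
# calling across replicates, retrieval counts per marker, read proportions
# over the expected species, cumulative absolute deviation from the
# equimolar expectation e = 1/S, treatment ranking and per-species trend
# classification across rupture treatments.

#' Expected read proportion for an equimolar community
#'
#' @param S number of species in the mock community (14 in the reference
#'   design).
#' @return `1 / S`.
#' @examples
#' round(expected_proportion(14), 4)
#' @export
expected_proportion <- function(S) {
  S <- as.integer(S)
  if (length(S) != 1 || is.na(S) || S < 1)
    stop("S must be a positive integer", call. = FALSE)
  1 / S
}

.validate_read_counts <- function(counts) {
  .validate_table(counts, "read_counts", "read counts")
}

#' Presence calling across replicates
#'
#' A species is called present for a marker when at least `min_replicates`
#' replicates of at least one of the considered treatments each carry at
#' least `min_reads` reads of that species. Replicate rows absent from the
#' table count as zero reads (with a warning when a considered treatment
#' is missing replicates for a species that has any reads elsewhere).
#'
#' @param counts data.frame in the `read_counts` schema.
#' @param expected_species character vector of mock-community species
#'   codes; defaults to all species present in `counts`.
#' @param cfg an [exine_config()]; supplies `min_reads`, `min_replicates`
#'   and `n_replicates`.
#' @param treatments treatment codes considered; defaults to the four
#'   rupture-level treatments (extended-lysis arms excluded).
#' @return data.frame in the `presence` schema (marker, species_code,
#'   present), one row per marker x expected species, with the parameters
#'   used stored as attributes.
#' @examples
#' counts <- data.frame(marker = "ITS1", treatment_code = "33",
#'                      replicate = 1:3, species_code = "AC",
#'                      reads = c(6L, 5L, 0L))
#' presence_call(counts, expected_species = "AC")
#' @export
presence_call <- function(counts, expected_species = NULL,
                          cfg = exine_config(),
                          treatments = rupture_treatments()) {
  counts <- .validate_read_counts(counts)
  if (is.null(expected_species))
    expected_species <- sort(unique(counts$species_code))
  markers <- sort(unique(counts$marker))
  sub <- counts[counts$treatment_code %in% treatments, , drop = FALSE]
  reps <- sort(unique(counts$replicate))
  if (!length(reps)) reps <- seq_len(cfg$n_replicates)

  out <- expand.grid(species_code = expected_species, marker = markers,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[c("marker", "species_code")]
  out$present <- 0L
  for (i in seq_len(nrow(out))) {
    rows <- sub[sub$marker == out$marker[i] &
                  sub$species_code == out$species_code[i], , drop = FALSE]
    hit <- FALSE
    for (tr in treatments) {
      r <- rows[rows$treatment_code == tr, , drop = FALSE]
      # unlisted replicates are zero reads
      n_missing <- length(reps) - nrow(r)
      if (n_missing > 0 && nrow(rows) > 0 && nrow(r) > 0)
        warning(sprintf("species %s, marker %s, treatment %s: %d replicate(s) missing, treated as 0 reads",
                        out$species_code[i], out$marker[i], tr, n_missing),
                call. = FALSE)
      if (sum(r$reads >= cfg$min_reads) >= cfg$min_replicates) {
        hit <- TRUE
        break
      }
    }
    out$present[i] <- as.integer(hit)
  }
  attr(out, "min_reads") <- cfg$min_reads
  attr(out, "min_replicates") <- cfg$min_replicates
  attr(out, "treatments") <- treatments
  rownames(out) <- NULL
  out
}

#' Number of expected species retrieved by a marker
#'
#' @param presence data.frame in the `presence` schema.
#' @param marker marker code.
#' @param expected_species optional restriction to the mock-community set.
#' @return integer count of retrieved species.
#' @export
retrieval_count <- function(presence, marker, expected_species = NULL) {
  stopifnot(all(c("marker", "species_code", "present") %in% names(presence)))
  rows <- presence[presence$marker == marker, , drop = FALSE]
  if (!is.null(expected_species))
    rows <- rows[rows$species_code %in% expected_species, , drop = FALSE]
  sum(rows$present > 0)
}

#' Read proportions over the expected species
#'
#' Proportions for one marker x treatment x replicate, computed over the
#' expected species only: off-target assignments are excluded from the
#' denominator, singleton reads are retained (no presence threshold is
#' applied at this stage) and expected species without reads get 0. A
#' replicate with no expected-species reads at all is "empty": every
#' proportion is `NA` and the `empty` attribute is set, so downstream
#' summaries can exclude it.
#'
#' @param reads named integer vector (names are species codes) or a
#'   data.frame with `species_code` and `reads` for a single replicate.
#' @param expected_species character vector of mock-community codes.
#' @return named numeric vector of proportions over `expected_species`,
#'   summing to 1 (or all `NA` with attribute `empty = TRUE`).
#' @examples
#' read_proportions(c(A = 10, B = 10, C = 20), c("A", "B", "C"))
#' @export
read_proportions <- function(reads, expected_species) {
  if (is.data.frame(reads))
    reads <- stats::setNames(reads$reads, reads$species_code)
  stopifnot(is.numeric(reads), !is.null(names(reads)))
  if (any(reads < 0)) stop("reads must be non-negative", call. = FALSE)
  full <- stats::setNames(numeric(length(expected_species)), expected_species)
  hit <- intersect(names(reads), expected_species)
  full[hit] <- reads[hit]
  total <- sum(full)
  if (total == 0) {
    out <- stats::setNames(rep(NA_real_, length(expected_species)),
                           expected_species)
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- full / total
  attr(out, "empty") <- FALSE
  out
}

#' Cumulative deviation from the expected proportion
#'
#' The score for one replicate is `D = sum_s |p_s - e|` over the expected
#' species, with absent species contributing `|0 - e|`. Because both the
#' proportions and the expectations sum to 1, the signed deviations sum to
#' exactly zero; the absolute value makes the score informative. `D`
#' ranges from 0 (perfectly equimolar) to `2 (1 - 1/S)` (all reads in one
#' species).
#'
#' @param proportions proportions over the expected species (see
#'   [read_proportions()]); an empty replicate (all `NA`) returns `NA`.
#' @param e expected proportion, `1/S` by default.
#' @return the deviation score `D`.
#' @examples
#' deviation_score(c(0.5, 0.5, 0, 0), e = 0.25)
#' @export
deviation_score <- function(proportions, e = expected_proportion(length(proportions))) {
  p <- as.numeric(proportions)
  if (anyNA(p)) return(NA_real_)
  sum(abs(p - e))
}

#' Mean and sample standard deviation of replicate deviation scores
#'
#' @param scores numeric vector of per-replicate deviation scores; `NA`
#'   entries (empty replicates) are dropped.
#' @return named vector `c(mean, sd, n_used)`; `sd` is `NA` with a warning
#'   when fewer than 2 usable scores remain, and both are `NA` when none
#'   remain.
#' @examples
#' treatment_summary(c(1.0824, 1.0136, 1.0129))
#' @export
treatment_summary <- function(scores) {
  s <- as.numeric(scores)
  s <- s[!is.na(s)]
  n <- length(s)
  if (n == 0) return(c(mean = NA_real_, sd = NA_real_, n_used = 0))
  if (n < 2) {
    warning("fewer than 2 usable replicates; SD omitted", call. = FALSE)
    return(c(mean = mean(s), sd = NA_real_, n_used = n))
  }
  c(mean = mean(s), sd = stats::sd(s), n_used = n)
}

#' Optimal treatment for a marker
#'
#' The optimal exine-rupture treatment is the one with the lowest mean
#' cumulative deviation from the expected proportions. Treatments without
#' a usable mean (all replicates empty) are excluded; exact ties go to the
#' lower rupture level (the gentler processing).
#'
#' @param means named numeric vector of mean deviation scores, names being
#'   treatment codes.
#' @return the optimal treatment code, with attribute `mean_D`.
#' @examples
#' optimal_treatment(c(`0` = 0.9572, `33` = 1.0547, `67` = 0.9622,
#'                     `100` = 1.4309))
#' @export
optimal_treatment <- function(means) {
  stopifnot(is.numeric(means), !is.null(names(means)))
  usable <- !is.na(means)
  if (!any(usable)) stop("no treatment with a usable mean", call. = FALSE)
  means <- means[usable]
  lev <- .rupture_level_of(names(means))
  ord <- order(means, lev)
  structure(names(means)[ord[1]], mean_D = unname(means[ord[1]]))
}

#' Classify the trend of one species across rupture treatments
#'
#' Given the mean signed deviation `d_t = mean over replicates of
#' (p_s - e)` for the ordered rupture treatments (0, 33, 67, 100%), the
#' species is classified, first match wins, as:
#' `ABOVE_ALL` (above expectation everywhere: `d_t > tau` for all t),
#' `BELOW_ALL` (`d_t < -tau` for all t),
#' `NEAR_ALL` (`|d_t| <= tau` for all t),
#' `CONVERGENT` (far from expectation without rupture, `|d_0| > tau`, and
#' approaching it at high rupture: `min(|d_67|, |d_100|) <= rho |d_0|`),
#' else `MIXED`.
#'
#' @param d named numeric vector of mean signed deviations with names
#'   `"0"`, `"33"`, `"67"`, `"100"`; all four required.
#' @param tau near-expectation tolerance; defaults to half the expected
#'   proportion of the 14-species community.
#' @param rho convergence ratio (default 0.5).
#' @return one of `"ABOVE_ALL"`, `"BELOW_ALL"`, `"NEAR_ALL"`,
#'   `"CONVERGENT"`, `"MIXED"`.
#' @examples
#' classify_trend(c(`0` = -0.06, `33` = -0.03, `67` = -0.01, `100` = -0.005))
#' @export
classify_trend <- function(d, tau = expected_proportion(14) / 2, rho = 0.5) {
  need <- rupture_treatments()
  if (!all(need %in% names(d)))
    stop("d must contain all rupture treatments: ",
         paste(need, collapse = ", "), call. = FALSE)
  d <- as.numeric(d[need])
  if (anyNA(d)) stop("missing deviation for a rupture treatment", call. = FALSE)
  if (all(d > tau)) return("ABOVE_ALL")
  if (all(d < -tau)) return("BELOW_ALL")
  if (all(abs(d) <= tau)) return("NEAR_ALL")
  if (abs(d[1]) > tau && min(abs(d[3]), abs(d[4])) <= rho * abs(d[1]))
    return("CONVERGENT")
  "MIXED"
}

#' Full deviation report for a read-count table
#'
#' Runs the proportion/deviation pipeline for every marker: per-replicate
#' deviation scores, per-treatment mean and sample SD, the optimal
#' treatment per marker, and per-species trend classification across the
#' rupture treatments.
#'
#' @param counts data.frame in the `read_counts` schema.
#' @param expected_species mock-community species codes; defaults to every
#'   species in `counts`.
#' @param cfg an [exine_config()].
#' @param treatments treatment codes scored; default the four rupture
#'   levels.
#' @return An object of class `deviation_report`: a list with data.frames
#'   `scores` (`deviation` schema), `summary` (`deviation_summary`
#'   schema), `trends` (`trends` schema), the named character vector
#'   `optimal` (per marker) and the expected proportion `e`.
#' @examples
#' set.seed(1)
#' spec <- simulation_spec(n_species = 4, depth = 2000)
#' rep <- deviation_report(simulate_community_reads(spec))
#' rep$optimal
#' @export
deviation_report <- function(counts, expected_species = NULL,
                             cfg = exine_config(),
                             treatments = rupture_treatments()) {
  counts <- .validate_read_counts(counts)
  if (is.null(expected_species))
    expected_species <- sort(unique(counts$species_code))
  S <- length(expected_species)
  e <- expected_proportion(S)
  tau <- cfg$near_tolerance %||% (0.5 / S)
  markers <- sort(unique(counts$marker))

  score_rows <- list()
  signed <- list()   # mean signed deviation per (marker, treatment, species)
  for (m in markers) {
    for (tr in treatments) {
      reps <- sort(unique(counts$replicate[counts$marker == m &
                                             counts$treatment_code == tr]))
      if (!length(reps)) reps <- seq_len(cfg$n_replicates)
      dmat <- matrix(NA_real_, nrow = length(reps), ncol = S,
                     dimnames = list(NULL, expected_species))
      for (j in seq_along(reps)) {
        rows <- counts[counts$marker == m & counts$treatment_code == tr &
                         counts$replicate == reps[j], , drop = FALSE]
        p <- read_proportions(rows[c("species_code", "reads")],
                              expected_species)
        D <- deviation_score(p, e)
        if (is.na(D))
          warning(sprintf("marker %s treatment %s replicate %s: no expected-species reads; replicate excluded",
                          m, tr, reps[j]), call. = FALSE)
        score_rows[[length(score_rows) + 1L]] <- data.frame(
          marker = m, treatment_code = tr, replicate = reps[j], D = D,
          stringsAsFactors = FALSE)
        if (!is.na(D)) dmat[j, ] <- p - e
      }
      signed[[paste(m, tr)]] <- colMeans(dmat, na.rm = TRUE)
    }
  }
  scores <- do.call(rbind, score_rows)

  sum_rows <- list()
  optimal <- character(0)
  for (m in markers) {
    means <- stats::setNames(rep(NA_real_, length(treatments)), treatments)
    for (tr in treatments) {
      s <- treatment_summary(scores$D[scores$marker == m &
                                        scores$treatment_code == tr])
      means[tr] <- s[["mean"]]
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        marker = m, treatment_code = tr, mean_D = s[["mean"]],
        sd_D = s[["sd"]], n_used = as.integer(s[["n_used"]]), optimal = 0L,
        stringsAsFactors = FALSE)
    }
    optimal[m] <- as.character(optimal_treatment(means))
  }
  summary_df <- do.call(rbind, sum_rows)
  summary_df$optimal <- as.integer(
    summary_df$treatment_code == optimal[summary_df$marker])

  trend_rows <- list()
  can_classify <- all(rupture_treatments() %in% treatments)
  if (can_classify) {
    for (m in markers) {
      for (sp in expected_species) {
        d <- vapply(rupture_treatments(),
                    function(tr) signed[[paste(m, tr)]][[sp]], numeric(1))
        cat_ <- if (anyNA(d) || any(is.nan(d))) "MIXED"
                else classify_trend(d, tau = tau, rho = cfg$convergence_ratio)
        trend_rows[[length(trend_rows) + 1L]] <- data.frame(
          marker = m, species_code = sp, category = cat_,
          stringsAsFactors = FALSE)
      }
    }
  }
  trends <- if (length(trend_rows)) do.call(rbind, trend_rows)
            else data.frame(marker = character(0), species_code = character(0),
                            category = character(0))

  structure(list(scores = scores, summary = summary_df, trends = trends,
                 optimal = optimal, e = e, tau = tau,
                 rho = cfg$convergence_ratio),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("Mock-community deviation report (e = %.4f, tau = %.4f, rho = %.2f)\n",
              x$e, x$tau, x$rho))
  df <- x$summary
  df$mean_D <- ifelse(is.na(df$mean_D), "-", sprintf("%.4f", df$mean_D))
  df$sd_D <- ifelse(is.na(df$sd_D), "-", sprintf("%.4f", df$sd_D))
  df$optimal <- ifelse(df$optimal == 1L, "*", "")
  print(df, row.names = FALSE)
  cat("optimal treatment per marker:\n")
  for (m in names(x$optimal)) cat(sprintf("  %-14s %s%%\n", m, x$optimal[m]))
  invisible(x)
}
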