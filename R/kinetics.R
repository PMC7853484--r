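# Exine rupture kinetics: intact-grain counts over milling time are
# normalised to fraction-intact survival curves and fitted with a
# one-parameter exponential decay, S(t) = exp(-k t), anchored at S(0) = 1.
# The fraction ruptured at time t is 1 - S(t), so the projected time to a
# rupture fraction p inverts the curve: t_p = log(1 / (1 - p)) / k.

#' Fraction of grains still intact at each milling time
#'
#' Normalises an intact-grain count series by its time-zero count. Counts
#' are totals over the 20 hemocytometer fields of one assay. Fractions
#' above 1 can arise from counting noise; they are kept (and flagged) here
#' and clipped only when fitting.
#'
#' @param trial data.frame with columns `time_s` and `intact_count`
#'   (a single species x bead-size series), or a numeric vector of counts
#'   when `time_s` is given separately.
#' @param time_s milling times in seconds; taken from `trial` when it is a
#'   data.frame.
#' @return numeric vector of fractions, with attribute `flagged_gt1` giving
#'   indices where counting noise pushed the fraction above 1.
#' @examples
#' fraction_intact(data.frame(time_s = c(0, 30, 60),
#'                            intact_count = c(200, 100, 50)))
#' @export
fraction_intact <- function(trial, time_s = NULL) {
  if (is.data.frame(trial)) {
    counts <- trial$intact_count
    time_s <- trial$time_s
  } else {
    counts <- trial
  }
  stopifnot(is.numeric(counts), is.numeric(time_s),
            length(counts) == length(time_s))
  if (is.unsorted(time_s, strictly = TRUE))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (time_s[1] != 0) stop("first time point must be 0", call. = FALSE)
  if (any(counts < 0)) stop("intact counts must be non-negative", call. = FALSE)
  if (counts[1] <= 0) stop("no grains at t=0", call. = FALSE)
  frac <- counts / counts[1]
  gt1 <- which(frac > 1)
  attr(frac, "flagged_gt1") <- gt1
  frac
}

#' Fit an exine rupture decay curve
#'
#' Fits the fraction-intact series of one species x bead-size grinding
#' trial. The default exponential model is a one-parameter decay
#' `S(t) = exp(-k t)` with the intercept fixed at 1, estimated by least
#' squares on log fractions over time points with a positive fraction
#' (zero counts have no defined log and are dropped from the regression;
#' fractions above 1 are clipped to 1 and flagged). The piecewise-linear
#' model stores the observed polyline, including zero-count points, for
#' interpolation. The residual sum of squares is reported in fraction
#' space for both models.
#'
#' @param trial data.frame with columns `time_s` and `intact_count`, or a
#'   numeric vector of fractions when `time_s` is supplied.
#' @param model `"exponential"` (default) or `"piecewise_linear"`.
#' @param time_s milling times, seconds; taken from `trial` when it is a
#'   data.frame.
#' @param complete_quantile rupture fraction operationalising "complete"
#'   rupture for reporting (default 0.999).
#' @param species_code,bead_size_mm optional labels carried into the fit.
#' @return An object of class `rupture_fit` with components `model`, `k`
#'   (per-second rate; `NA` for the piecewise model), `rss`, `time_s`,
#'   `fraction` (as fitted, i.e. clipped), `fraction_raw`, `flags`
#'   (may contain `"no_decay"` and/or `"fraction_gt1"`), and `t_p`, the
#'   projected times to 33%, 67%, 95% and complete rupture.
#' @seealso [time_to_rupture()], [select_optimal_bead()]
#' @examples
#' tr <- data.frame(time_s = c(0, 30, 60, 120, 300, 600),
#'                  intact_count = round(200 * exp(-0.01 * c(0, 30, 60, 120, 300, 600))))
#' fit <- fit_rupture(tr)
#' coef(fit)
#' time_to_rupture(fit, 0.95)
#' @export
fit_rupture <- function(trial, model = c("exponential", "piecewise_linear"),
                        time_s = NULL, complete_quantile = 0.999,
                        species_code = NA_character_,
                        bead_size_mm = NA_real_) {
  model <- match.arg(model)
  if (is.data.frame(trial)) {
    frac <- fraction_intact(trial)
    time_s <- trial$time_s
  } else {
    frac <- trial
    stopifnot(is.numeric(frac), is.numeric(time_s),
              length(frac) == length(time_s))
    if (is.unsorted(time_s, strictly = TRUE))
      stop("time_s must be strictly increasing", call. = FALSE)
  }
  stopifnot(complete_quantile > 0, complete_quantile < 1)
  flags <- character(0)
  raw <- as.numeric(frac)
  clipped <- pmin(raw, 1)
  if (any(raw > 1)) flags <- c(flags, "fraction_gt1")

  if (model == "exponential") {
    use <- clipped > 0
    if (sum(use) < 2)
      stop("insufficient data: need >= 2 time points with positive fraction",
           call. = FALSE)
    t_u <- time_s[use]
    y <- log(clipped[use])
    # least squares through the origin in (t, log f): k = -sum(t y)/sum(t^2)
    denom <- sum(t_u^2)
    k <- if (denom == 0) 0 else max(0, -sum(t_u * y) / denom)
    fitted <- exp(-k * time_s)
    rss <- sum((clipped - fitted)^2)
    if (k == 0) flags <- c(flags, "no_decay")
  } else {
    if (length(time_s) < 2)
      stop("insufficient data: need >= 2 time points", call. = FALSE)
    k <- NA_real_
    fitted <- clipped
    rss <- 0
    if (all(clipped >= 1)) flags <- c(flags, "no_decay")
  }

  fit <- structure(list(
    model = model, k = k, rss = rss,
    time_s = as.numeric(time_s), fraction = clipped, fraction_raw = raw,
    fitted = fitted, flags = flags,
    complete_quantile = complete_quantile,
    species_code = species_code, bead_size_mm = bead_size_mm
  ), class = "rupture_fit")
  fit$t_p <- c(t33 = time_to_rupture(fit, 0.33),
               t67 = time_to_rupture(fit, 0.67),
               t95 = time_to_rupture(fit, 0.95),
               t_complete = time_to_rupture(fit, complete_quantile))
  fit
}

#' Projected time to reach a rupture fraction
#'
#' Inverts a fitted rupture curve. For the exponential model,
#' `t_p = log(1 / (1 - p)) / k`. For the piecewise-linear model the
#' observed fraction-intact polyline is interpolated at `1 - p`, with
#' last-segment extrapolation when `p` exceeds the observed rupture range.
#' A target that the fitted curve never reaches (no decay, or a flat or
#' rising final segment) returns `NA` with the `"unreachable"` attribute
#' set.
#'
#' @param fit a [fit_rupture()] object.
#' @param p rupture fraction(s) in `[0, 1)`.
#' @return numeric vector of seconds; unreachable targets are `NA` and the
#'   logical attribute `unreachable` marks them.
#' @export
time_to_rupture <- function(fit, p) {
  stopifnot(inherits(fit, "rupture_fit"), is.numeric(p),
            all(p >= 0), all(p < 1))
  out <- numeric(length(p))
  unreach <- logical(length(p))
  if (fit$model == "exponential") {
    for (i in seq_along(p)) {
      if (p[i] == 0) out[i] <- 0
      else if (fit$k <= 0) { out[i] <- NA_real_; unreach[i] <- TRUE }
      else out[i] <- log(1 / (1 - p[i])) / fit$k
    }
  } else {
    tt <- fit$time_s
    ff <- fit$fraction
    for (i in seq_along(p)) {
      target <- 1 - p[i]
      if (p[i] == 0) { out[i] <- 0; next }
      hit <- which(ff <= target)
      if (length(hit)) {
        j <- hit[1]
        if (j == 1) { out[i] <- 0; next }
        # first crossing of the target within segment (j-1, j)
        f0 <- ff[j - 1]; f1 <- ff[j]
        out[i] <- tt[j - 1] + (f0 - target) / (f0 - f1) * (tt[j] - tt[j - 1])
      } else {
        n <- length(tt)
        slope <- (ff[n] - ff[n - 1]) / (tt[n] - tt[n - 1])
        if (slope >= 0) { out[i] <- NA_real_; unreach[i] <- TRUE }
        else out[i] <- tt[n] + (ff[n] - target) / (-slope)
      }
    }
  }
  attr(out, "unreachable") <- unreach
  out
}

#' Choose the optimal bead size for a species
#'
#' The optimal bead size is the one whose fitted curve gives the shortest
#' projected time to 95% rupture. Candidates whose curves never reach 95%
#' rank last; exact ties go to the smallest bead (the gentler processing).
#'
#' @param fits either a named numeric vector of t95 values (names are bead
#'   sizes in mm) or a list of `rupture_fit` objects carrying
#'   `bead_size_mm`.
#' @return the optimal bead size (numeric, mm), with attribute `t95`.
#' @examples
#' select_optimal_bead(c(`0.5` = 700, `1.4` = 112, `2.8` = 300, `5.0` = 450))
#' @export
select_optimal_bead <- function(fits) {
  if (is.list(fits) && all(vapply(fits, inherits, logical(1), "rupture_fit"))) {
    beads <- vapply(fits, function(f) as.numeric(f$bead_size_mm), numeric(1))
    t95 <- vapply(fits, function(f) unname(f$t_p[["t95"]]), numeric(1))
  } else if (is.numeric(fits) && !is.null(names(fits))) {
    beads <- as.numeric(names(fits))
    t95 <- as.numeric(fits)
  } else {
    stop("fits must be a named t95 vector or a list of rupture_fit objects",
         call. = FALSE)
  }
  if (!length(beads)) stop("no candidate fits", call. = FALSE)
  if (all(is.na(t95))) stop("no effective bead size", call. = FALSE)
  key <- ifelse(is.na(t95), Inf, t95)
  ord <- order(key, beads)   # ties: smallest bead wins
  best <- ord[1]
  structure(beads[best], t95 = t95[best])
}

#' Summary statistics for a set of t95 values
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and
#' range (max - min) of projected times to 95% rupture across species.
#'
#' @param t95_values numeric vector of at least 2 values (seconds).
#' @return named numeric vector `c(mean, sd, range)`.
#' @examples
#' summarize_t95(c(100, 100, 100))
#' @export
summarize_t95 <- function(t95_values) {
  t95_values <- as.numeric(t95_values)
  if (length(t95_values) < 2)
    stop("need at least 2 t95 values", call. = FALSE)
  if (anyNA(t95_values)) stop("t95 values must not be NA", call. = FALSE)
  c(mean = mean(t95_values), sd = stats::sd(t95_values),
    range = max(t95_values) - min(t95_values))
}

#' Fit rupture curves for a whole grinding-count table
#'
#' Fits every (species, bead size) series of a `grinding_counts` table,
#' pooling replicates by summing intact counts per time point, and
#' tabulates rates and projected rupture times.
#'
#' @param counts data.frame in the `grinding_counts` schema.
#' @param model passed to [fit_rupture()].
#' @param complete_quantile passed to [fit_rupture()].
#' @return data.frame in the `kinetics` schema, plus a `fits` attribute
#'   holding the underlying `rupture_fit` objects.
#' @export
fit_kinetics_table <- function(counts,
                               model = c("exponential", "piecewise_linear"),
                               complete_quantile = 0.999) {
  model <- match.arg(model)
  counts <- .validate_table(counts, "grinding_counts", "fit_kinetics_table")
  pooled <- stats::aggregate(intact_count ~ species_code + bead_size_mm + time_s,
                             data = counts, FUN = sum)
  pooled <- pooled[order(pooled$species_code, pooled$bead_size_mm,
                         pooled$time_s), ]
  groups <- unique(pooled[c("species_code", "bead_size_mm")])
  fits <- vector("list", nrow(groups))
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- pooled[pooled$species_code == groups$species_code[i] &
                  pooled$bead_size_mm == groups$bead_size_mm[i], ]
    fit <- fit_rupture(data.frame(time_s = g$time_s,
                                  intact_count = g$intact_count),
                       model = model, complete_quantile = complete_quantile,
                       species_code = groups$species_code[i],
                       bead_size_mm = groups$bead_size_mm[i])
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      species_code = groups$species_code[i],
      bead_size_mm = groups$bead_size_mm[i],
      model = model,
      k = if (is.na(fit$k)) NA_real_ else fit$k,
      rss = fit$rss,
      t33 = unname(fit$t_p[["t33"]]),
      t67 = unname(fit$t_p[["t67"]]),
      t95 = unname(fit$t_p[["t95"]]),
      t_complete = unname(fit$t_p[["t_complete"]]),
      flags = paste(fit$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  # piecewise fits carry no rate; the schema stores 0 for "not applicable"
  out$k[is.na(out$k)] <- 0
  attr(out, "fits") <- fits
  out
}

# ---- S3 methods for rupture_fit ------------------------------------------

#' @export
print.rupture_fit <- function(x, ...) {
  lbl <- if (!is.na(x$species_code))
    sprintf(" [%s, %s mm]", x$species_code, format(x$bead_size_mm)) else ""
  cat(sprintf("Exine rupture fit%s\n", lbl))
  cat(sprintf("  model: %s\n", x$model))
  if (x$model == "exponential")
    cat(sprintf("  decay rate k: %.6g /s\n", x$k))
  cat(sprintf("  rss (fraction space): %.6g\n", x$rss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  tp <- x$t_p
  cat(sprintf("  t33 %.1f s | t67 %.1f s | t95 %.1f s | complete %.1f s\n",
              tp[["t33"]], tp[["t67"]], tp[["t95"]], tp[["t_complete"]]))
  invisible(x)
}

#' @export
summary.rupture_fit <- function(object, ...) {
  out <- list(fit = object,
              n = length(object$time_s),
              half_time = if (identical(object$model, "exponential") &&
                              !is.na(object$k) && object$k > 0)
                log(2) / object$k else NA_real_)
  class(out) <- "summary.rupture_fit"
  out
}

#' @export
print.summary.rupture_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  n time points: %d\n", x$n))
  if (!is.na(x$half_time))
    cat(sprintf("  half-life of intact fraction: %.1f s\n", x$half_time))
  invisible(x)
}

#' @export
coef.rupture_fit <- function(object, ...) c(k = object$k)

#' @rdname fit_rupture
#' @param object,x a `rupture_fit` object.
#' @param newdata optional numeric vector of times (seconds) at which to
#'   predict the intact fraction; defaults to the observed times.
#' @param ... unused.
#' @export
predict.rupture_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$time_s else as.numeric(newdata)
  if (object$model == "exponential") {
    exp(-object$k * tt)
  } else {
    n <- length(object$time_s)
    slope <- (object$fraction[n] - object$fraction[n - 1]) /
      (object$time_s[n] - object$time_s[n - 1])
    out <- stats::approx(object$time_s, object$fraction, xout = tt,
                         rule = 2)$y
    beyond <- tt > object$time_s[n]
    out[beyond] <- pmax(0, object$fraction[n] +
                          slope * (tt[beyond] - object$time_s[n]))
    out
  }
}

#' @export
residuals.rupture_fit <- function(object, ...) {
  object$fraction - predict(object)
}

#' @rdname fit_rupture
#' @export
plot.rupture_fit <- function(x, ...) {
  tt <- seq(0, max(x$time_s), length.out = 200)
  graphics::plot(x$time_s, x$fraction_raw, xlab = "milling time (s)",
                 ylab = "fraction intact", ylim = c(0, max(1, x$fraction_raw)),
                 ...)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' @rdname fit_rupture
#' @param nsim number of simulated count series.
#' @param seed optional integer seed.
#' @param baseline expected grain count at time zero for simulation.
#' @export
simulate.rupture_fit <- function(object, nsim = 1, seed = NULL,
                                 baseline = 200, ...) {
  if (object$model != "exponential" || is.na(object$k))
    stop("simulate() requires an exponential fit", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, simulate_grinding_counts(
    k = object$k, baseline = baseline, time_points = object$time_s
  )$intact_count)
  as.data.frame(out)
}
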