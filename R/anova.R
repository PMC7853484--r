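# Morphology statistics: does time to 95% rupture associate with pollen
# grain size category and aperture number? Main-effects two-way ANOVA with
# sequential (Type I) sums of squares in the fixed order size, apertures.

#' Numeric aperture value from a printed aperture range
#'
#' Pollen atlases print aperture numbers as single values ("3"), ranges
#' ("9-15", "5-6") or open-ended ranges ("25-70+"). All are collapsed to
#' the lower bound, which is always defined and monotone in the printed
#' ranges. An alternative categorical encoding bins the lower bound into
#' the classes 0, 1, 3, 5+ and many (>= 9).
#'
#' @param apertures character or numeric vector of printed aperture
#'   numbers; en dashes and hyphens are both accepted in ranges. A
#'   `morphology`-schema data.frame is also accepted, in which case
#'   `aperture_min` is used.
#' @param mode `"numeric"` (lower bound, default) or `"categorical"`.
#' @return numeric vector, or a factor with levels `0 < 1 < 3 < 5+ < many`
#'   in categorical mode.
#' @examples
#' encode_apertures(c("3", "9-15", "25-70+", "0"))
#' encode_apertures("9-15", mode = "categorical")
#' @export
encode_apertures <- function(apertures, mode = c("numeric", "categorical")) {
  mode <- match.arg(mode)
  if (is.data.frame(apertures)) {
    low <- as.numeric(apertures$aperture_min)
  } else {
    s <- trimws(as.character(apertures))
    s <- gsub("–", "-", s)          # en dash in printed ranges
    low <- suppressWarnings(as.numeric(sub("[-+].*$", "", s)))
    bad <- is.na(low) & !is.na(s)
    if (any(bad))
      stop("unparseable aperture value: ", s[which(bad)[1]], call. = FALSE)
  }
  if (mode == "numeric") return(low)
  cut_lv <- c("0", "1", "3", "5+", "many")
  idx <- findInterval(low, c(0, 1, 2, 5, 9))
  factor(cut_lv[idx], levels = cut_lv, ordered = TRUE)
}

#' Two-way ANOVA of rupture time on size category and aperture number
#'
#' Main-effects (no interaction) analysis of variance of a response --
#' projected time to 95% rupture per species -- on pollen size category
#' and aperture number, using sequential sums of squares with the factor
#' order (size, apertures), so unbalanced designs are decomposed in a
#' fixed, reported order. Aperture number enters as a numeric covariate
#' by default; pass a factor for a categorical analysis. A term with a
#' single observed level is dropped with a warning rather than aborting
#' the analysis.
#'
#' @param response numeric response, e.g. t95 in seconds, one per species.
#' @param size_category factor or character of size classes.
#' @param apertures numeric aperture values (see [encode_apertures()]) or a
#'   factor.
#' @return An object of class `rupture_anova`: a data.frame with one row
#'   per term (`size`, `apertures`, `residual`) and columns `df`,
#'   `sum_sq`, `mean_sq`, `f_value`, `p_value`.
#' @examples
#' set.seed(1)
#' sz <- rep(c("small", "large"), each = 4)
#' ap <- rep(c(0, 3), 4)
#' y <- 100 + 20 * ap + rnorm(8, sd = 5)
#' anova_rupture(y, sz, ap)
#' @export
anova_rupture <- function(response, size_category, apertures) {
  response <- as.numeric(response)
  n <- length(response)
  stopifnot(length(size_category) == n, length(apertures) == n)
  if (!is.numeric(apertures)) apertures <- factor(apertures)
  size_category <- factor(size_category)

  terms <- c("size", "apertures")
  keep <- c(size = nlevels(size_category) > 1,
            apertures = if (is.factor(apertures)) nlevels(apertures) > 1
                        else length(unique(apertures)) > 1)
  for (tm in terms[!keep])
    warning("factor '", tm, "' has a single level; its test is skipped",
            call. = FALSE)
  if (!any(keep)) stop("no testable factor", call. = FALSE)

  dat <- data.frame(y = response, size = size_category, apertures = apertures)
  rhs <- paste(terms[keep], collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
  if (fit$df.residual < 1)
    stop("not enough observations for the model", call. = FALSE)
  a <- stats::anova(fit)   # sequential (Type I) SS in formula order

  rn <- rownames(a)
  rn[rn == "Residuals"] <- "residual"
  out <- data.frame(term = rn, df = a$Df, sum_sq = a$`Sum Sq`,
                    mean_sq = a$`Mean Sq`, f_value = a$`F value`,
                    p_value = a$`Pr(>F)`, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("rupture_anova", "data.frame"),
            skipped = terms[!keep])
}

#' @export
print.rupture_anova <- function(x, ...) {
  cat("Two-way ANOVA (sequential SS, order: size, apertures)\n")
  df <- as.data.frame(x)
  df$sum_sq <- sprintf("%.4f", df$sum_sq)
  df$mean_sq <- sprintf("%.4f", df$mean_sq)
  df$f_value <- ifelse(is.na(df$f_value), "", sprintf("%.4f", df$f_value))
  df$p_value <- ifelse(is.na(df$p_value), "",
                       format.pval(df$p_value, digits = 4))
  print(df, row.names = FALSE)
  sk <- attr(x, "skipped")
  if (length(sk)) cat("skipped single-level term(s):",
                      paste(sk, collapse = ", "), "\n")
  invisible(x)
}
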