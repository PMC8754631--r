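# Mutation-selection-balance scaling analysis: relative centromeric A+T
# (centromere minus genome, percentage points) regressed on log genome
# size across species, with full OLS inference and clade subset testing.

speciesCols <- c("species", "clade", "genome_size_bp", "genome_at_pct",
                 "centromere_at_pct")

#' Read and validate a species table
#'
#' TSV schema: `species`, `clade`, `genome_size_bp`, `genome_at_pct`,
#' `centromere_at_pct`. A+T values are percentages (0-100); genome sizes
#' are in bp. Duplicate species names are rejected.
#'
#' @param file Input path.
#' @return A validated data.frame.
#' @export
readSpeciesTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  validateSpeciesTable(df)
}

#' @rdname readSpeciesTable
#' @param df A species data.frame to validate in place.
#' @export
validateSpeciesTable <- function(df) {
  if (!all(speciesCols %in% names(df)))
    stop("species table must have columns: ",
         paste(speciesCols, collapse = ", "))
  if (anyDuplicated(df$species))
    stop("duplicate species name(s): ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  if (any(df$genome_size_bp <= 0)) stop("genome sizes must be positive")
  atv <- c(df$genome_at_pct, df$centromere_at_pct)
  if (any(atv < 0 | atv > 100))
    stop("A+T percentages must lie in [0, 100]")
  df
}

#' Relative centromeric A+T content
#'
#' Centromeric minus genome-wide A+T, in percentage points — the dependent
#' variable of the scaling regression.
#'
#' @param df A species data.frame (see [readSpeciesTable()]).
#' @return Numeric vector, one value per species.
#' @export
relativeAT <- function(df) {
  df$centromere_at_pct - df$genome_at_pct
}

#' Fit the centromeric A+T scaling regression
#'
#' Ordinary least squares of relative centromeric A+T (percentage points)
#' on `log(genome_size_bp, logBase)`, with slope standard error, two-sided
#' t test, R-squared, adjusted R-squared and the F statistic on
#' `(1, n - 2)` degrees of freedom. Under the mutation-selection-balance
#' model the slope is negative: species with larger genomes (smaller
#' effective population sizes) show weaker centromeric A+T enrichment.
#'
#' @param df A species data.frame (see [readSpeciesTable()]).
#' @param logBase Base of the genome-size logarithm (default 10).
#' @return A [ScalingFit-class].
#' @examples
#' tab <- genSpeciesTable(n = 10, sigma = 0, seed = 1)$records
#' fitScaling(tab)
#' @export
fitScaling <- function(df, logBase = 10) {
  df <- validateSpeciesTable(df)
  n <- nrow(df)
  if (n < 3L) stop("need at least 3 species to fit the regression")
  xv <- log(df$genome_size_bp, base = logBase)
  if (stats::var(xv) == 0)
    stop("zero variance in log genome size: regression undefined")
  yv <- relativeAT(df)
  fit <- stats::lm(yv ~ xv)
  sm <- summary(fit)
  new("ScalingFit",
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      slopeSE = unname(sm$coefficients[2L, 2L]),
      tStatistic = unname(sm$coefficients[2L, 3L]),
      pValue = unname(sm$coefficients[2L, 4L]),
      rSquared = sm$r.squared,
      adjRSquared = sm$adj.r.squared,
      fStatistic = unname(sm$fstatistic[1L]),
      df = c(1L, n - 2L), n = n, logBase = as.numeric(logBase))
}

#' @rdname ScalingFit-class
#' @param x A `ScalingFit`.
#' @export
scalingCoefficients <- function(x) {
  c(slope = x@slope, intercept = x@intercept)
}

#' @rdname ScalingFit-class
#' @param object A `ScalingFit`.
#' @export
setMethod("show", "ScalingFit", function(object) {
  cat(sprintf("ScalingFit (n = %d species, log base %g):\n",
              object@n, object@logBase))
  cat(sprintf("  slope     %8.4f (SE %.4f), t = %.3f, p = %.3g\n",
              object@slope, object@slopeSE, object@tStatistic,
              object@pValue))
  cat(sprintf("  intercept %8.4f\n", object@intercept))
  cat(sprintf("  R^2 %.4f, adj. R^2 %.4f, F = %.2f on (%d, %d) df\n",
              object@rSquared, object@adjRSquared, object@fStatistic,
              object@df[1L], object@df[2L]))
})

#' JSON report for a scaling fit
#'
#' @param x A [ScalingFit-class].
#' @param file Output path.
#' @export
writeScalingJSON <- function(x, file) {
  jsonlite::write_json(
    list(slope = x@slope, intercept = x@intercept, slope_se = x@slopeSE,
         t_statistic = x@tStatistic, p_value = x@pValue,
         r_squared = x@rSquared, adjusted_r_squared = x@adjRSquared,
         f_statistic = x@fStatistic, df = x@df, n = x@n,
         log_base = x@logBase),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Scaling fit restricted to one clade
#'
#' Refits the regression on the species of a single clade and reports a
#' significance verdict at level `alpha`. A subset with fewer than 3
#' species yields an explicit `insufficient_species` outcome rather than
#' an error, matching the way small clades (e.g. a six-species green-plant
#' set) may simply fail to reject the null.
#'
#' @param df A species data.frame.
#' @param clade Clade label to keep.
#' @param alpha Significance level for the verdict (default 0.05).
#' @param logBase Passed to [fitScaling()].
#' @return A list with elements `status` (`"ok"` or
#'   `"insufficient_species"`), `clade`, `n`, `alpha`, `fit` (a
#'   [ScalingFit-class] or `NULL`) and `significant` (logical or `NA`).
#' @export
cladeSubsetFit <- function(df, clade, alpha = 0.05, logBase = 10) {
  df <- validateSpeciesTable(df)
  sub <- df[df$clade == clade, , drop = FALSE]
  if (nrow(sub) < 3L) {
    return(list(status = "insufficient_species", clade = clade,
                n = nrow(sub), alpha = alpha, fit = NULL,
                significant = NA))
  }
  fit <- fitScaling(sub, logBase = logBase)
  list(status = "ok", clade = clade, n = nrow(sub), alpha = alpha,
       fit = fit, significant = fit@pValue < alpha)
}

#' Scatter-and-line plot of the scaling relationship
#'
#' Relative centromeric A+T against genome size (x log-scaled) with the
#' fitted regression line. Requires ggplot2.
#'
#' @param df A species data.frame.
#' @param fit Optional [ScalingFit-class] (default: fit from `df`).
#' @return A ggplot object.
#' @export
plotScaling <- function(df, fit = fitScaling(df)) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotScaling")
  df <- validateSpeciesTable(df)
  df$relative_at <- relativeAT(df)
  lx <- log(df$genome_size_bp, base = fit@logBase)
  df$predicted <- fit@intercept + fit@slope * lx
  ggplot2::ggplot(df, ggplot2::aes(x = genome_size_bp)) +
    ggplot2::geom_point(ggplot2::aes(y = relative_at,
                                     colour = clade)) +
    ggplot2::geom_line(ggplot2::aes(y = predicted)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Genome size (bp)",
                  y = "Centromere A+T - genome A+T (percentage points)")
}

utils::globalVariables(c("genome_size_bp", "relative_at", "predicted",
                         "clade"))
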