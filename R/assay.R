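# Statistics of the centromere-replacement recovery assay and zero-event
# confidence bounds for missegregation and centromere repositioning.

#' Construct AssayCounts
#'
#' @param arm `"integrase"` (test) or `"empty_vector"` (control).
#' @param coloniesPooled Number of pooled colonies (~50 in the standard
#'   protocol).
#' @param viableCells Viable cell count from plating on rich medium.
#' @param fracUraMinus Fraction of recovered cells that are uracil
#'   auxotrophs.
#' @param fracSwapped Fraction of auxotrophs with a PCR-confirmed swap.
#' @return An [AssayCounts-class].
#' @export
assayCounts <- function(arm, coloniesPooled, viableCells,
                        fracUraMinus = 1, fracSwapped = 1) {
  new("AssayCounts", arm = arm, coloniesPooled = as.numeric(coloniesPooled),
      viableCells = as.numeric(viableCells),
      fracUraMinus = as.numeric(fracUraMinus),
      fracSwapped = as.numeric(fracSwapped))
}

#' Read assay count tables
#'
#' TSV with header columns `arm`, `colonies_pooled`, `viable_cells`,
#' `frac_ura_minus`, `frac_swapped`; one row per arm.
#'
#' @param file Input path.
#' @return A list of [AssayCounts-class], named by arm.
#' @export
readAssayCounts <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("arm", "colonies_pooled", "viable_cells", "frac_ura_minus",
            "frac_swapped")
  if (!all(need %in% names(df)))
    stop("assay TSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    assayCounts(df$arm[i], df$colonies_pooled[i], df$viable_cells[i],
                df$frac_ura_minus[i], df$frac_swapped[i]))
  names(out) <- df$arm
  out
}

#' Recovery efficiency of the replacement assay
#'
#' Confirmed centromere-swap recovery in the test (integrase) arm as a
#' proportion of viable cells in the empty-vector control arm:
#' `(viable * fracUraMinus * fracSwapped)_test / viable_control`. Values
#' above 1 are meaningful (cells that completed the swap can outgrow the
#' control) and are returned as computed.
#'
#' @param test [AssayCounts-class] for the integrase arm.
#' @param control [AssayCounts-class] for the empty-vector arm.
#' @return Recovery efficiency (non-negative, may exceed 1).
#' @export
recoveryEfficiency <- function(test, control) {
  stopifnot(is(test, "AssayCounts"), is(control, "AssayCounts"))
  if (control@viableCells <= 0)
    stop("control arm has no viable cells; efficiency undefined")
  (test@viableCells * test@fracUraMinus * test@fracSwapped) /
    control@viableCells
}

#' Zero-event upper confidence bound on a per-trial probability
#'
#' Observing zero events in `trials` independent trials bounds the
#' per-trial event probability: the largest `p` consistent with the data at
#' the stated confidence solves `(1 - p)^trials = 1 - confidence`, i.e.
#' `p = 1 - (1 - confidence)^(1 / trials)`. Trials may be non-integer
#' (continuous extension), as when they count informative lineage
#' divisions. With 233 trials at 99% confidence the bound is 0.0196.
#'
#' @param trials Effective trial count (> 0).
#' @param confidence Confidence level in (0, 1).
#' @return A [RateBound-class].
#' @examples
#' rateBoundValue(zeroEventUpperBound(233, 0.99))  # 0.0196 to 4 d.p.
#' @export
zeroEventUpperBound <- function(trials, confidence = 0.99) {
  if (trials <= 0) stop("trials must be positive")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)")
  new("RateBound", trials = as.numeric(trials), events = 0L,
      confidence = as.numeric(confidence),
      bound = 1 - (1 - confidence)^(1 / trials))
}

#' @rdname RateBound-class
#' @param x A `RateBound`.
#' @export
rateBoundValue <- function(x) x@bound

#' @rdname RateBound-class
#' @export
rateBoundPercent <- function(x) 100 * x@bound

#' @rdname RateBound-class
#' @param object A `RateBound`.
#' @export
setMethod("show", "RateBound", function(object) {
  cat(sprintf(
    "RateBound: 0 events in %.4g trials -> p <= %.6g (%.0f%% confidence)\n",
    object@trials, object@bound, 100 * object@confidence))
})

#' Construct a lineage model for mutation-accumulation accounting
#'
#' @param colonySize Cells per colony at each streak round (>= 2).
#' @param rounds Streak rounds per lineage (>= 1).
#' @param lines Independent lineages (>= 1).
#' @return A [LineageModel-class].
#' @export
lineageModel <- function(colonySize, rounds = 1L, lines = 1L) {
  new("LineageModel", colonySize = as.numeric(colonySize),
      rounds = as.integer(rounds), lines = as.integer(lines))
}

#' Informative divisions in a mutation-accumulation experiment
#'
#' Serial single-colony passaging propagates, per lineage and round, only
#' the founding lineage of the picked colony: `log2(colonySize)` cell
#' divisions. The effective (possibly non-integer) trial count is
#' `lines * rounds * log2(colonySize)`; 20 lines through 10 rounds at
#' colony size 5e6 give ~4450.7 divisions.
#'
#' @param model A [LineageModel-class].
#' @return Effective division count.
#' @export
lineageDivisions <- function(model) {
  stopifnot(is(model, "LineageModel"))
  model@lines * model@rounds * log2(model@colonySize)
}

#' Upper bound on the per-division centromere repositioning rate
#'
#' Zero observed repositioning events across a mutation-accumulation
#' experiment bound the per-cell-division probability of centromere
#' movement: the bound is [zeroEventUpperBound()] evaluated at
#' [lineageDivisions()] trials. Use [rateBoundPercent()] to express it in
#' percent (the conventional reporting scale; ~0.1% for 20 lines, 10
#' rounds, colony size 5e6 at 99% confidence).
#'
#' @param model A [LineageModel-class].
#' @param confidence Confidence level in (0, 1).
#' @return A [RateBound-class].
#' @export
movementRateBound <- function(model, confidence = 0.99) {
  zeroEventUpperBound(lineageDivisions(model), confidence)
}

#' JSON report for a rate bound
#'
#' @param x A [RateBound-class].
#' @param file Output path.
#' @param model Optional [LineageModel-class] echoed into the report.
#' @export
writeRateBoundJSON <- function(x, file, model = NULL) {
  rep <- list(trials = x@trials, events = x@events,
              confidence = x@confidence, bound = x@bound,
              bound_percent = 100 * x@bound)
  if (!is.null(model))
    rep$model <- list(colony_size = model@colonySize,
                      rounds = model@rounds, lines = model@lines)
  jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
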