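#' Baseline band of the un-induced Eu response
#'
#' The band plays the role of the figures' shaded baseline area: the range
#' of Eu probability expected on the control diet with no induction
#' history. Either pass explicit `bounds` (configured mode; the default
#' upper bound used elsewhere in the package is 0.5, which a ~30% Eu
#' baseline with plate-level noise stays below), or pass baseline-generation
#' fits to estimate the band as the HDI of their pooled theta draws (fitted
#' mode).
#'
#' @param bounds numeric length-2 vector `c(lower, upper)`, or `NULL`.
#' @param draws a single `mf_draws` or list of `mf_draws` for baseline
#'   generations, or `NULL`.
#' @param mass HDI mass for fitted mode.
#' @return An object of class `mf_band`: list `lower`, `upper`, `source`.
#' @export
baseline_band <- function(bounds = NULL, draws = NULL, mass = 0.95) {
  if (!is.null(bounds)) {
    bounds <- as.numeric(bounds)
    if (length(bounds) != 2L || anyNA(bounds) ||
        bounds[1] > bounds[2] || bounds[1] < 0 || bounds[2] > 1) {
      stop("bounds must be c(lower, upper) with 0 <= lower <= upper <= 1")
    }
    return(structure(list(lower = bounds[1], upper = bounds[2],
                          source = "configured"), class = "mf_band"))
  }
  if (!is.null(draws)) {
    if (inherits(draws, "mf_draws")) draws <- list(draws)
    if (length(draws) == 0L) stop("no baseline fits supplied")
    pooled <- unlist(lapply(draws, pool_theta))
    h <- hdi(pooled, mass)
    return(structure(list(lower = h[["lower"]], upper = h[["upper"]],
                          source = "fitted"), class = "mf_band"))
  }
  stop("supply either explicit bounds or baseline-generation fits")
}

#' Is a generation's response elevated above baseline?
#'
#' A generation counts as elevated exactly when the lower bound of its HDI
#' lies strictly above the baseline band's upper bound — the rule implied
#' by reporting reversal generations through HDIs that exclude the
#' baseline. A tie (HDI lower equal to the band upper) is not elevated.
#'
#' @param summary one row of [summarize_group()] output (or any data frame
#'   with an `hdi_lower` column).
#' @param band an [baseline_band()] object.
#' @return Logical vector, one entry per summary row.
#' @export
classify_generation <- function(summary, band) {
  stopifnot(inherits(band, "mf_band"), "hdi_lower" %in% names(summary))
  summary$hdi_lower > band$upper
}

#' Memory duration: consecutive elevated reversal generations from R1
#'
#' The duration is the largest m such that reversal generations R1..Rm are
#' all elevated; the first non-elevated generation terminates the count
#' (a later rebound does not extend memory).
#'
#' @param reversal_summaries [summarize_group()] rows for the reversal
#'   generations of one condition. If a `generation` column is present the
#'   rows are ordered by their parsed reversal index; otherwise they are
#'   taken as already ordered R1, R2, ...
#' @param band an [baseline_band()] object.
#' @return Non-negative integer; 0 (with a warning) for an empty input.
#' @export
memory_duration <- function(reversal_summaries, band) {
  if (is.null(reversal_summaries) || nrow(reversal_summaries) == 0L) {
    warning("no reversal generations supplied: duration 0", call. = FALSE)
    return(0L)
  }
  if ("generation" %in% names(reversal_summaries)) {
    g <- parse_generation(reversal_summaries$generation)
    if (any(g$phase != "reversal")) {
      stop("all summaries must belong to reversal generations (F<k>R<m>)")
    }
    reversal_summaries <- reversal_summaries[order(g$reversal_index), ,
                                             drop = FALSE]
  }
  flags <- classify_generation(reversal_summaries, band)
  not_elevated <- which(!flags)
  if (length(not_elevated) == 0L) return(length(flags))
  not_elevated[1L] - 1L
}

#' Memory category from duration
#'
#' No elevated reversal generation means no memory; persistence for one or
#' two generations after stimulus removal is intergenerational
#' inheritance; persistence for three or more is transgenerational
#' epigenetic inheritance (TEI).
#'
#' @param duration non-negative integer (vectorized).
#' @return Character vector: `"none"`, `"intergenerational"` or
#'   `"transgenerational"`.
#' @export
categorize_memory <- function(duration) {
  duration <- as.integer(duration)
  if (anyNA(duration) || any(duration < 0L)) {
    stop("duration must be a non-negative integer")
  }
  ifelse(duration == 0L, "none",
         ifelse(duration <= 2L, "intergenerational", "transgenerational"))
}

#' Memory calls for every condition in a summary table
#'
#' Applies the elevation rule, duration count and categorization to the
#' reversal generations of each condition in a group-summary table.
#'
#' @param summaries data frame of [summarize_group()] rows (any mix of
#'   conditions and generations; induction generations are ignored).
#' @param band an [baseline_band()] object.
#' @return Data frame with columns `condition_id`, `duration`, `category`
#'   and `flags` (per-reversal-generation elevation booleans as a
#'   `"1|0|..."` string, ordered by reversal index).
#' @export
classify_memory <- function(summaries, band) {
  stopifnot(is.data.frame(summaries),
            all(c("condition_id", "generation", "hdi_lower") %in%
                  names(summaries)))
  g <- parse_generation(summaries$generation)
  rev_rows <- summaries[g$phase == "reversal", , drop = FALSE]
  out <- lapply(split(rev_rows, rev_rows$condition_id), function(d) {
    idx <- parse_generation(d$generation)$reversal_index
    d <- d[order(idx), , drop = FALSE]
    flags <- classify_generation(d, band)
    dur <- memory_duration(d, band)
    data.frame(condition_id = d$condition_id[1L],
               duration = dur,
               category = categorize_memory(dur),
               flags = paste(as.integer(flags), collapse = "|"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
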