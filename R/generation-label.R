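#' Parse generation labels
#'
#' Experiments label generations by phase: `"F<k>"` for the k-th generation
#' on the inducing diet (induction phase) and `"F<k>R<m>"` for the m-th
#' generation after reversal to the non-inducing diet, following k inducing
#' generations (e.g. `"F5R2"` = five generations induced, then two reversed).
#'
#' @param x character vector of labels such as `"F1"`, `"F5R2"`.
#' @return A data frame with one row per label and columns `label`, `phase`
#'   (`"induction"` or `"reversal"`), `exposure_index` (k) and
#'   `reversal_index` (m; 0 for induction-phase labels).
#' @examples
#' parse_generation(c("F1", "F5R2"))
#' @export
parse_generation <- function(x) {
  if (!is.character(x) || length(x) == 0) {
    stop("`x` must be a non-empty character vector of generation labels")
  }
  m <- regmatches(x, regexec("^F([0-9]+)(?:R([0-9]+))?$", x))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("unparseable generation label(s): ",
         paste(shQuote(x[bad]), collapse = ", "),
         " (expected \"F<k>\" or \"F<k>R<m>\" with k >= 1, m >= 1)")
  }
  k <- as.integer(vapply(m, `[`, character(1), 2L))
  r <- vapply(m, `[`, character(1), 3L)
  rm_idx <- ifelse(r == "", 0L, suppressWarnings(as.integer(r)))
  if (any(k < 1L) || any(rm_idx < 1L & r != "")) {
    stop("generation indices must satisfy k >= 1 and m >= 1: ",
         paste(shQuote(x[k < 1L | (rm_idx < 1L & r != "")]), collapse = ", "))
  }
  data.frame(
    label = x,
    phase = ifelse(rm_idx == 0L, "induction", "reversal"),
    exposure_index = k,
    reversal_index = rm_idx,
    stringsAsFactors = FALSE
  )
}

#' Render generation labels
#'
#' Inverse of [parse_generation()]: `format_generation(parse_generation(x))`
#' reproduces `x`.
#'
#' @param phase character vector, `"induction"` or `"reversal"`; may also be
#'   a data frame with columns `phase`, `exposure_index`, `reversal_index`.
#' @param exposure_index integer k in `"F<k>"`.
#' @param reversal_index integer m in `"R<m>"`; must be 0 exactly when
#'   `phase` is `"induction"`.
#' @return character vector of labels.
#' @export
format_generation <- function(phase, exposure_index = NULL,
                              reversal_index = NULL) {
  if (is.data.frame(phase)) {
    exposure_index <- phase$exposure_index
    reversal_index <- phase$reversal_index
    phase <- phase$phase
  }
  phase <- match.arg(phase, c("induction", "reversal"), several.ok = TRUE)
  k <- as.integer(exposure_index)
  m <- as.integer(reversal_index)
  if (length(phase) == 1L) phase <- rep(phase, length(k))
  if (any(k < 1L)) stop("exposure_index must be >= 1")
  if (any((phase == "induction") != (m == 0L))) {
    stop("reversal_index must be 0 exactly for induction-phase labels")
  }
  ifelse(phase == "induction",
         sprintf("F%d", k),
         sprintf("F%dR%d", k, m))
}
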