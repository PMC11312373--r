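#' Neutrophil-to-lymphocyte ratio
#'
#' Computes NLR, the ratio of the absolute neutrophil count to the absolute
#' lymphocyte count (both on the 10^9 cells/L scale), a marker of the balance
#' between innate and adaptive immunity.
#'
#' @param neutrophil Numeric vector of neutrophil counts (> 0 expected).
#' @param lymphocyte Numeric vector of lymphocyte counts; must be strictly
#'   positive, otherwise the ratio is undefined and an error is raised
#'   (records with zero lymphocytes are expected to be excluded upstream).
#' @return Numeric vector of ratios.
#' @examples
#' compute_nlr(4.22, 1.96)
#' @export
compute_nlr <- function(neutrophil, lymphocyte) {
  if (length(neutrophil) != length(lymphocyte))
    stop("neutrophil and lymphocyte must have equal length")
  bad <- !is.na(lymphocyte) & lymphocyte <= 0
  if (any(bad))
    stop("lymphocyte count must be > 0 for NLR to be defined (",
         sum(bad), " offending record(s))")
  neutrophil / lymphocyte
}

#' INFLA-Score marker set
#' @keywords internal
INFLA_MARKERS <- c("crp", "wbc", "plt", "nlr")

#' Fit the empirical decile map for the INFLA-Score
#'
#' Estimates, on the analysis population, the nine empirical decile
#' cut-points (10th..90th percentiles, linear-interpolation quantiles) for
#' each of the four inflammatory markers: CRP (mg/L), white blood cell
#' count, platelet count and NLR. The map is later used to convert marker
#' values into decile points.
#'
#' Values falling exactly on a cut-point are assigned to the lower decile.
#'
#' @param data Data frame containing the marker columns.
#' @param markers Character vector of marker column names (default the four
#'   INFLA markers).
#' @param variant Decile-to-points mapping: `"halves"` maps deciles 1..5 to
#'   -4..0 and 6..10 to 0..+4 (deciles 5 and 6 both score 0);
#'   `"bonaccio"` maps deciles 1..4 to -4..-1, 5..6 to 0, and 7..10 to
#'   +1..+4, as in the original composite-index literature.
#' @param directions Named vector of +1/-1 per marker; +1 means higher
#'   values are scored as more inflammatory. Platelet count defaults to +1
#'   but is configurable because its association can be discordant.
#' @return An object of class `decile_map`: list with `cuts` (9 ascending
#'   cut-points per marker), `variant`, `directions`.
#' @export
fit_decile_map <- function(data, markers = INFLA_MARKERS,
                           variant = c("halves", "bonaccio"),
                           directions = NULL) {
  variant <- match.arg(variant)
  if (is.null(directions))
    directions <- stats::setNames(rep(1, length(markers)), markers)
  stopifnot(all(markers %in% names(directions)),
            all(directions[markers] %in% c(-1, 1)))
  cuts <- lapply(markers, function(m) {
    x <- data[[m]]
    if (is.null(x)) stop("marker column '", m, "' not found")
    x <- x[!is.na(x)]
    if (length(x) < 10)
      stop("need at least 10 non-missing values to fit deciles for '", m, "'")
    q <- stats::quantile(x, probs = 1:9 / 10, names = FALSE, type = 7)
    if (all(q == q[1]))
      warning("degenerate decile map for '", m, "': all cut-points equal")
    q
  })
  names(cuts) <- markers
  structure(list(cuts = cuts, variant = variant,
                 directions = directions[markers]),
            class = "decile_map")
}

#' @export
print.decile_map <- function(x, ...) {
  cat("Decile map (", x$variant, " variant) for ",
      paste(names(x$cuts), collapse = ", "), "\n", sep = "")
  for (m in names(x$cuts))
    cat(sprintf("  %-4s dir %+d cuts: %s\n", m, x$directions[[m]],
                paste(signif(x$cuts[[m]], 4), collapse = " ")))
  invisible(x)
}

# decile index 1..10; values exactly at a cut-point go to the lower decile
.decile_index <- function(value, cuts) {
  idx <- rep(1L, length(value))
  for (c in cuts) idx <- idx + (value > c)
  idx[is.na(value)] <- NA_integer_
  idx
}

.points_from_decile <- function(d, variant) {
  if (variant == "halves") {
    ifelse(d <= 5L, d - 5L, d - 6L)
  } else { # bonaccio: 1-4 -> -4..-1, 5-6 -> 0, 7-10 -> +1..+4
    ifelse(d <= 4L, d - 5L, ifelse(d <= 6L, 0L, d - 6L))
  }
}

#' Decile points for one marker
#'
#' Maps marker values to integer points in \[-4, +4\] according to a fitted
#' decile map. Under the default (`"halves"`) mapping the lowest five deciles
#' score -4..0 and the highest five score 0..+4. A direction of -1 for the
#' marker reverses the decile ordering before the mapping is applied.
#'
#' @param value Numeric vector of marker values.
#' @param marker Marker name (must be present in the map).
#' @param map A `decile_map` from [fit_decile_map()].
#' @return Integer vector in \[-4, 4\].
#' @export
decile_points <- function(value, marker, map) {
  if (!inherits(map, "decile_map")) stop("map must be a fitted decile_map")
  if (!marker %in% names(map$cuts)) stop("marker '", marker, "' not in map")
  d <- .decile_index(value, map$cuts[[marker]])
  if (map$directions[[marker]] < 0) d <- 11L - d
  as.integer(.points_from_decile(d, map$variant))
}

#' Compute the INFLA-Score
#'
#' The INFLA-Score aggregates equally weighted decile points for CRP, white
#' blood cell count, platelet count and NLR: each marker contributes an
#' integer in \[-4, +4\], so the total ranges from -16 to +16, with higher
#' values indicating a more pro-inflammatory state. Rows with any missing
#' marker receive `NA` (such participants are excluded from inflammation
#' analyses rather than imputed).
#'
#' @param data Data frame with the marker columns named in `map`.
#' @param map A fitted `decile_map`.
#' @return Data frame with one `infla_pts_<marker>` column per marker and
#'   the `infla_score` total.
#' @export
compute_infla_score <- function(data, map) {
  if (!inherits(map, "decile_map")) stop("map must be a fitted decile_map")
  markers <- names(map$cuts)
  pts <- lapply(markers, function(m) decile_points(data[[m]], m, map))
  names(pts) <- paste0("infla_pts_", markers)
  out <- as.data.frame(pts)
  out$infla_score <- as.integer(Reduce(`+`, pts))
  out
}

#' Quantile exposure bins
#'
#' Bins a score vector into k empirical quantile groups labelled Q1..Qk,
#' Q1 (lowest) being the reference. Cut-points are linear-interpolation
#' quantiles; values exactly at a cut-point fall in the lower bin, so with
#' heavily tied integer scores occupancy is equal only up to tie blocks.
#'
#' @param scores Numeric vector.
#' @param k Number of groups, typically 4 (quartiles) or 5 (quintiles).
#' @param labels Optional labels; default `Q1..Qk`.
#' @return Factor of length `length(scores)` with `k` levels.
#' @export
bin_exposure <- function(scores, k = 4, labels = paste0("Q", seq_len(k))) {
  stopifnot(k >= 2, length(labels) == k)
  x <- scores[!is.na(scores)]
  if (length(unique(x)) < k)
    stop("cannot form ", k, " bins: fewer than ", k, " distinct values")
  cuts <- stats::quantile(x, probs = seq_len(k - 1) / k, names = FALSE,
                          type = 7)
  idx <- rep(1L, length(scores))
  for (c in cuts) idx <- idx + (scores > c)
  idx[is.na(scores)] <- NA_integer_
  if (length(unique(stats::na.omit(idx))) < k)
    stop("cannot form ", k, " bins: ties collapse adjacent quantiles")
  factor(labels[idx], levels = labels)
}
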