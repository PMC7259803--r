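#' Greedy pruning of highly correlated variables
#'
#' Reduces a table of per-location environmental variables to a subset with
#' no pairwise Pearson correlation above \code{r_max}: zero-variance columns
#' are dropped first (with a warning), then, while any pair exceeds
#' \code{r_max} in absolute value, the member of the worst pair with the
#' higher mean absolute correlation to the remaining variables is dropped
#' (ties broken by column order).
#'
#' @param table Data frame or matrix, columns = variables, rows = locations.
#' @param r_max Maximum tolerated absolute pairwise correlation (exclusive:
#'   pairs with \eqn{|r| > r_{max}} trigger a drop).
#' @return Character vector of kept variable names.
#' @export
prune_correlated_variables <- function(table, r_max = 0.85) {
  x <- as.matrix(table)
  if (ncol(x) < 2L) stop("need at least 2 variables")
  if (nrow(x) < 3L) stop("need at least 3 locations")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variables: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  keep <- colnames(x)
  repeat {
    if (length(keep) < 2L) break
    cm <- abs(stats::cor(x[, keep, drop = FALSE]))
    diag(cm) <- 0
    worst <- max(cm)
    if (worst <= r_max) break
    idx <- which(cm == worst, arr.ind = TRUE)[1L, ]
    cand <- keep[sort(idx)]
    mac <- vapply(cand, function(v)
      mean(cm[v, setdiff(keep, v)]), 0)
    drop <- cand[which.max(mac)]        # which.max: first max = earlier column
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Suitable area of a presence-probability raster
#'
#' Counts the non-nodata cells with presence probability at or above the
#' threshold (inclusive). When a per-cell area grid is supplied the areas of
#' those cells are summed instead.
#'
#' @param r A \code{\link{suit_raster}}.
#' @param threshold Probability cutoff (inclusive at \code{>=}).
#' @param cell_area Optional matrix of per-cell areas (e.g. km^2) matching
#'   the raster grid.
#' @return Suitable cell count (or total area).
#' @export
suitable_area <- function(r, threshold = 0.8, cell_area = NULL) {
  stopifnot(inherits(r, "suit_raster"))
  v <- r$values
  if (all(is.na(v))) stop("all-nodata raster")
  hit <- !is.na(v) & v >= threshold
  if (is.null(cell_area)) sum(hit) else sum(cell_area[hit])
}

#' Relative change of suitable area between two time slices
#'
#' \code{(current - past) / current}: positive values mean the suitable area
#' has grown since the past period (range expansion toward the present),
#' negative values mean the past area was larger. Undefined (NA, flagged)
#' when the current area is zero.
#'
#' @param current,past Either suitable areas (numbers) or
#'   \code{\link{suit_raster}}s, in which case \code{\link{suitable_area}} is
#'   applied with \code{threshold}.
#' @param species Label carried into the result.
#' @param threshold Probability cutoff used when rasters are supplied.
#' @return One-row data frame: \code{species}, \code{area_current},
#'   \code{area_past}, \code{rel_change} (NA when undefined),
#'   \code{defined}.
#' @export
relative_area_change <- function(current, past, species = NA_character_,
                                 threshold = 0.8) {
  if (inherits(current, "suit_raster"))
    current <- suitable_area(current, threshold)
  if (inherits(past, "suit_raster"))
    past <- suitable_area(past, threshold)
  defined <- current > 0
  data.frame(species = species, area_current = current, area_past = past,
             rel_change = if (defined) (current - past) / current
             else NA_real_,
             defined = defined, stringsAsFactors = FALSE)
}

#' Correlate range change with demography (Tajima's D)
#'
#' Pearson correlation between per-species relative suitable-area change and
#' per-species median Tajima's D, with the usual two-sided t-test on
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.
#'
#' @param changes Data frame of \code{\link{relative_area_change}} rows.
#' @param tajd Data frame with columns \code{species} and \code{median_d}.
#' @param group Optional character vector of species to restrict to (e.g.
#'   the diploids).
#' @return List of class \code{demography_correlation}: \code{n},
#'   \code{pearson_r}, \code{r_squared}, \code{p_value}, \code{species}.
#' @export
correlate_demography <- function(changes, tajd, group = NULL) {
  m <- merge(changes[changes$defined, c("species", "rel_change")],
             tajd[, c("species", "median_d")], by = "species")
  if (!is.null(group)) m <- m[m$species %in% group, , drop = FALSE]
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 species after filtering")
  if (stats::sd(m$rel_change) == 0 || stats::sd(m$median_d) == 0)
    stop("zero variance in one of the variables; correlation undefined")
  r <- stats::cor(m$rel_change, m$median_d)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(n = n, pearson_r = r, r_squared = r^2, p_value = p,
                 species = m$species),
            class = "demography_correlation")
}

#' @export
print.demography_correlation <- function(x, ...) {
  cat(sprintf(
    "<demography_correlation> n = %d: r = %.3f (R^2 = %.3f, p = %.3g)\n",
    x$n, x$pearson_r, x$r_squared, x$p_value))
  invisible(x)
}
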