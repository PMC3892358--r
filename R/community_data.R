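# ---- community matrix and plot metadata -------------------------------------

#' Eight-class cover scale midpoints (percent)
#'
#' Midpoints of the ordinal cover classes <0.1, 0.1-1, 1-5, 5-15, 15-25,
#' 25-50, 50-75 and >75 percent used in alpine vegetation releves.
#' @export
COVER_CLASS_MIDPOINTS <- c(0.05, 0.5, 3, 10, 20, 37.5, 62.5, 82.5)

#' Construct a plot x species community matrix
#'
#' @param cover Numeric matrix, plots in rows, species in columns; percent
#'   cover in [0, 100], 0 = absent. Row and column names are required and must
#'   be unique.
#' @return An object of class \code{community_matrix} (the validated matrix).
#' @export
community_matrix <- function(cover) {
  cover <- as.matrix(cover)
  storage.mode(cover) <- "double"
  if (is.null(rownames(cover)) || is.null(colnames(cover)))
    stop("cover matrix needs plot row names and species column names")
  if (anyDuplicated(rownames(cover))) stop("duplicate plot ids")
  if (anyDuplicated(colnames(cover))) stop("duplicate species names")
  if (anyNA(cover)) stop("cover values must not be missing")
  if (any(cover < 0) || any(cover > 100))
    stop("cover values must lie in [0, 100]")
  structure(cover, class = c("community_matrix", "matrix", "array"))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("Community matrix:", nrow(x), "plots x", ncol(x), "species;",
      sum(x > 0), "occurrences\n")
  invisible(x)
}

#' Presence/absence view of a community matrix
#' @param cm A \code{community_matrix}.
#' @return Integer 0/1 matrix of the same shape.
#' @export
presence <- function(cm) {
  p <- unclass(cm) > 0
  storage.mode(p) <- "integer"
  p
}

#' Per-species occurrence counts
#' @param cm A \code{community_matrix}.
#' @export
occurrence_counts <- function(cm) colSums(presence(cm))

#' Map ordinal cover classes to percent midpoints
#'
#' Class k (1..8) is replaced by the midpoint of its cover interval
#' (0.05, 0.5, 3, 10, 20, 37.5, 62.5, 82.5 percent); 0 stays 0 (absent).
#'
#' @param raw Integer matrix of classes 0..8 with plot/species dimnames.
#' @param midpoints Midpoint vector, one value per class (default the
#'   standard 8-class scale).
#' @return A \code{community_matrix} of percent covers.
#' @export
map_cover_classes <- function(raw, midpoints = COVER_CLASS_MIDPOINTS) {
  raw <- as.matrix(raw)
  if (length(midpoints) != 8L || any(diff(midpoints) <= 0))
    stop("'midpoints' must be 8 strictly increasing values")
  vals <- unique(as.vector(raw))
  if (anyNA(vals) || any(vals != round(vals)) || any(vals < 0 | vals > 8))
    stop("cover classes must be integers in 0..8")
  out <- matrix(c(0, midpoints)[raw + 1L], nrow = nrow(raw),
                dimnames = dimnames(raw))
  community_matrix(out)
}

#' Drop infrequent species
#'
#' Retains species present in strictly more than \code{min_occurrences}
#' plots (the "more than 20 times" rule by default).
#'
#' @param cm A \code{community_matrix}.
#' @param min_occurrences Occurrence threshold (species kept if count >
#'   this; default 20).
#' @return Filtered \code{community_matrix}.
#' @export
filter_species_by_frequency <- function(cm, min_occurrences = 20) {
  stopifnot(inherits(cm, "community_matrix"), min_occurrences >= 1)
  n <- occurrence_counts(cm)
  keep <- n > min_occurrences
  if (!any(keep))
    stop("no species occurs more than ", min_occurrences,
         " times (max frequency observed: ", max(n), ")")
  community_matrix(unclass(cm)[, keep, drop = FALSE])
}

#' Keep plots dominated by a retained species set
#'
#' A plot is kept when the retained species account for at least
#' \code{min_fraction} of its total cover (boundary inclusive). Plots with
#' zero total cover are dropped with a warning.
#'
#' @param cm A \code{community_matrix} (all species, including non-retained).
#' @param retained Character vector of retained species.
#' @param min_fraction Minimum relative cover of the retained set (default
#'   0.8).
#' @return \code{community_matrix} restricted to the surviving plots and the
#'   retained species columns.
#' @export
filter_plots_by_relative_cover <- function(cm, retained, min_fraction = 0.8) {
  stopifnot(inherits(cm, "community_matrix"),
            min_fraction > 0, min_fraction <= 1)
  retained <- intersect(as.character(retained), colnames(cm))
  if (!length(retained)) stop("'retained' species set is empty")
  tot <- rowSums(unclass(cm))
  if (any(tot == 0)) {
    warning(sum(tot == 0), " plot(s) with zero total cover dropped")
  }
  frac <- rowSums(unclass(cm)[, retained, drop = FALSE]) / tot
  keep <- !is.na(frac) & tot > 0 & frac >= min_fraction
  if (!any(keep)) stop("no plot reaches relative cover ", min_fraction)
  community_matrix(unclass(cm)[keep, retained, drop = FALSE])
}

#' Construct plot metadata
#'
#' @param plot_id Character vector of unique plot ids.
#' @param elevation Elevation in metres above sea level.
#' @param zone Optional vegetation-zone factor.
#' @param valid_range Allowed elevation span (default 0..5000 m).
#' @return A data.frame of class \code{plot_metadata}.
#' @export
plot_metadata <- function(plot_id, elevation, zone = NULL,
                          valid_range = c(0, 5000)) {
  plot_id <- as.character(plot_id)
  if (anyDuplicated(plot_id)) stop("duplicate plot ids in metadata")
  elevation <- as.numeric(elevation)
  if (length(elevation) != length(plot_id)) stop("length mismatch")
  if (anyNA(elevation) || any(elevation < valid_range[1]) ||
      any(elevation > valid_range[2]))
    stop("elevations must lie in [", valid_range[1], ", ", valid_range[2], "] m")
  out <- data.frame(plot_id = plot_id, elevation = elevation,
                    stringsAsFactors = FALSE)
  if (!is.null(zone)) out$zone <- as.character(zone)
  class(out) <- c("plot_metadata", "data.frame")
  out
}

#' Assign vegetation zones by elevation breakpoints
#'
#' Zones are half-open elevation bands [low, high): with breakpoints
#' (900, 1500, 2200) an elevation of exactly 1500 m falls in the third zone.
#'
#' @param meta A \code{plot_metadata}.
#' @param breakpoints Three strictly increasing elevations separating the
#'   four zones (default 900, 1500, 2200 m; these are configuration values,
#'   not field-derived).
#' @param labels Zone names, low to high.
#' @return \code{meta} with a \code{zone} column; elevations outside the
#'   configured span get zone \code{"unassigned"} with a warning.
#' @export
assign_vegetation_zones <- function(meta,
                                    breakpoints = c(900, 1500, 2200),
                                    labels = c("colline", "montane",
                                               "subalpine", "alpine"),
                                    span = c(0, 5000)) {
  stopifnot(inherits(meta, "plot_metadata"))
  if (length(breakpoints) != length(labels) - 1L || any(diff(breakpoints) <= 0))
    stop("need strictly increasing breakpoints, one fewer than labels")
  idx <- findInterval(meta$elevation, breakpoints, left.open = FALSE) + 1L
  zone <- labels[idx]
  out_of_span <- meta$elevation < span[1] | meta$elevation >= span[2]
  if (any(out_of_span)) {
    warning(sum(out_of_span), " plot(s) outside configured span marked unassigned")
    zone[out_of_span] <- "unassigned"
  }
  meta$zone <- zone
  meta
}

#' Read a community matrix from CSV (first column = plot id)
#'
#' @param path CSV path.
#' @param cover_classes If TRUE values are ordinal classes 0..8 and are mapped
#'   through \code{\link{map_cover_classes}}; if FALSE they are percent cover.
#' @return A \code{community_matrix}.
#' @export
read_community_csv <- function(path, cover_classes = FALSE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (cover_classes) map_cover_classes(m) else community_matrix(m)
}

#' Read plot metadata from CSV (columns plot_id, elevation[, zone])
#' @param path CSV path.
#' @export
read_metadata_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("plot_id", "elevation") %in% names(df)))
    stop("metadata CSV needs columns 'plot_id' and 'elevation'")
  plot_metadata(df$plot_id, df$elevation,
                zone = if ("zone" %in% names(df)) df$zone else NULL)
}

#' Write a community matrix to CSV
#' @param cm A \code{community_matrix}.
#' @param path Output path.
#' @export
write_community_csv <- function(cm, path) {
  df <- data.frame(plot_id = rownames(cm), unclass(cm), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
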