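#' Threshold an occurrence-probability map
#'
#' Converts a 0-1 occurrence-probability map to a presence mask.  A zero
#' threshold means "anywhere the probability is larger than zero" (strict
#' `> 0`); a positive threshold is inclusive (`>= threshold`), so cells at
#' exactly the printed threshold are kept.
#'
#' @param prob_map Numeric matrix of probabilities in `[0, 1]` (`NA` allowed
#'   for land).
#' @param threshold Number in `[0, 1]`.
#' @return Logical matrix (`NA` maps to `FALSE`).
#' @export
threshold_probability <- function(prob_map, threshold) {
  if (length(threshold) != 1 || is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a single number in [0, 1]")
  if (any(prob_map < 0 | prob_map > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  m <- if (threshold == 0) prob_map > 0 else prob_map >= threshold
  m[is.na(m)] <- FALSE
  m
}

#' Threshold a habitat-suitability map
#'
#' Squid distributions come as habitat-suitability surfaces with
#' species-specific published thresholds; suitability at or above the
#' threshold is habitat.
#'
#' @param suit_map Numeric matrix of suitabilities in `[0, 1]`.
#' @param species_threshold Species-specific threshold in `[0, 1]`.
#' @return Logical matrix.
#' @export
threshold_suitability <- function(suit_map, species_threshold) {
  m <- suit_map >= species_threshold
  m[is.na(m)] <- FALSE
  m
}

# Overlap length of 1-D cell [a1,a2] with cells given by bounds vector b.
# Returns a (length(b)-1) vector.
overlap_1d <- function(a1, a2, b) {
  lo <- pmax(a1, b[-length(b)])
  hi <- pmin(a2, b[-1])
  pmax(hi - lo, 0)
}

#' Largest-area-fraction regridding of a categorical mask
#'
#' Each target cell takes the 0/1 class covering the largest fraction of its
#' area.  Overlaps are computed on a plate-carree approximation with
#' cosine-latitude weighting (area element proportional to
#' `dlon * dsin(lat)`), which is exact for the majority vote on regular
#' lon-lat grids.
#'
#' @param mask Logical matrix `[lon, lat]` on the source grid.
#' @param src_lon_bounds,src_lat_bounds Source cell edges, degrees.
#' @param target An `ocean_grid` (its lon/lat bounds are used).
#' @return Logical matrix on the target grid.
#' @export
regrid_largest_area_fraction <- function(mask, src_lon_bounds, src_lat_bounds,
                                         target) {
  nsl <- length(src_lon_bounds) - 1L
  nsb <- length(src_lat_bounds) - 1L
  stopifnot(all(dim(mask) == c(nsl, nsb)))
  tl <- target$lon_bounds; tb <- target$lat_bounds
  if (max(src_lon_bounds) <= min(tl) || min(src_lon_bounds) >= max(tl) ||
      max(src_lat_bounds) <= min(tb) || min(src_lat_bounds) >= max(tb))
    stop("source and target grids do not overlap")
  sinb <- sin(src_lat_bounds * pi / 180)
  out <- matrix(FALSE, target$nlon, target$nlat)
  any_overlap <- FALSE
  for (i in seq_len(target$nlon)) {
    wlon <- overlap_1d(tl[i], tl[i + 1], src_lon_bounds)
    if (all(wlon == 0)) next
    for (j in seq_len(target$nlat)) {
      wlat <- overlap_1d(sin(tb[j] * pi / 180), sin(tb[j + 1] * pi / 180), sinb)
      if (all(wlat == 0)) next
      w <- outer(wlon, wlat)                # area weights of source cells
      tot <- sum(w)
      if (tot == 0) next
      any_overlap <- TRUE
      out[i, j] <- sum(w[mask]) > tot / 2   # strict majority for class 1
    }
  }
  if (!any_overlap) stop("source and target grids do not overlap")
  out
}

#' Extrude a 2-D habitat mask over a species depth range
#'
#' A depth level belongs to the species range iff its centre lies in the
#' closed interval `[min_depth, max_depth]`.  The result is intersected
#' with the wet mask (so land columns and below-seafloor cells are empty)
#' and capped at `depth_cap`.
#'
#' @param mask2d Logical `[lon, lat]` matrix.
#' @param min_depth,max_depth Species depth range, metres, `min < max`.
#' @param grid An `ocean_grid`.
#' @param depth_cap Analysis depth cap in metres (default 3185).
#' @return Logical `[lon, lat, depth]` array.
#' @export
extrude_depth <- function(mask2d, min_depth, max_depth, grid, depth_cap = 3185) {
  stopifnot(min_depth < max_depth)
  in_range <- grid$depth >= min_depth & grid$depth <= max_depth &
    grid$depth <= depth_cap
  if (!any(in_range))
    warning("no depth level centre falls inside the species depth range")
  levsel <- aperm(array(in_range, dim = c(grid$ndepth, grid$nlon, grid$nlat)),
                  c(2, 3, 1))
  expand_mask3d(mask2d, grid) & levsel & grid$wet
}

#' Load the species registry from a table and probability maps
#'
#' Builds a `species_registry`: per species the depth range, the 2-D
#' probability (or suitability) map thresholded and regridded to the model
#' grid, and the 3-D habitat mask.  Species whose maps extend north of the
#' domain are truncated; the truncated probability-weighted fraction is
#' reported via a message.
#'
#' @param table Data frame with columns `species_id`, `name`, `common_name`,
#'   `min_depth_m`, `max_depth_m` and optionally `suitability_threshold`
#'   (non-`NA` only for suitability-based species).
#' @param prob_maps Named list (names = `species_id`) of probability maps,
#'   each a list with `map` (matrix `[lon, lat]`), `lon_bounds`,
#'   `lat_bounds`.  Maps already on the model grid may omit the bounds.
#' @param grid Target `ocean_grid`.
#' @param probability_threshold Occurrence-probability threshold (0 or 0.8
#'   in the study design; any value in `[0, 1]` accepted).  Suitability
#'   species always use their own `suitability_threshold`.
#' @return An object of class `species_registry`: list of records, each with
#'   `species_id`, `name`, `common_name`, `min_depth`, `max_depth`,
#'   `mask2d`, `habitat3d`.
#' @export
load_registry <- function(table, prob_maps, grid, probability_threshold = 0) {
  if (anyDuplicated(table$species_id))
    stop("duplicate species_id in species table")
  records <- lapply(seq_len(nrow(table)), function(r) {
    row <- table[r, ]
    key <- as.character(row$species_id)
    pm <- prob_maps[[key]]
    if (is.null(pm)) stop(sprintf("missing probability map for species %s (%s)",
                                  key, row$name))
    suit <- if ("suitability_threshold" %in% names(row)) row$suitability_threshold else NA
    m2_src <- if (!is.na(suit)) threshold_suitability(pm$map, suit)
              else threshold_probability(pm$map, probability_threshold)
    if (!is.null(pm$lon_bounds) &&
        !(identical(pm$lon_bounds, grid$lon_bounds) &&
          identical(pm$lat_bounds, grid$lat_bounds))) {
      north <- pm$lat_bounds[-1] > max(grid$lat_bounds)
      tot <- sum(pm$map, na.rm = TRUE)
      if (any(north) && tot > 0) {
        frac <- sum(pm$map[, north], na.rm = TRUE) / tot
        if (frac > 0)
          message(sprintf("species %s: %.2f%% of probability mass north of the domain truncated",
                          key, 100 * frac))
      }
      m2 <- regrid_largest_area_fraction(m2_src, pm$lon_bounds, pm$lat_bounds, grid)
    } else m2 <- m2_src
    list(species_id = row$species_id, name = row$name,
         common_name = row$common_name,
         min_depth = row$min_depth_m, max_depth = row$max_depth_m,
         mask2d = m2,
         habitat3d = extrude_depth(m2, row$min_depth_m, row$max_depth_m, grid))
  })
  names(records) <- as.character(table$species_id)
  structure(list(records = records, predator_id = table$species_id[1],
                 probability_threshold = probability_threshold),
            class = "species_registry")
}

#' @export
print.species_registry <- function(x, ...) {
  cat(sprintf("<species_registry> %d species (predator id %s), p-threshold %g\n",
              length(x$records), x$predator_id, x$probability_threshold))
  invisible(x)
}

#' Packaged reference species table
#'
#' The 29-species table of the toothfish food-web study: the Antarctic
#' toothfish (id 1) and its 28 prey, with depth ranges, the squid
#' suitability thresholds, and the published preferred temperature, pO2
#' threshold and critical AGI at both occurrence-probability thresholds
#' (the values for threshold 0.8 are the parenthesised columns `*_p08`).
#'
#' @return A data frame with one row per species.
#' @export
species_table <- function() {
  path <- system.file("extdata", "species_table.csv", package = "agihabitat")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
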