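# Community-composition metrics, pool physical attributes, and light
# processing.

# functional groups recognised in surveys
.fg_levels <- c("fleshy_algae", "surfgrass", "coralline_algae",
                "non_coralline_crust", "invertebrate", "mussel", "bare_rock")
.fg_producers <- c("fleshy_algae", "surfgrass")          # non-encrusting
.fg_consumers <- c("invertebrate", "mussel")

#' Relative cover by functional group
#'
#' Percent cover of each functional group divided by the total cover in the
#' pool. Total cover may exceed 100% because of canopy layering, so the
#' result is a proper composition (fractions summing to 1) rather than raw
#' percentages.
#'
#' @param survey Data frame with columns `group` (one of fleshy_algae,
#'   surfgrass, coralline_algae, non_coralline_crust, invertebrate, mussel,
#'   bare_rock) and `percent_cover` (>= 0).
#' @return Named numeric vector of fractions summing to 1 over the groups
#'   present.
#' @examples
#' sv <- data.frame(group = c("fleshy_algae", "invertebrate"),
#'                  percent_cover = c(60, 60))
#' relative_cover(sv) # 0.5, 0.5
#' @export
relative_cover <- function(survey) {
  stopifnot(all(c("group", "percent_cover") %in% names(survey)))
  if (any(survey$percent_cover < 0)) {
    stop("`percent_cover` must be >= 0", call. = FALSE)
  }
  bad <- setdiff(unique(survey$group), .fg_levels)
  if (length(bad)) {
    stop("unknown functional group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tot <- sum(survey$percent_cover)
  if (tot <= 0) stop("degenerate survey: total cover is zero", call. = FALSE)
  out <- c(tapply(survey$percent_cover, survey$group, sum) / tot)
  out[order(match(names(out), .fg_levels))]
}

#' Producer dominance
#'
#' Relative percent cover of non-encrusting producers (fleshy macroalgae +
#' surfgrass) minus relative percent cover of consumers (all invertebrates,
#' mussels included), in percentage points. Encrusting algae (coralline and
#' non-coralline crusts) and bare rock enter the relative-cover denominator
#' but neither term, since crusts contribute little to producer biomass.
#' Positive values indicate producer-dominated communities; the score lies
#' in \[-100, 100\].
#'
#' @inheritParams relative_cover
#' @return Producer dominance in percentage points.
#' @export
producer_dominance <- function(survey) {
  rc <- relative_cover(survey) * 100
  sum(rc[names(rc) %in% .fg_producers]) - sum(rc[names(rc) %in% .fg_consumers])
}

#' Convert mobile-organism counts to percent cover
#'
#' Mobile invertebrates are counted rather than surveyed for cover; each
#' taxon's count is converted with a per-individual footprint area:
#' `cover = count * area_cm2 / surface_area_m2 / 1e4 * 100`.
#'
#' @param mobile_counts Data frame with columns `taxon`, `count` and
#'   optionally `area_cm2` (per-individual footprint); taxa without an
#'   `area_cm2` value are looked up in `footprints`.
#' @param surface_area_m2 Pool bottom surface area, m2 (> 0).
#' @param footprints Lookup table (`taxon`, `area_cm2`) used for taxa
#'   without an explicit area; defaults to [default_mobile_footprints()].
#' @return Data frame with columns `taxon`, `group` ("invertebrate") and
#'   `percent_cover`, ready to append to a survey.
#' @examples
#' mobile_counts_to_cover(data.frame(taxon = "snail", count = 10,
#'                                   area_cm2 = 10), 1) # 1%
#' @export
mobile_counts_to_cover <- function(mobile_counts, surface_area_m2,
                                   footprints = default_mobile_footprints()) {
  stopifnot(all(c("taxon", "count") %in% names(mobile_counts)),
            surface_area_m2 > 0)
  area <- if ("area_cm2" %in% names(mobile_counts)) {
    mobile_counts$area_cm2
  } else {
    rep(NA_real_, nrow(mobile_counts))
  }
  need <- is.na(area)
  area[need] <- footprints$area_cm2[match(mobile_counts$taxon[need],
                                          footprints$taxon)]
  if (any(is.na(area))) {
    stop("per-individual `area_cm2` missing for taxa: ",
         paste(mobile_counts$taxon[is.na(area)], collapse = ", "),
         call. = FALSE)
  }
  data.frame(taxon = mobile_counts$taxon, group = "invertebrate",
             percent_cover = mobile_counts$count * area /
               (surface_area_m2 * 1e4) * 100)
}

#' Default per-individual footprint areas for mobile invertebrates
#'
#' Synthetic placeholder values (order-of-magnitude body footprints for
#' common rocky-intertidal mobile taxa); replace with locally calibrated
#' areas for real surveys.
#'
#' @return Data frame with `taxon` and `area_cm2`.
#' @export
default_mobile_footprints <- function() {
  data.frame(
    taxon = c("hermit_crab", "snail", "limpet", "chiton", "crab",
              "sea_star", "urchin"),
    area_cm2 = c(2, 3, 6, 9, 18, 60, 30))
}

#' Normalise tide height to the site's maximum tidal extent
#'
#' @param height Surveyed tide height, m.
#' @param site_max_extent Maximum tidal extent at the site, m (> 0).
#' @return Fraction of the tidal extent.
#' @export
normalize_tide_height <- function(height, site_max_extent) {
  if (any(site_max_extent <= 0)) {
    stop("`site_max_extent` must be > 0", call. = FALSE)
  }
  height / site_max_extent
}

#' Convert logger light intensity to PAR
#'
#' Linear conversion from lumens/m2 (lux) to photosynthetically active
#' radiation. The default coefficient 0.0185 umol photons m-2 s-1 per lux
#' is the customary daylight conversion (about 54 lux per umol m-2 s-1)
#' appropriate for pendant-style loggers; it is configurable because the
#' calibration is instrument- and spectrum-specific.
#'
#' @param intensity Light intensity, lumens/m2 (>= 0).
#' @param coefficient umol photons m-2 s-1 per lumen/m2.
#' @return PAR, umol photons m-2 s-1.
#' @export
lumens_to_par <- function(intensity, coefficient = 0.0185) {
  if (any(intensity < 0)) stop("`intensity` must be >= 0", call. = FALSE)
  coefficient * intensity
}

#' Integrate PAR over the sampling window
#'
#' Trapezoidal integral of the PAR series between the first and last water
#' sample, giving the cumulative light available over the sampling period.
#'
#' @param times_min Times of the light readings, minutes.
#' @param par PAR readings, umol photons m-2 s-1 (same length).
#' @param t_first_min,t_last_min Window limits, minutes (within the series
#'   span).
#' @return Integrated PAR in mol photons m-2.
#' @export
integrate_par <- function(times_min, par, t_first_min, t_last_min) {
  stopifnot(length(times_min) == length(par))
  keep <- times_min >= t_first_min & times_min <= t_last_min
  if (sum(keep) < 2) {
    stop("fewer than 2 light readings inside the sampling window",
         call. = FALSE)
  }
  t <- times_min[keep] * 60   # -> seconds
  y <- par[keep]
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2) * 1e-6  # umol -> mol
}

#' PCA of pool physical attributes
#'
#' Principal components of the standardised physical-attribute table
#' (correlation-matrix PCA, since the attributes have mixed units). The
#' loading signs are oriented so that pool volume loads positively on PC1,
#' making PC1 interpretable as "pool size" and PC2 as "pool location".
#'
#' @param geometry Data frame of pools x attributes; expected columns
#'   `tide_height_norm`, `max_depth_m`, `volume_m3`, `perimeter_m`,
#'   `surface_area_m2`, `sa_to_vol` (any numeric columns are accepted;
#'   at least 3 rows). Constant columns are dropped with a warning.
#' @return List with `scores` (pools x PCs), `loadings`, `explained`
#'   (variance fractions summing to 1), and `sdev`.
#' @export
physical_pca <- function(geometry) {
  num <- geometry[vapply(geometry, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("need at least 3 pools for a PCA", call. = FALSE)
  sds <- vapply(num, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(names(num)[sds == 0], collapse = ", "))
    num <- num[sds > 0]
  }
  p <- stats::prcomp(num, center = TRUE, scale. = TRUE)
  if ("volume_m3" %in% rownames(p$rotation) &&
      p$rotation["volume_m3", 1] < 0) {
    p$rotation[, 1] <- -p$rotation[, 1]
    p$x[, 1] <- -p$x[, 1]
  }
  list(scores = p$x, loadings = p$rotation,
       explained = p$sdev^2 / sum(p$sdev^2), sdev = p$sdev)
}
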