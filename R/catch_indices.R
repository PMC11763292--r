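#' Mean trophic level of a year's catch
#'
#' Catch-weighted mean of species trophic levels. Species lacking a
#' trophic-level entry are excluded from numerator and denominator; the
#' fraction of catch carrying a known trophic level is reported as a
#' coverage diagnostic.
#'
#' @param catch Named numeric vector of catches (tonnes) by species code.
#' @param tl A [tl_table()] (or named numeric) of species trophic levels.
#' @return List with `mtl`, `coverage` (usable / total catch), `n_excluded`.
#' @export
mean_trophic_level <- function(catch, tl) {
  if (is.null(names(catch))) stop("catch must be named by species",
                                  call. = FALSE)
  if (anyNA(catch) || any(catch < 0)) {
    stop("catches must be non-negative", call. = FALSE)
  }
  known <- names(catch) %in% names(tl)
  usable <- catch[known]
  if (sum(usable) <= 0) {
    stop("no usable catch: zero catch with known trophic level",
         call. = FALSE)
  }
  list(
    mtl = sum(usable * tl[names(usable)]) / sum(usable),
    coverage = if (sum(catch) > 0) sum(usable) / sum(catch) else NA_real_,
    n_excluded = sum(!known)
  )
}

#' Fishing-in-Balance index
#'
#' `FiB_k = log10(Y_k (1/TE)^MTL_k) - log10(Y_0 (1/TE)^MTL_0)` relative to a
#' reference year. Zero means the change in catch is compatible with the
#' change in mean trophic level at transfer efficiency `TE`; positive values
#' indicate geographic or bathymetric expansion of the fishery.
#'
#' @param Y Numeric vector of yearly catches (must be positive).
#' @param MTL Numeric vector of yearly mean trophic levels.
#' @param ref Index of the reference year within the vectors (default 1).
#' @param TE Transfer efficiency in (0, 1), default 0.1.
#' @return Numeric vector of FiB values; exactly 0 at the reference year.
#' @export
fishing_in_balance <- function(Y, MTL, ref = 1L, TE = 0.1) {
  if (length(Y) != length(MTL)) stop("Y and MTL lengths differ", call. = FALSE)
  if (anyNA(Y) || any(Y <= 0)) stop("all catches must be positive",
                                    call. = FALSE)
  if (TE <= 0 || TE >= 1) stop("TE must lie in (0, 1)", call. = FALSE)
  fib <- (log10(Y) + MTL * log10(1 / TE)) -
    (log10(Y[ref]) + MTL[ref] * log10(1 / TE))
  fib[ref] <- 0
  fib
}

#' Yearly catch, MTL and FiB series from landing records
#'
#' Aggregates landing records by year, computes the mean trophic level of
#' the catch and the Fishing-in-Balance index relative to a reference year
#' (default: the first year of the series).
#'
#' @param records Data frame of landing records with at least `year`,
#'   `species_code`, `catch_t` columns (see [read_catch_table()]).
#' @param tl A [tl_table()] keyed by `species_code`.
#' @param ref_year Reference year; default the first year present.
#' @param TE Transfer efficiency, default 0.1.
#' @return Data frame `(year, Y, MTL, coverage, FiB)`, one row per year.
#' @export
index_series <- function(records, tl, ref_year = NULL, TE = 0.1) {
  stopifnot(is.data.frame(records),
            all(c("year", "species_code", "catch_t") %in% names(records)))
  years <- sort(unique(records$year))
  if (is.null(ref_year)) ref_year <- years[1]
  if (!ref_year %in% years) stop("reference year not in series",
                                 call. = FALSE)
  per_year <- lapply(years, function(y) {
    sub <- records[records$year == y, , drop = FALSE]
    catch <- tapply(sub$catch_t, sub$species_code, sum)
    m <- mean_trophic_level(stats::setNames(as.numeric(catch), names(catch)),
                            tl)
    data.frame(year = y, Y = sum(sub$catch_t), MTL = m$mtl,
               coverage = m$coverage)
  })
  out <- do.call(rbind, per_year)
  out$FiB <- fishing_in_balance(out$Y, out$MTL,
                                ref = match(ref_year, out$year), TE = TE)
  attr(out, "ref_year") <- ref_year
  attr(out, "TE") <- TE
  out
}

# Single two-region split at breakpoint n1 (last year of the initial
# region). Assumes the initial region stays in trophic balance (FiB = 0
# anchored at n1), so its catch follows
#   Yhat1_k = Y_n1 (1/TE)^(MTL_n1 - MTL_k)
# and its MTL follows
#   MTLhat1_k = MTL_n1 - log10(Y_k / Y_n1) / log10(1/TE);
# the expanded region takes the residual catch and the MTL forced by the
# mass-weighted identity MTL_k Y_k = sum_r MTLhat_r Yhat_r.
rmtl_split_once <- function(year, Y, MTL, n1, TE) {
  i1 <- match(n1, year)
  lg <- log10(1 / TE)
  out <- data.frame(year = rep(year, each = 2L),
                    region = rep(1:2, length(year)),
                    Y_hat = NA_real_, MTL_hat = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  for (k in seq_along(year)) {
    r1 <- 2L * k - 1L
    r2 <- 2L * k
    if (year[k] <= n1) {
      out$Y_hat[r1] <- Y[k]; out$MTL_hat[r1] <- MTL[k]
      out$Y_hat[r2] <- 0;    out$MTL_hat[r2] <- NA_real_
      next
    }
    y1 <- Y[i1] * (1 / TE)^(MTL[i1] - MTL[k])
    m1 <- MTL[i1] - log10(Y[k] / Y[i1]) / lg
    flag <- ""
    y2 <- Y[k] - y1
    if (y2 < 0) {         # reported catch below the balanced-region estimate
      y1 <- Y[k]; y2 <- 0
      flag <- "assumption_violated"
    }
    m2 <- if (y2 > 0) (MTL[k] * Y[k] - m1 * y1) / y2 else NA_real_
    if (y2 == 0 && flag == "") flag <- "expanded_mtl_undefined"
    out$Y_hat[r1] <- y1; out$MTL_hat[r1] <- m1
    out$Y_hat[r2] <- y2; out$MTL_hat[r2] <- m2
    out$flag[r1] <- flag; out$flag[r2] <- flag
  }
  out
}

#' Region-based decomposition of catch and MTL under fleet expansion
#'
#' Splits a yearly (catch, MTL) series into an initial fishing region and
#' one expanded region per breakpoint. The initial region is assumed to
#' remain in trophic balance (Fishing-in-Balance fixed at zero, anchored at
#' the breakpoint year), which determines its estimated catch and MTL; each
#' expanded region receives the residual catch and the MTL required by the
#' mass-weighted identity `sum_r MTLhat_r Yhat_r = MTL_k Y_k`. With more
#' than one breakpoint the two-region split is applied recursively to the
#' residual series.
#'
#' @param series Data frame with columns `year`, `Y`, `MTL` (e.g. from
#'   [index_series()]).
#' @param breakpoints Increasing vector of breakpoint years; breakpoint
#'   `n_r` is the last year attributed wholly to regions `1..r`.
#' @param TE Transfer efficiency, default 0.1.
#' @return Data frame `(year, region, Y_hat, MTL_hat, flag)`. Years where
#'   the residual catch is negative are flagged `assumption_violated` (the
#'   region-1 estimate is capped at the reported total so the partition
#'   still sums to `Y_k`).
#' @export
rmtl_decompose <- function(series, breakpoints, TE = 0.1) {
  stopifnot(is.data.frame(series),
            all(c("year", "Y", "MTL") %in% names(series)))
  if (length(breakpoints) < 1L || is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  if (!all(breakpoints %in% series$year)) {
    stop("every breakpoint year must be in the series", call. = FALSE)
  }
  if (any(series$Y <= 0)) stop("all catches must be positive", call. = FALSE)
  ord <- order(series$year)
  year <- series$year[ord]; Y <- series$Y[ord]; MTL <- series$MTL[ord]

  split <- rmtl_split_once(year, Y, MTL, breakpoints[1], TE)
  if (length(breakpoints) == 1L) return(split)

  # recurse on the residual (newest-region) series for later breakpoints
  res <- split[split$region == 2L & split$Y_hat > 0 &
                 !is.na(split$MTL_hat), , drop = FALSE]
  if (!all(breakpoints[-1] %in% res$year)) {
    stop("residual series does not cover later breakpoints", call. = FALSE)
  }
  sub <- rmtl_decompose(
    data.frame(year = res$year, Y = res$Y_hat, MTL = res$MTL_hat),
    breakpoints[-1], TE = TE)
  sub$region <- sub$region + 1L
  keep <- split[!(split$region == 2L & split$year %in% sub$year), ,
                drop = FALSE]
  out <- rbind(keep, sub)
  out[order(out$year, out$region), , drop = FALSE]
}

#' Grid landing records into 30-arc-minute quadrants
#'
#' Each record with coordinates is assigned to one half-degree cell of a
#' lattice anchored at integer degrees, with half-open `[edge, edge + 0.5)`
#' bands indexed by the signed floor `(floor(lat/0.5), floor(lon/0.5))`.
#' Per-cell sea-surface area is computed on a spherical Earth at the cell
#' centre latitude (111.32 km per degree).
#'
#' @param records Data frame with `lat`, `lon` (decimal degrees, south/west
#'   negative) and `catch_t` columns.
#' @return Object of class `quadrant_grid`: list with `cells` (data frame
#'   `cell_lat`, `cell_lon`, `catch_t`, `n_records`, `area_km2`) and
#'   `n_excluded` (records lacking coordinates).
#' @export
grid_quadrants <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("lat", "lon", "catch_t") %in% names(records)))
  ok <- !is.na(records$lat) & !is.na(records$lon)
  sub <- records[ok, , drop = FALSE]
  cl <- floor(sub$lat / 0.5)
  cn <- floor(sub$lon / 0.5)
  key <- paste(cl, cn, sep = ":")
  cells <- data.frame(
    cell_lat = as.integer(tapply(cl, key, `[`, 1)),
    cell_lon = as.integer(tapply(cn, key, `[`, 1)),
    catch_t = as.numeric(tapply(sub$catch_t, key, sum)),
    n_records = as.integer(tapply(sub$catch_t, key, length)),
    row.names = NULL
  )
  cells$area_km2 <- quadrant_area((cells$cell_lat + 0.5) * 0.5)
  structure(list(cells = cells, n_excluded = sum(!ok)),
            class = "quadrant_grid")
}

#' Area of a 30-arc-minute quadrant at a given centre latitude
#'
#' @param lat_centre Centre latitude of the cell in decimal degrees.
#' @return Area in square kilometres.
#' @export
quadrant_area <- function(lat_centre) {
  km_per_deg <- 111.32
  (km_per_deg * 0.5) * (km_per_deg * cos(lat_centre * pi / 180) * 0.5)
}

#' Distinct quadrants visited per year and fleet
#'
#' @param records Landing records with `year`, `fleet`, `lat`, `lon`.
#' @return Data frame `(year, fleet, n_quadrants)`.
#' @export
quadrant_counts <- function(records) {
  ok <- !is.na(records$lat) & !is.na(records$lon)
  sub <- records[ok, , drop = FALSE]
  key <- paste(floor(sub$lat / 0.5), floor(sub$lon / 0.5), sep = ":")
  agg <- stats::aggregate(key, by = list(year = sub$year, fleet = sub$fleet),
                          FUN = function(k) length(unique(k)))
  names(agg)[3] <- "n_quadrants"
  agg[order(agg$year, agg$fleet), , drop = FALSE]
}

#' Per-species yearly biomass and density from gridded catches
#'
#' Yearly biomass of a species is the catch summed over all quadrants
#' visited that year; density divides by the total area of the quadrants
#' visited in that year (by any species).
#'
#' @param records Landing records with `year`, `species_code`, `lat`, `lon`,
#'   `catch_t`.
#' @return Data frame `(year, species_code, biomass_t, area_km2,
#'   density_t_km2, flag)`; density is `NA` and flagged when no record of
#'   the year carries coordinates.
#' @export
biomass_by_year <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("year", "species_code", "lat", "lon", "catch_t") %in%
                  names(records)))
  out <- list()
  for (y in sort(unique(records$year))) {
    sub <- records[records$year == y, , drop = FALSE]
    grid <- grid_quadrants(sub)
    area <- sum(grid$cells$area_km2)
    ok <- !is.na(sub$lat) & !is.na(sub$lon)
    b <- tapply(sub$catch_t[ok], sub$species_code[ok], sum)
    if (length(b) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      year = y, species_code = names(b), biomass_t = as.numeric(b),
      area_km2 = area,
      density_t_km2 = if (area > 0) as.numeric(b) / area else NA_real_,
      flag = if (area > 0) "" else "zero_visited_area",
      row.names = NULL)
  }
  do.call(rbind, out)
}

#' Relative fishing-effort indices per year and fleet
#'
#' Yearly totals of days at sea, fishing days and hauls divided by the
#' fleet's reference-year totals (reference year = 1). Fleets absent in the
#' reference year (e.g. a fleet entering mid-series) use their first
#' observed year as reference and are flagged.
#'
#' @param records Landing records with `year`, `fleet` and effort columns
#'   `days_at_sea`, `fishing_days`, `hauls` (missing values excluded and
#'   counted).
#' @param ref_year Reference year (default: first year in the records).
#' @return Data frame `(year, fleet, days_at_sea, fishing_days, hauls,
#'   n_missing, ref_year, flag)` with the three effort columns expressed as
#'   ratios to the fleet's reference year.
#' @export
effort_indices <- function(records, ref_year = NULL) {
  eff_cols <- c("days_at_sea", "fishing_days", "hauls")
  stopifnot(is.data.frame(records),
            all(c("year", "fleet", eff_cols) %in% names(records)))
  if (is.null(ref_year)) ref_year <- min(records$year)
  out <- list()
  for (fl in sort(unique(records$fleet))) {
    sub <- records[records$fleet == fl, , drop = FALSE]
    fl_ref <- ref_year
    flag <- ""
    if (!fl_ref %in% sub$year) {
      fl_ref <- min(sub$year)
      flag <- "fleet_absent_in_reference_year"
    }
    tot <- function(y, col) sum(sub[[col]][sub$year == y], na.rm = TRUE)
    ref_tot <- vapply(eff_cols, function(cc) tot(fl_ref, cc), numeric(1))
    if (any(ref_tot <= 0)) {
      stop(sprintf("fleet '%s': reference-year effort totals must be > 0",
                   fl), call. = FALSE)
    }
    for (y in sort(unique(sub$year))) {
      rows <- sub[sub$year == y, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        year = y, fleet = fl,
        days_at_sea = tot(y, "days_at_sea") / ref_tot["days_at_sea"],
        fishing_days = tot(y, "fishing_days") / ref_tot["fishing_days"],
        hauls = tot(y, "hauls") / ref_tot["hauls"],
        n_missing = sum(is.na(rows[, eff_cols])),
        ref_year = fl_ref, flag = flag, row.names = NULL)
    }
  }
  do.call(rbind, out)
}
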