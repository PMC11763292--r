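#' Generate a seeded, balanced synthetic food web
#'
#' Builds a trophically ordered web — one detritus group, `n_prod`
#' producers, and consumers whose diets are drawn from strictly
#' lower-indexed groups (acyclic) with optional small cannibalism. Biomass
#' follows a trophic pyramid (roughly an order of magnitude per level) and
#' rate parameters bracket the magnitudes seen in coastal pelagic models
#' (consumer P/B 0.2-5 /yr, P/Q 0.1-0.35, producer P/B 10-100 /yr). Every
#' non-detritus group receives a small fishery catch so its ecotrophic
#' efficiency is strictly positive; parameter draws are resampled until all
#' EE fall inside (0, 1). The same seed always returns the identical web.
#'
#' @param n_groups Total number of groups (>= 3: detritus, >= 1 producer,
#'   >= 1 consumer).
#' @param seed Integer seed.
#' @param n_prod Number of producers, default 1.
#' @param cannibalism_prob Probability a consumer gets a small (< 0.1)
#'   diagonal diet fraction, default 0.2.
#' @param max_tries Resampling budget, default 200.
#' @return List with `diet` (a [diet_matrix()]) and `groups` (a
#'   [group_params()] table with all of B, PB, QB, EE specified).
#' @export
generate_foodweb <- function(n_groups, seed, n_prod = 1L,
                             cannibalism_prob = 0.2, max_tries = 200L) {
  if (n_groups < 3L) stop("need at least 3 groups", call. = FALSE)
  if (n_prod < 1L || n_prod > n_groups - 2L) {
    stop("need at least one producer and one consumer", call. = FALSE)
  }
  set.seed(seed)
  n_cons <- n_groups - 1L - n_prod
  codes <- c("DET", paste0("P", seq_len(n_prod)), paste0("C", seq_len(n_cons)))
  roles <- c("detritus", rep("producer", n_prod), rep("consumer", n_cons))

  for (try in seq_len(max_tries)) {
    dc <- matrix(0, n_groups, n_groups, dimnames = list(codes, codes))
    for (j in (n_prod + 2L):n_groups) {
      lower <- seq_len(j - 1L)
      n_prey <- sample.int(length(lower), 1L)
      prey <- sample(lower, n_prey)
      w <- stats::runif(n_prey)
      frac <- w / sum(w)
      dc[prey, j] <- frac
      if (stats::runif(1) < cannibalism_prob) {
        can <- stats::runif(1, 0.01, 0.1)
        dc[, j] <- dc[, j] * (1 - can)
        dc[j, j] <- dc[j, j] + can
      }
    }
    # trophic pyramid: biomass shrinks with index, rates by role
    level <- c(0, rep(0, n_prod), ceiling(seq_len(n_cons) / 2))
    B <- stats::rlnorm(n_groups, meanlog = log(10) * (1 - level), sdlog = 0.3)
    B[1] <- stats::rlnorm(1, log(100), 0.2)              # detritus pool
    PB <- ifelse(roles == "producer", stats::runif(n_groups, 10, 100),
                 stats::runif(n_groups, 0.2, 5))
    PB[roles == "detritus"] <- NA_real_
    QB <- ifelse(roles == "consumer",
                 PB / stats::runif(n_groups, 0.1, 0.35), NA_real_)
    catch <- ifelse(roles == "detritus", 0,
                    stats::runif(n_groups, 0.001, 0.01) * B *
                      ifelse(is.na(PB), 1, PB))
    pred_on <- as.numeric(dc %*% ifelse(is.na(QB), 0, B * QB))
    EE <- ifelse(roles == "detritus", NA_real_,
                 (pred_on + catch) / (B * PB))
    ok <- roles == "detritus" | (EE > 0 & EE < 1)
    if (all(ok)) {
      diet <- diet_matrix(dc, roles)
      groups <- group_params(code = codes, role = roles, B = B, PB = PB,
                             QB = QB, EE = EE, catch = catch)
      return(list(diet = diet, groups = groups))
    }
  }
  stop("resampling budget exhausted without a balanced web", call. = FALSE)
}

#' Scenario configuration for the synthetic catch generator
#'
#' Defaults mirror the study system's timeline and structure: a 2000-2016
#' span with the refrigerated-brine fleet and the expanded fishing region
#' appearing in 2008, an ice-fleet original region off southern Brazil and
#' a northern expansion region with a distinct species pool (different mean
#' trophic level), lognormal catch noise, and record counts small enough
#' for fast tests.
#'
#' @param seed Integer seed.
#' @param years Year span, default `2000:2016`.
#' @param expansion_year First year of the expanded region and of the VRB
#'   fleet, default 2008.
#' @param n_trips Records per fleet-region-year, default 60.
#' @param region1_pool,region2_pool Named TL vectors for the two regional
#'   species pools.
#' @param region1_mean_catch,region2_mean_catch Mean catch per record (t).
#' @param sdlog Lognormal log-sd of catch noise, default 0.6.
#' @param region1_box,region2_box Lat/lon boxes `c(lat_min, lat_max,
#'   lon_min, lon_max)` (degrees, south/west negative).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L, years = 2000:2016,
                            expansion_year = 2008L, n_trips = 60L,
                            region1_pool = c(SV = 2.77, SL = 2.61, PA = 2.49,
                                             CA = 2.99, TA = 2.00, CO = 3.11),
                            region2_pool = c(SV = 2.77, XI = 2.77, GA = 3.28,
                                             GU = 3.28, ES = 3.21, BL = 3.24),
                            region1_mean_catch = 20,
                            region2_mean_catch = 30,
                            sdlog = 0.6,
                            region1_box = c(-28.6, -23.5, -49, -44),
                            region2_box = c(-23.5, -21, -43, -40)) {
  if (!expansion_year %in% years) {
    stop("expansion year must lie within the span", call. = FALSE)
  }
  if (sdlog < 0) stop("noise sd must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "scenario_config")
}

sample_records <- function(n, year, fleet, pool, mean_catch, sdlog, box) {
  sp <- sample(names(pool), n, replace = TRUE)
  ds <- sample(3:12, n, replace = TRUE)
  data.frame(
    year = year, month = sample.int(12L, n, replace = TRUE), fleet = fleet,
    species_code = sp,
    lat = stats::runif(n, box[1], box[2]),
    lon = stats::runif(n, box[3], box[4]),
    depth_m = stats::runif(n, 20, 110),
    catch_t = stats::rlnorm(n, log(mean_catch) - sdlog^2 / 2, sdlog),
    days_at_sea = ds,
    fishing_days = pmax(1L, ds - sample.int(3L, n, replace = TRUE)),
    hauls = sample(1:8, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic two-region, two-fleet catch series
#'
#' Emulates the structure of a purse-seine landing series under fleet
#' expansion: the ice fleet (VIC) fishes the original region over the whole
#' span; from the expansion year onwards a refrigerated-brine fleet (VRB)
#' appears and both fleets also fish an expanded region carrying a distinct
#' species pool with a different mean trophic level. Catches are lognormal
#' around the configured means; coordinates are drawn inside the region
#' boxes so quadrant gridding and biomass-density estimation are exercised.
#'
#' @param config A [scenario_config()].
#' @return Data frame of landing records (columns of the catch CSV dialect,
#'   plus a `region` column).
#' @export
generate_catch_series <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  out <- list()
  for (y in config$years) {
    out[[length(out) + 1L]] <- cbind(
      sample_records(config$n_trips, y, "VIC", config$region1_pool,
                     config$region1_mean_catch, config$sdlog,
                     config$region1_box),
      region = 1L)
    if (y >= config$expansion_year) {
      out[[length(out) + 1L]] <- cbind(
        sample_records(config$n_trips, y, "VIC", config$region2_pool,
                       config$region2_mean_catch, config$sdlog,
                       config$region2_box),
        region = 2L)
      out[[length(out) + 1L]] <- cbind(
        sample_records(config$n_trips, y, "VRB", config$region2_pool,
                       config$region2_mean_catch, config$sdlog,
                       config$region2_box),
        region = 2L)
    }
  }
  do.call(rbind, out)
}

#' Noise-free expansion series with a known expanded-region MTL
#'
#' Constructs a yearly (catch, MTL) series that satisfies the two
#' assumptions of the region-based decomposition exactly: before the
#' breakpoint the whole catch belongs to the initial region; after it, the
#' total MTL of each year is solved (by root finding) so that the balanced
#' initial-region estimates plus an expanded region of constant, configured
#' MTL reproduce the totals. Running [rmtl_decompose()] on the result
#' recovers `mtl2` up to root-finding tolerance.
#'
#' The expanded-region MTL must exceed the initial-region MTL: a balanced
#' initial region expects its catch to grow as the total MTL falls, so a
#' positive expanded-region residual requires the expansion to add
#' higher-trophic-level catch (the pattern observed when a fleet reaches
#' new grounds).
#'
#' @param mtl2 Target expanded-region MTL (> `mtl1`).
#' @param years Year span, default `2000:2016`.
#' @param breakpoint Last initial-region year, default 2007.
#' @param Y0 Catch at the breakpoint year, default 100.
#' @param mtl1 Initial-region MTL at the breakpoint, default 3.0.
#' @param jump Multiplicative catch jump in the first expansion year,
#'   default 3 (the new grounds add a block of catch at once; a nontrivial
#'   split only exists when `mtl2` exceeds the balanced-region MTL estimate
#'   by more than `1/ln(10)` in `log10(1/TE)` units, which requires a
#'   sufficiently large catch increase).
#' @param growth Yearly multiplicative catch growth after the first
#'   expansion year, default 1.2.
#' @param TE Transfer efficiency, default 0.1.
#' @return Data frame `(year, Y, MTL)`.
#' @export
make_expansion_series <- function(mtl2 = 3.2, years = 2000:2016,
                                  breakpoint = 2007, Y0 = 100, mtl1 = 3.0,
                                  jump = 3, growth = 1.2, TE = 0.1) {
  stopifnot(breakpoint %in% years, mtl2 > mtl1, growth > 1, jump > 1)
  lg <- log10(1 / TE)
  Y <- numeric(length(years))
  MTL <- numeric(length(years))
  for (k in seq_along(years)) {
    if (years[k] <= breakpoint) {
      Y[k] <- Y0 * growth^((years[k] - breakpoint) / 4)
      MTL[k] <- mtl1
    } else {
      Y[k] <- Y0 * jump * growth^(years[k] - breakpoint - 1)
      m1k <- mtl1 - log10(Y[k] / Y0) / lg
      if (mtl2 - m1k <= 1 / log(10) / lg + 1e-9) {
        stop("infeasible construction: increase jump or mtl2", call. = FALSE)
      }
      # total MTL m solving the mass-weighted identity with region-2 fixed
      # at mtl2; the balanced-region catch y1(m) = Y0 (1/TE)^(mtl1 - m)
      # decreases in m, and the nontrivial root lies in (m1k, mtl2)
      y1f <- function(m) Y0 * (1 / TE)^(mtl1 - m)
      f <- function(m) (m - mtl2) * Y[k] + (mtl2 - m1k) * y1f(m)
      m <- stats::uniroot(f, c(m1k + 1e-6, mtl2), tol = 1e-12)$root
      fp <- function(m) Y[k] - (mtl2 - m1k) * log(1 / TE) * y1f(m)
      for (it in 1:3) m <- m - f(m) / fp(m)      # polish to machine precision
      MTL[k] <- m
    }
  }
  data.frame(year = years, Y = Y, MTL = MTL)
}

#' Load a packaged parameter table
#'
#' Typed copies of the study-system tables that ship with the package:
#' `"table1_tl"` (species trophic-level catalogue, returned as a
#' [tl_table()] keyed by species with the full data frame in attribute
#' `"table"`), `"table2_original"` / `"table2_expanded"` (functional-group
#' parameter tables, data frames), and `"sardine_diet"` (named diet
#' fractions with prey trophic levels in attribute `"prey_tl"`).
#'
#' @param name Fixture name.
#' @return See description.
#' @export
load_fixture <- function(name) {
  known <- c("table1_tl", "table2_original", "table2_expanded",
             "sardine_diet")
  if (!name %in% known) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "fishweb",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  switch(name,
    table1_tl = {
      out <- tl_table(stats::setNames(df$tl, df$species))
      attr(out, "table") <- df
      out
    },
    sardine_diet = {
      out <- stats::setNames(df$fraction, df$item)
      attr(out, "prey_tl") <- stats::setNames(df$prey_tl, df$item)
      attr(out, "codes") <- stats::setNames(df$code, df$item)
      out
    },
    df)
}
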