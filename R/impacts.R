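#' Direct trophic impact matrix
#'
#' Entry `q[i, j]` is the direct impact of an increase in group `j` on
#' group `i`: the fraction of `i`'s diet supplied by `j` (a positive,
#' bottom-up food-supply effect) minus the share of total predation and
#' removal on `i` exerted by `j` (a negative, top-down effect). Predation
#' shares are flow-weighted, `B_j QB_j DC[i, j]` over the total predation
#' on `i`. With `include_fleets = TRUE` each fishing fleet is appended as
#' an extra "predator" whose removals enter the denominator and whose
#' "diet" is its catch composition.
#'
#' @param model A `balanced_model`.
#' @param fleet_catches Optional named list of per-fleet catch vectors
#'   (t/km^2/yr, named by group code) used when `include_fleets = TRUE`.
#' @param include_fleets Append fleet rows/columns, default `FALSE`.
#' @return Square matrix `q` with entries in `[-1, 1]`, impacted groups in
#'   rows and impacting groups in columns.
#' @export
direct_impacts <- function(model, fleet_catches = NULL,
                           include_fleets = FALSE) {
  stopifnot(inherits(model, "balanced_model"))
  g <- model$groups
  dc <- model$diet$dc
  n <- nrow(g)
  cons_flow <- ifelse(is.na(g$QB), 0, g$B * g$QB)
  # predation flow on prey i by predator j
  flow <- sweep(dc, 2, cons_flow, `*`)

  fleets <- character(0)
  fmat <- NULL
  if (include_fleets) {
    if (is.null(fleet_catches)) {
      fleet_catches <- list(fleet = stats::setNames(g$catch, g$code))
    }
    fleets <- names(fleet_catches)
    fmat <- vapply(fleet_catches, function(y) {
      v <- stats::setNames(numeric(n), g$code)
      v[names(y)] <- y
      v
    }, numeric(n))
  }

  tot_removal <- rowSums(flow)
  if (include_fleets) tot_removal <- tot_removal + rowSums(fmat)

  m <- n + length(fleets)
  q <- matrix(0, m, m)
  codes <- c(g$code, fleets)
  dimnames(q) <- list(codes, codes)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dc_ij <- dc[j, i] +                       # share of i's diet from j
        0
      fc_ji <- if (tot_removal[i] > 0) flow[i, j] / tot_removal[i] else 0
      q[i, j] <- dc_ij - fc_ji
    }
  }
  if (include_fleets) {
    for (f in seq_along(fleets)) {
      col <- n + f
      tot_f <- sum(fmat[, f])
      for (i in seq_len(n)) {
        # fleet as impacting "predator" of i
        q[i, col] <- -(if (tot_removal[i] > 0) fmat[i, f] / tot_removal[i]
                       else 0)
        # fleet as impacted "consumer": its diet is its catch composition
        q[col, i] <- if (tot_f > 0) fmat[i, f] / tot_f else 0
      }
    }
  }
  q
}

#' Mixed (direct + indirect) trophic impacts
#'
#' Propagates the direct impact matrix over all interaction paths:
#' `m = (I - q)^-1 - I`, the Leontief-inverse closed form of the Neumann
#' series `q + q^2 + q^3 + ...`, valid when the spectral radius of `q` is
#' below 1. If the series diverges but `I - q` is invertible, a truncated
#' series is returned with a warning; a singular `I - q` is an error.
#'
#' @param q Direct impact matrix from [direct_impacts()].
#' @param max_order Truncation order used in the divergent fallback,
#'   default 50.
#' @return Total impact matrix `m` (same dimnames as `q`).
#' @export
mixed_trophic_impacts <- function(q, max_order = 50L) {
  q <- as.matrix(q)
  stopifnot(nrow(q) == ncol(q))
  sr <- max(Mod(eigen(q, only.values = TRUE)$values), 0)
  eye <- diag(nrow(q))
  if (sr < 1 - 1e-10) {
    inv <- tryCatch(solve(eye - q), error = function(e) {
      stop("non-convergent impact propagation", call. = FALSE)
    })
    m <- inv - eye
  } else {
    warning(sprintf(
      "impact propagation truncated at order %d (spectral radius %.3f >= 1)",
      max_order, sr))
    m <- matrix(0, nrow(q), ncol(q))
    term <- eye
    for (k in seq_len(max_order)) {
      term <- term %*% q
      m <- m + term
    }
  }
  dimnames(m) <- dimnames(q)
  m
}

#' Overall trophic effect exerted by each group
#'
#' Root-sum-square of the off-diagonal total impacts a group exerts on the
#' rest of the web (column of the mixed impact matrix, self-impact
#' excluded).
#'
#' @param m Total impact matrix from [mixed_trophic_impacts()].
#' @return Named numeric vector of overall effects, one per group.
#' @export
overall_effect <- function(m) {
  m <- as.matrix(m)
  eps <- vapply(seq_len(ncol(m)), function(j) {
    sqrt(sum(m[-j, j]^2))
  }, numeric(1))
  stats::setNames(eps, colnames(m))
}

#' Keystone classification from impact and biomass
#'
#' Places every group on a scatter of `x = log10(biomass)` against
#' `y = log10(overall effect squared)` and partitions it with data-driven
#' splits: the medians of each axis, surrounded by an "intermediate" band
#' of half an interquartile range (median +/- IQR/4). Keystone groups are
#' those with high impact and low biomass; the remaining quadrants are
#' low-impact--low-biomass, low-impact--high-biomass and
#' high-impact--high-biomass; groups inside a band on either axis are
#' intermediate.
#'
#' @param m Total impact matrix.
#' @param biomass Named numeric vector of biomasses (same codes as `m`);
#'   groups with zero or missing biomass are excluded with a warning.
#' @param x_split,y_split Optional fixed split points overriding the
#'   medians.
#' @param band_frac Half-width of the intermediate band as a fraction of
#'   each axis IQR, default 0.25.
#' @return Data frame `(code, logB, logEps2, category)` of class
#'   `keystone_result`.
#' @export
keystone_classify <- function(m, biomass, x_split = NULL, y_split = NULL,
                              band_frac = 0.25) {
  m <- as.matrix(m)
  codes <- colnames(m)
  if (is.null(codes)) codes <- paste0("G", seq_len(ncol(m)))
  biomass <- biomass[codes]
  if (length(biomass) != ncol(m) || anyNA(match(codes, names(biomass)))) {
    stop("biomass must be named and cover all groups", call. = FALSE)
  }
  eps <- overall_effect(m)
  drop <- is.na(biomass) | biomass <= 0
  if (any(drop)) {
    warning(sprintf("%d group(s) with zero or missing biomass excluded",
                    sum(drop)))
  }
  keep <- which(!drop)
  if (length(keep) < 4L) stop("need at least 4 groups", call. = FALSE)
  x <- log10(biomass[keep])
  y <- log10(eps[keep]^2)        # -Inf when a group exerts no impact
  y_fin <- y[is.finite(y)]
  mx <- if (is.null(x_split)) stats::median(x) else x_split
  my <- if (is.null(y_split)) stats::median(y_fin) else y_split
  bx <- band_frac * stats::IQR(x)
  by <- band_frac * (if (length(y_fin) > 1) stats::IQR(y_fin) else 0)
  category <- character(length(keep))
  for (k in seq_along(keep)) {
    if (abs(x[k] - mx) <= bx || (is.finite(y[k]) && abs(y[k] - my) <= by)) {
      category[k] <- "intermediate"
    } else if (y[k] > my && x[k] < mx) {
      category[k] <- "keystone"
    } else if (y[k] > my && x[k] >= mx) {
      category[k] <- "high-impact-high-biomass"
    } else if (x[k] >= mx) {
      category[k] <- "low-impact-high-biomass"
    } else {
      category[k] <- "low-impact-low-biomass"
    }
  }
  structure(data.frame(code = codes[keep], logB = as.numeric(x),
                       logEps2 = as.numeric(y), category = category,
                       row.names = NULL),
            class = c("keystone_result", "data.frame"))
}
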