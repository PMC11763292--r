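#' von Bertalanffy length at age
#'
#' `L_t = Linf * (1 - exp(-K * (t - t0)))`: monotone increasing in age with
#' asymptote `Linf`. Negative ages are allowed and may yield negative
#' lengths; interpreting those is the caller's concern.
#'
#' @param t Age in years (vectorized).
#' @param Linf Asymptotic length (cm), > 0.
#' @param K Growth coefficient (1/yr), > 0.
#' @param t0 Nominal age at zero length (yr), default 0.
#' @return Length (cm).
#' @export
vbgf_length <- function(t, Linf, K, t0 = 0) {
  if (Linf <= 0 || K <= 0) stop("Linf and K must be positive", call. = FALSE)
  Linf * (1 - exp(-K * (t - t0)))
}

#' Pauly empirical natural mortality
#'
#' `log10 M = 0.654 log10 K - 0.279 log10 Linf + 0.463 log10 T`, the
#' classic growth-and-temperature regression for fish natural mortality.
#'
#' @param K Growth coefficient (1/yr).
#' @param Linf Asymptotic length (cm).
#' @param T_C Mean annual water temperature (degrees Celsius).
#' @return Natural mortality M (1/yr).
#' @examples
#' pauly_M(K = 0.5, Linf = 30, T_C = 23.4)
#' @export
pauly_M <- function(K, Linf, T_C) {
  if (any(c(K, Linf, T_C) <= 0)) {
    stop("K, Linf and T_C must all be positive", call. = FALSE)
  }
  10^(0.654 * log10(K) - 0.279 * log10(Linf) + 0.463 * log10(T_C))
}

#' Hoenig longevity-based total mortality
#'
#' `Z = exp(a + b * ln(Tm))` with taxon-specific regression coefficients:
#' `a = 1.46, b = -1.01` for fish and `a = 1.23, b = -0.832` for mollusks.
#' Z decreases with longevity.
#'
#' @param Tm Observed longevity (yr), > 0.
#' @param taxon `"fish"` or `"mollusk"`.
#' @return Total mortality Z (1/yr).
#' @export
hoenig_Z <- function(Tm, taxon = c("fish", "mollusk")) {
  taxon <- match.arg(taxon)
  if (any(Tm <= 0)) stop("longevity must be positive", call. = FALSE)
  ab <- switch(taxon, fish = c(1.46, -1.01), mollusk = c(1.23, -0.832))
  exp(ab[1] + ab[2] * log(Tm))
}

#' Caudal-fin aspect ratio
#'
#' `Ar = h^2 / S` from fin height `h` (mm) and fin surface area `S` (mm^2).
#'
#' @param h Fin height (mm).
#' @param S Fin surface area (mm^2).
#' @return Dimensionless aspect ratio.
#' @export
aspect_ratio <- function(h, S) {
  if (any(h <= 0) || any(S <= 0)) {
    stop("fin height and surface must be positive", call. = FALSE)
  }
  h^2 / S
}

#' Palomares-Pauly empirical consumption rate
#'
#' `log10 Q/B = 7.964 - 0.204 log10 Winf - 1.965 T' + 0.083 Ar + 0.532 H +
#' 0.398 D` with `T' = 1000 / (T_C + 273.15)` the inverse absolute
#' temperature. `H = 1` for herbivores, `D = 1` for detritivores and
#' iliophages; carnivores have `H = D = 0`.
#'
#' @param Winf Asymptotic weight (g wet weight), > 0.
#' @param T_C Mean water temperature (degrees Celsius), default 23.4 (the
#'   study-system mean; the bracketed constant of the published formula).
#' @param Ar Caudal-fin aspect ratio; alternatively supply `h` and `S`.
#' @param H Herbivory flag (0/1).
#' @param D Detritivory flag (0/1).
#' @param h,S Optional fin height (mm) and surface (mm^2); if both `Ar` and
#'   `(h, S)` are given they must agree within 1%.
#' @return Consumption per biomass Q/B (1/yr).
#' @export
palomares_QB <- function(Winf, T_C = 23.4, Ar = NULL, H = 0, D = 0,
                         h = NULL, S = NULL) {
  if (any(Winf <= 0)) stop("Winf must be positive", call. = FALSE)
  if (!all(H %in% c(0, 1)) || !all(D %in% c(0, 1))) {
    stop("H and D must be 0 or 1", call. = FALSE)
  }
  if (any(H == 1 & D == 1)) {
    stop("H and D cannot both be 1 for the same species", call. = FALSE)
  }
  if (!is.null(h) && !is.null(S)) {
    ar_hs <- aspect_ratio(h, S)
    if (!is.null(Ar)) {
      if (any(abs(Ar - ar_hs) > 0.01 * abs(Ar))) {
        stop("supplied Ar disagrees with h^2/S by more than 1%",
             call. = FALSE)
      }
    } else {
      Ar <- ar_hs
    }
  }
  if (is.null(Ar)) stop("supply Ar or both h and S", call. = FALSE)
  Tprime <- 1000 / (T_C + 273.15)
  10^(7.964 - 0.204 * log10(Winf) - 1.965 * Tprime + 0.083 * Ar +
        0.532 * H + 0.398 * D)
}

#' Production per biomass from total mortality
#'
#' Under equilibrium, production per biomass equals total mortality
#' `Z = M + F`. When natural mortality `M` is supplied, fishing mortality
#' `F = Z - M` is also returned, clamped at zero (and flagged) if `M > Z`.
#'
#' @param Z Total mortality (1/yr), >= 0.
#' @param M Optional natural mortality (1/yr).
#' @return List with `PB` (= Z), and when `M` is given also `F` and
#'   `flag` (`"M_exceeds_Z"` or `""`).
#' @export
pb_from_Z <- function(Z, M = NULL) {
  if (any(Z < 0)) stop("Z must be non-negative", call. = FALSE)
  out <- list(PB = Z)
  if (!is.null(M)) {
    out$F <- pmax(Z - M, 0)
    out$flag <- ifelse(M > Z, "M_exceeds_Z", "")
  }
  out
}
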