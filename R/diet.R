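#' Normalize a diet column to fractions
#'
#' Converts raw, non-negative diet weights (percentages, counts, pooled
#' scores) into fractions that sum to one, preserving proportions. This is
#' the normalization step applied to every literature diet record before it
#' enters the diet-composition matrix.
#'
#' @param weights Named numeric vector of non-negative weights, one entry
#'   per food item. At least one weight must be positive.
#' @return Named numeric vector of the same length summing to 1.
#' @examples
#' normalize_diet(c(zooplankton = 70.3, phytoplankton = 29.7))
#' @export
normalize_diet <- function(weights) {
  if (length(weights) == 0L || !is.numeric(weights)) {
    stop("empty diet", call. = FALSE)
  }
  if (anyNA(weights) || any(weights < 0)) {
    stop("diet weights must be non-negative and non-missing", call. = FALSE)
  }
  tot <- sum(weights)
  if (tot <= 0) stop("empty diet", call. = FALSE)
  weights / tot
}

#' Pool several diet studies into a single composition
#'
#' Multiple published diet determinations for the same predator are pooled
#' into one column by a (weighted) mean over the union of food items, then
#' renormalized. Items missing from a study are treated as zero.
#'
#' @param studies List of named numeric vectors, one per study; each is
#'   normalized internally before pooling.
#' @param weights Optional numeric vector of per-study weights (e.g. sample
#'   sizes). Defaults to equal weights.
#' @return Named numeric vector over the union of items, summing to 1.
#' @examples
#' pool_diets(list(c(a = 1), c(b = 1)))
#' @export
pool_diets <- function(studies, weights = NULL) {
  if (!is.list(studies) || length(studies) == 0L) {
    stop("need at least one diet study", call. = FALSE)
  }
  studies <- lapply(studies, normalize_diet)
  items <- unique(unlist(lapply(studies, names)))
  if (is.null(items) || any(!nzchar(items))) {
    stop("diet studies must have named items", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(studies))
  if (length(weights) != length(studies) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("invalid study weights", call. = FALSE)
  }
  acc <- stats::setNames(numeric(length(items)), items)
  for (s in seq_along(studies)) {
    col <- studies[[s]]
    acc[names(col)] <- acc[names(col)] + weights[s] * col
  }
  normalize_diet(acc)
}

#' Construct a diet-composition matrix
#'
#' The diet matrix `DC` is indexed `[prey, predator]`: column `j` holds the
#' fractions of each prey in the diet of predator `j`. Consumer columns must
#' sum to one (including any import fraction, i.e. diet taken from outside
#' the modelled system); producer and detritus columns are all zero.
#'
#' @param dc Numeric matrix `[prey, predator]` with identical row and column
#'   codes; entries in `[0, 1]`.
#' @param roles Character vector (one per group) in
#'   `c("producer", "consumer", "detritus")`.
#' @param import Optional numeric vector of import fractions per predator
#'   (default 0).
#' @param tol Column-sum tolerance, default `1e-6`.
#' @return Object of class `diet_matrix`: list with elements `dc`, `roles`,
#'   `import`, `codes`.
#' @export
diet_matrix <- function(dc, roles, import = NULL, tol = 1e-6) {
  dc <- as.matrix(dc)
  n <- nrow(dc)
  if (ncol(dc) != n) stop("diet matrix must be square", call. = FALSE)
  codes <- rownames(dc)
  if (is.null(codes)) {
    codes <- colnames(dc)
    if (is.null(codes)) codes <- paste0("G", seq_len(n))
    dimnames(dc) <- list(codes, codes)
  }
  if (anyDuplicated(codes)) stop("group codes must be unique", call. = FALSE)
  if (is.null(colnames(dc))) colnames(dc) <- codes
  if (!identical(rownames(dc), colnames(dc))) {
    stop("row and column codes must match", call. = FALSE)
  }
  roles <- match.arg(roles, c("producer", "consumer", "detritus"),
                     several.ok = TRUE)
  if (length(roles) != n) stop("one role per group required", call. = FALSE)
  names(roles) <- codes
  if (is.null(import)) import <- stats::setNames(numeric(n), codes)
  if (length(import) != n) stop("one import fraction per group", call. = FALSE)
  names(import) <- codes
  if (anyNA(dc) || any(dc < -tol) || any(dc > 1 + tol)) {
    stop("diet fractions must lie in [0, 1]", call. = FALSE)
  }
  for (j in seq_len(n)) {
    s <- sum(dc[, j]) + import[j]
    if (roles[j] == "consumer") {
      if (abs(s - 1) > tol) {
        stop(sprintf("diet column '%s' sums to %.8f, not 1", codes[j], s),
             call. = FALSE)
      }
    } else if (s > tol) {
      stop(sprintf("non-consumer column '%s' must be all zero", codes[j]),
           call. = FALSE)
    }
  }
  structure(list(dc = dc, roles = roles, import = import, codes = codes),
            class = "diet_matrix")
}

#' @export
print.diet_matrix <- function(x, ...) {
  cat("diet_matrix:", length(x$codes), "groups (",
      sum(x$roles == "consumer"), "consumers,",
      sum(x$roles == "producer"), "producers,",
      sum(x$roles == "detritus"), "detritus )\n")
  invisible(x)
}

#' Trophic-level table
#'
#' A catalogue mapping species/group codes to trophic levels. Every trophic
#' level is at least 1 (primary producers and detritus) and codes are
#' unique.
#'
#' @param values Named numeric vector of trophic levels.
#' @return Named numeric vector of class `tl_table`.
#' @export
tl_table <- function(values) {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("trophic levels must be named by species code", call. = FALSE)
  }
  if (anyDuplicated(names(values))) {
    stop("species codes must be unique", call. = FALSE)
  }
  if (anyNA(values) || any(values < 1)) {
    stop("every trophic level must be >= 1", call. = FALSE)
  }
  structure(as.numeric(stats::setNames(values, names(values))),
            names = names(values), class = c("tl_table", "numeric"))
}

#' Trophic levels from a diet matrix
#'
#' Solves the linear fixed point `TL_i = 1 + sum_j DC[j, i] * TL_j` for all
#' consumers simultaneously; producers and detritus are fixed at trophic
#' level 1 and imported diet is assigned trophic level 1 (its trophic
#' history is untracked). The linear solve is exact for webs with cycles
#' (mutual predation, cannibalism) provided the consumer-only diet
#' sub-matrix has spectral radius below 1.
#'
#' @param diet A [diet_matrix()].
#' @return A [tl_table()] over all groups.
#' @export
compute_trophic_levels <- function(diet) {
  stopifnot(inherits(diet, "diet_matrix"))
  codes <- diet$codes
  cons <- which(diet$roles == "consumer")
  tl <- stats::setNames(rep(1, length(codes)), codes)
  if (length(cons) > 0L) {
    # TL_c = b_c + sum_{c'} A[c, c'] TL_{c'} over consumers only
    A <- t(diet$dc[cons, cons, drop = FALSE])
    if (length(cons) > 0L) {
      sr <- max(Mod(eigen(A, only.values = TRUE)$values), 0)
      if (sr >= 1 - 1e-12) stop("degenerate diet cycle", call. = FALSE)
    }
    fixed <- setdiff(seq_along(codes), cons)
    b <- 1 + colSums(diet$dc[fixed, cons, drop = FALSE]) + diet$import[cons]
    tl[cons] <- solve(diag(length(cons)) - A, b)
  }
  tl_table(tl)
}

#' One-step trophic level from a diet column
#'
#' Evaluates `1 + sum(fractions * prey_tl)` for a single predator whose prey
#' trophic levels are already known, as when working directly from a
#' published parameter table.
#'
#' @param fractions Named or unnamed diet fractions (renormalized if needed).
#' @param prey_tl Trophic level of each prey, same order/length.
#' @return Scalar trophic level.
#' @examples
#' tl_from_diet(c(0.703, 0.297), c(2.05, 1.00))
#' @export
tl_from_diet <- function(fractions, prey_tl) {
  fractions <- normalize_diet(fractions)
  if (length(prey_tl) != length(fractions)) {
    stop("one prey trophic level per diet fraction", call. = FALSE)
  }
  1 + sum(fractions * prey_tl)
}
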