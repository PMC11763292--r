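#' Functional-group parameter table
#'
#' Builds and validates the per-group input table of the static mass-balance
#' model. `NA` marks the unknown to be solved; at most one of `B`, `PB`,
#' `EE` may be unknown per non-detritus group. Detritus groups carry no
#' production equation: their `B` must be known, and any supplied detritus
#' `PB` is ignored with a warning (its turnover is driven by inflows).
#'
#' @param code Character vector of unique group codes.
#' @param role One of `"producer"`, `"consumer"`, `"detritus"` per group.
#' @param B Biomass (t/km^2); `NA` = unknown.
#' @param PB Production per biomass (1/yr); `NA` = unknown; `NA` required
#'   for detritus.
#' @param QB Consumption per biomass (1/yr); consumers only (> 0), `NA`
#'   otherwise.
#' @param EE Ecotrophic efficiency in `[0, 1]`; `NA` = unknown.
#' @param catch Fishery removals Y (t/km^2/yr), default 0.
#' @param export Other exports EX (t/km^2/yr), default 0.
#' @param name Optional long names, defaults to `code`.
#' @return Data frame of class `group_params`.
#' @export
group_params <- function(code, role, B = NA_real_, PB = NA_real_,
                         QB = NA_real_, EE = NA_real_, catch = 0,
                         export = 0, name = code) {
  n <- length(code)
  if (anyDuplicated(code)) stop("group codes must be unique", call. = FALSE)
  role <- match.arg(role, c("producer", "consumer", "detritus"),
                    several.ok = TRUE)
  g <- data.frame(code = as.character(code), name = as.character(name),
                  role = rep_len(role, n),
                  B = rep_len(as.numeric(B), n),
                  PB = rep_len(as.numeric(PB), n),
                  QB = rep_len(as.numeric(QB), n),
                  EE = rep_len(as.numeric(EE), n),
                  catch = rep_len(as.numeric(catch), n),
                  export = rep_len(as.numeric(export), n),
                  stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    for (col in c("B", "PB", "QB", "EE", "catch", "export")) {
      v <- g[[col]][i]
      if (!is.na(v) && v < 0) {
        stop(sprintf("group '%s': %s must be non-negative", g$code[i], col),
             call. = FALSE)
      }
    }
    if (!is.na(g$EE[i]) && g$EE[i] > 1) {
      stop(sprintf("group '%s': known EE must lie in [0, 1]", g$code[i]),
           call. = FALSE)
    }
    if (g$role[i] == "consumer") {
      if (is.na(g$QB[i]) || g$QB[i] <= 0) {
        stop(sprintf("consumer '%s' needs QB > 0", g$code[i]), call. = FALSE)
      }
    } else if (!is.na(g$QB[i])) {
      stop(sprintf("non-consumer '%s' must not have QB", g$code[i]),
           call. = FALSE)
    }
    if (g$role[i] == "detritus") {
      if (is.na(g$B[i])) {
        stop(sprintf("detritus '%s' needs a known biomass", g$code[i]),
             call. = FALSE)
      }
      if (!is.na(g$PB[i])) {
        warning(sprintf(
          "detritus '%s': supplied PB ignored (detritus balance is computed from inflows)",
          g$code[i]))
        g$PB[i] <- NA_real_
      }
    } else {
      unknown <- is.na(c(g$B[i], g$PB[i], g$EE[i]))
      if (sum(unknown) > 1L) {
        stop(sprintf("group '%s': more than one of B, PB, EE is unknown",
                     g$code[i]), call. = FALSE)
      }
    }
  }
  class(g) <- c("group_params", "data.frame")
  g
}

#' Solve the static mass balance of a food web
#'
#' For every non-detritus group `i` the production balance
#' `B_i PB_i EE_i - sum_j B_j QB_j DC[i, j] - Y_i - EX_i = 0`
#' must hold: production used within the system (ecotrophic efficiency
#' `EE_i`) equals predation by all consumers plus fishery catches and other
#' exports. Each group may leave exactly one of `B`, `PB`, `EE` unknown;
#' because only one unknown enters each product, the whole system is linear
#' in the unknown vector and is assembled and solved simultaneously (groups
#' whose unknown `EE` depends on an unknown predator biomass are thereby
#' handled without iteration). Groups whose solved `EE` falls outside
#' `[0, 1]` are flagged `"unbalanced"` but returned.
#'
#' @param groups A [group_params()] table.
#' @param diet A [diet_matrix()] over the same codes (same order).
#' @param unassimilated Fraction of consumption egested to detritus,
#'   default 0.2.
#' @param tol Residual tolerance for the post-solve check, default `1e-9`
#'   relative to `max(1, B PB)`.
#' @return Object of class `balanced_model`: list with `groups` (inputs with
#'   unknowns filled in and derived columns `TL`, `M2`, `F`, `PQ`, `OI`,
#'   `flow_detritus`, `net_efficiency`, `FZ`, `prop_M`, `residual`, `flag`),
#'   the `diet`, and `unassimilated`.
#' @export
solve_balance <- function(groups, diet, unassimilated = 0.2, tol = 1e-9) {
  stopifnot(inherits(diet, "diet_matrix"))
  if (!identical(groups$code, diet$codes)) {
    stop("group codes must match the diet matrix (same order)",
         call. = FALSE)
  }
  if (!identical(unname(as.character(groups$role)), unname(diet$roles))) {
    stop("group roles must match the diet matrix", call. = FALSE)
  }
  g <- as.data.frame(groups)
  n <- nrow(g)
  dc <- diet$dc
  eaten <- rowSums(sweep(dc, 2, ifelse(is.na(g$QB), 0, 1), `*`)) > 0

  det <- g$role == "detritus"
  unk_col <- rep(NA_character_, n)
  for (i in which(!det)) {
    miss <- c("B", "PB", "EE")[is.na(c(g$B[i], g$PB[i], g$EE[i]))]
    if (length(miss) == 1L) unk_col[i] <- miss
  }
  # structural check: an unknown biomass only appears with nonzero
  # coefficients if the group produces into the system or is preyed upon
  for (i in which(unk_col == "B")) {
    if (!eaten[i] && g$catch[i] + g$export[i] <= 0) {
      stop(sprintf(
        "cannot solve B for group '%s': nobody eats it and it has no catch",
        g$code[i]), call. = FALSE)
    }
  }

  # one equation per unknown: the solved groups' own balance equations,
  # paired row r <-> unknown of group unk[r] (the standard Ecopath pairing)
  unk <- which(!is.na(unk_col))
  x_of <- match(seq_len(n), unk)           # group -> unknown index or NA
  if (length(unk) > 0L) {
    A <- matrix(0, length(unk), length(unk))
    b <- numeric(length(unk))
    for (r in seq_along(unk)) {
      i <- unk[r]
      # production term B_i PB_i EE_i
      prod_terms <- c(B = g$B[i], PB = g$PB[i], EE = g$EE[i])
      coef <- prod(prod_terms[setdiff(names(prod_terms), unk_col[i])])
      A[r, x_of[i]] <- A[r, x_of[i]] + coef
      # predation terms -B_j QB_j DC[i, j]
      for (j in seq_len(n)) {
        if (is.na(g$QB[j]) || dc[i, j] == 0) next
        if (!is.na(unk_col[j]) && unk_col[j] == "B") {
          A[r, x_of[j]] <- A[r, x_of[j]] - g$QB[j] * dc[i, j]
        } else {
          b[r] <- b[r] + g$B[j] * g$QB[j] * dc[i, j]
        }
      }
      b[r] <- b[r] + g$catch[i] + g$export[i]
    }
    sol <- tryCatch(solve(A, b), error = function(e) {
      stop("structurally unsolvable mass-balance system", call. = FALSE)
    })
    for (k in seq_along(unk)) {
      i <- unk[k]
      g[[unk_col[i]]][i] <- sol[k]
    }
  }

  flag <- rep("", n)
  bad_ee <- !det & (g$EE < -1e-12 | g$EE > 1 + 1e-12)
  flag[bad_ee] <- "unbalanced"

  # residuals of the balance equation (diagnostic for fully-specified rows)
  pred_on <- as.numeric(dc %*% ifelse(is.na(g$QB), 0, g$B * g$QB))
  residual <- ifelse(det, 0,
                     g$B * g$PB * g$EE - pred_on - g$catch - g$export)
  over <- !det & abs(residual) > tol * pmax(1, abs(g$B * g$PB)) &
    is.na(x_of)
  flag[over] <- trimws(paste(flag[over], "residual_above_tol"))

  g$TL <- as.numeric(compute_trophic_levels(diet))
  g$M2 <- predation_mortality(g, diet)
  g$F <- ifelse(g$B > 0, g$catch / g$B, NA_real_)
  g$PQ <- ifelse(!is.na(g$QB) & g$QB > 0, g$PB / g$QB, NA_real_)
  g$OI <- omnivory_index(diet, g$TL)
  g$residual <- residual
  g$flag <- flag

  model <- structure(list(groups = g, diet = diet,
                          unassimilated = unassimilated),
                     class = "balanced_model")
  fl <- flows(model)
  model$groups <- cbind(g, fl[, c("flow_detritus", "net_efficiency",
                                  "FZ", "prop_M")])
  # detritus EE: share of detrital inflow consumed or exported
  for (i in which(det)) {
    inflow <- sum(fl$flow_detritus, na.rm = TRUE)
    removal <- pred_on[i] + g$catch[i] + g$export[i]
    model$groups$EE[i] <- if (inflow > 0) removal / inflow else NA_real_
  }
  model
}

#' @export
print.balanced_model <- function(x, ...) {
  g <- x$groups
  cat("balanced_model:", nrow(g), "groups;",
      sum(g$flag != ""), "flagged\n")
  print(g[, c("code", "role", "TL", "B", "PB", "QB", "EE", "PQ", "OI")],
        digits = 4)
  invisible(x)
}

#' Predation mortality per group
#'
#' `M2_i = sum_j B_j QB_j DC[i, j] / B_i`: per-biomass losses of prey `i`
#' to all its consumers.
#'
#' @param groups Data frame with `B`, `QB` columns (e.g. `model$groups`).
#' @param diet A [diet_matrix()] over the same groups.
#' @return Numeric vector of M2 (1/yr); 0 for groups without predators.
#' @export
predation_mortality <- function(groups, diet) {
  stopifnot(inherits(diet, "diet_matrix"))
  cons_flow <- ifelse(is.na(groups$QB), 0, groups$B * groups$QB)
  pred_on <- as.numeric(diet$dc %*% cons_flow)
  m2 <- numeric(length(pred_on))
  pos <- groups$B > 0
  m2[pos] <- pred_on[pos] / groups$B[pos]
  if (any(!pos & pred_on > 0)) {
    stop("zero biomass with nonzero predation", call. = FALSE)
  }
  m2
}

#' Production/consumption ratio
#'
#' @param PB Production per biomass (1/yr).
#' @param QB Consumption per biomass (1/yr), > 0.
#' @return `PB / QB`.
#' @export
pq_ratio <- function(PB, QB) {
  if (any(is.na(QB)) || any(QB <= 0)) {
    stop("PQ undefined: QB must be positive", call. = FALSE)
  }
  PB / QB
}

#' Omnivory index
#'
#' Variance of a consumer's prey trophic levels weighted by diet fractions:
#' `OI_i = sum_j DC[j, i] (TL_j - (TL_i - 1))^2`, with imported diet counted
#' at trophic level 1. Producers and detritus have OI 0 by convention.
#'
#' @param diet A [diet_matrix()].
#' @param tls Trophic levels of all groups (defaults to
#'   [compute_trophic_levels()] of `diet`).
#' @return Numeric vector of omnivory indices.
#' @export
omnivory_index <- function(diet, tls = NULL) {
  stopifnot(inherits(diet, "diet_matrix"))
  if (is.null(tls)) tls <- compute_trophic_levels(diet)
  tls <- as.numeric(tls)
  n <- length(diet$codes)
  oi <- numeric(n)
  for (i in which(diet$roles == "consumer")) {
    mean_prey <- tls[i] - 1
    oi[i] <- sum(diet$dc[, i] * (tls - mean_prey)^2) +
      diet$import[i] * (1 - mean_prey)^2
  }
  oi
}

#' Derived flow attributes of a balanced model
#'
#' Per group: flow to detritus `B PB (1 - EE)` plus, for consumers, the
#' unassimilated fraction of consumption `ua B QB`; net efficiency
#' `PB / ((1 - ua) QB)` (production over assimilated consumption);
#' exploitation rate `F/Z = Y / (B PB)`; and the complementary proportion
#' of natural mortality `1 - F/Z`.
#'
#' @param model A `balanced_model`.
#' @return Data frame `(code, flow_detritus, net_efficiency, FZ, prop_M)`.
#' @export
flows <- function(model) {
  stopifnot(inherits(model, "balanced_model"))
  g <- model$groups
  ua <- model$unassimilated
  det <- g$role == "detritus"
  cons <- g$role == "consumer"
  fd <- ifelse(det, NA_real_, g$B * g$PB * pmax(0, 1 - g$EE))
  fd[cons] <- fd[cons] + ua * g$B[cons] * g$QB[cons]
  ne <- ifelse(cons, g$PB / ((1 - ua) * g$QB), NA_real_)
  prod <- g$B * g$PB
  fz <- ifelse(!det & prod > 0, g$catch / prod, NA_real_)
  data.frame(code = g$code, flow_detritus = fd, net_efficiency = ne,
             FZ = fz, prop_M = 1 - fz, row.names = NULL)
}

#' Primary production (and detritus) required to sustain the catches
#'
#' Back-calculates, along every food-web path from each caught group down
#' to the primary producers and detritus, the flow needed to sustain the
#' catch: `PPR = sum_paths Y_i / P_i * prod_links(Q_j / P_j * EE_j *
#' DC_{j,i})`, the formula as published (`convention = "printed"`). The
#' conventional raising-factor form `sum_paths Y_i * prod_links(Q_j / P_j *
#' DC)` is available as `convention = "raising"`. Paths are enumerated
#' depth-first through diet links, cycles are cut on first node repetition,
#' and contributions below `prune` are dropped.
#'
#' @param model A `balanced_model`.
#' @param catches Optional named vector of catches overriding
#'   `model$groups$catch`.
#' @param convention `"printed"` (default) or `"raising"`.
#' @param prune Contribution pruning threshold, default `1e-12`.
#' @return Scalar PPR (flow units per area per year); 0 when nothing is
#'   caught.
#' @export
ppr <- function(model, catches = NULL, convention = c("printed", "raising"),
                prune = 1e-12) {
  stopifnot(inherits(model, "balanced_model"))
  convention <- match.arg(convention)
  g <- model$groups
  dc <- model$diet$dc
  n <- nrow(g)
  Y <- g$catch
  if (!is.null(catches)) {
    Y <- rep(0, n)
    idx <- match(names(catches), g$code)
    if (anyNA(idx)) stop("unknown group in catches", call. = FALSE)
    Y[idx] <- catches
  }
  P <- g$B * g$PB
  Q <- ifelse(is.na(g$QB), 0, g$B * g$QB)
  basal <- g$role %in% c("producer", "detritus")

  total <- 0
  walk <- function(node, factor, visited) {
    if (basal[node]) {
      total <<- total + factor
      return(invisible(NULL))
    }
    # links: node (predator) -> its prey
    link <- if (convention == "printed") {
      (Q[node] / P[node]) * g$EE[node]
    } else {
      Q[node] / P[node]
    }
    for (prey in which(dc[, node] > 0)) {
      if (visited[prey]) next                       # cycle cut
      contrib <- factor * link * dc[prey, node]
      if (abs(contrib) < prune) next
      v <- visited; v[prey] <- TRUE
      walk(prey, contrib, v)
    }
    invisible(NULL)
  }
  for (i in which(Y > 0)) {
    base <- if (convention == "printed") Y[i] / P[i] else Y[i]
    if (basal[i]) {
      total <- total + base
      next
    }
    visited <- rep(FALSE, n)
    visited[i] <- TRUE
    walk(i, base, visited)
  }
  total
}
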