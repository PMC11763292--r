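# shared toy webs and independent oracles

# linear 3-level chain: producer -> herbivore -> carnivore
toy_chain_diet <- function() {
  dc <- matrix(0, 3, 3, dimnames = list(c("P", "H", "C"), c("P", "H", "C")))
  dc["P", "H"] <- 1
  dc["H", "C"] <- 1
  diet_matrix(dc, c("producer", "consumer", "consumer"))
}

# two-group predator-prey toy with hand-solvable balance; both EE unknown
toy_two <- function(catch_P = 0) {
  dc <- matrix(c(0, 0, 1, 0), 2, 2,
               dimnames = list(c("P", "C"), c("P", "C")))
  list(
    diet = diet_matrix(dc, c("producer", "consumer")),
    groups = group_params(c("P", "C"), c("producer", "consumer"),
                          B = c(10, 1), PB = c(10, 2), QB = c(NA, 5),
                          EE = c(NA, NA), catch = c(catch_P, 0))
  )
}

# brute-force trophic levels on an acyclic web by recursive path expansion
# from producers upwards (independent of the package's linear solve)
tl_recursive <- function(diet) {
  n <- length(diet$codes)
  memo <- rep(NA_real_, n)
  expand <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    if (diet$roles[i] != "consumer") {
      memo[i] <<- 1
      return(1)
    }
    val <- 1 + diet$import[i] * 1
    for (j in seq_len(n)) {
      if (diet$dc[j, i] > 0) val <- val + diet$dc[j, i] * expand(j)
    }
    memo[i] <<- val
    val
  }
  vapply(seq_len(n), expand, numeric(1))
}

# random acyclic diet matrix: consumers eat strictly lower-indexed groups
random_acyclic_diet <- function(n, seed) {
  set.seed(seed)
  codes <- paste0("G", seq_len(n))
  roles <- c("producer", rep("consumer", n - 1))
  dc <- matrix(0, n, n, dimnames = list(codes, codes))
  for (j in 2:n) {
    prey <- sample(seq_len(j - 1), sample.int(j - 1, 1))
    w <- runif(length(prey))
    dc[prey, j] <- w / sum(w)
  }
  diet_matrix(dc, roles)
}

# truncated Neumann series oracle: sum of walk products up to `order`
path_sum <- function(q, order = 50L) {
  m <- matrix(0, nrow(q), ncol(q))
  term <- diag(nrow(q))
  for (k in seq_len(order)) {
    term <- term %*% q
    m <- m + term
  }
  m
}

# random direct-impact matrix rescaled to a target spectral radius
random_impact_matrix <- function(n, seed, sr_target) {
  set.seed(seed)
  q <- matrix(runif(n * n, -1, 1), n, n)
  sr <- max(Mod(eigen(q, only.values = TRUE)$values))
  q * (sr_target / sr)
}

# exhaustive PPR path enumerator, written independently of fishweb::ppr:
# enumerates predator->prey paths as explicit lists of nodes
ppr_oracle <- function(model, convention = "printed") {
  g <- model$groups
  dc <- model$diet$dc
  basal <- g$role %in% c("producer", "detritus")
  P <- g$B * g$PB
  Q <- ifelse(is.na(g$QB), 0, g$B * g$QB)
  total <- 0
  grow <- function(path, factor) {
    tip <- path[length(path)]
    if (basal[tip]) {
      total <<- total + factor
      return(invisible(NULL))
    }
    link <- if (convention == "printed") Q[tip] / P[tip] * g$EE[tip]
            else Q[tip] / P[tip]
    for (prey in which(dc[, tip] > 0)) {
      if (prey %in% path) next
      grow(c(path, prey), factor * link * dc[prey, tip])
    }
  }
  for (i in which(g$catch > 0)) {
    base <- if (convention == "printed") g$catch[i] / P[i] else g$catch[i]
    grow(i, base)
  }
  total
}
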