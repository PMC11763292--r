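test_that("solve_balance recovers hand-solved ecotrophic efficiencies", {
  toy <- toy_two()
  mod <- solve_balance(toy$groups, toy$diet)
  expect_equal(mod$groups$EE[1], 0.05, tolerance = 1e-12)   # (1*5*1)/(10*10)
  toy2 <- toy_two(catch_P = 10)
  expect_equal(solve_balance(toy2$groups, toy2$diet)$groups$EE[1], 0.15,
               tolerance = 1e-12)
  # group with no predators and no catch has EE 0
  expect_equal(mod$groups$EE[2], 0)
  expect_true(all(abs(mod$groups$residual) < 1e-9))
})

test_that("structurally unsolvable biomass raises a named error", {
  dc <- matrix(c(0, 0, 1, 0), 2, 2,
               dimnames = list(c("P", "C"), c("P", "C")))
  dm <- diet_matrix(dc, c("producer", "consumer"))
  g <- group_params(c("P", "C"), c("producer", "consumer"),
                    B = c(10, NA), PB = c(10, 2), QB = c(NA, 5),
                    EE = c(0.5, 0.5))
  expect_error(solve_balance(g, dm), "C")
})

test_that("out-of-range solved EE is flagged unbalanced but returned", {
  dc <- matrix(c(0, 0, 1, 0), 2, 2,
               dimnames = list(c("P", "C"), c("P", "C")))
  dm <- diet_matrix(dc, c("producer", "consumer"))
  # consumer demand exceeds producer production -> EE > 1
  g <- group_params(c("P", "C"), c("producer", "consumer"),
                    B = c(1, 10), PB = c(1, 2), QB = c(NA, 5),
                    EE = c(NA, 0.5))
  mod <- solve_balance(g, dm)
  expect_gt(mod$groups$EE[1], 1)
  expect_match(mod$groups$flag[1], "unbalanced")
})

test_that("blank-one-parameter round trips recover the generated web", {
  set.seed(99)
  for (i in 1:10) {
    web <- generate_foodweb(sample(5:12, 1), seed = 1000 + i)
    g <- web$groups
    truth <- g
    for (r in which(g$role != "detritus")) {
      col <- sample(c("B", "PB", "EE"), 1)
      g[[col]][r] <- NA
    }
    mod <- solve_balance(g, web$diet)
    for (col in c("B", "PB", "EE")) {
      rel <- abs(mod$groups[[col]] - truth[[col]]) / abs(truth[[col]])
      expect_lt(max(rel[truth$role != "detritus"]), 1e-9)
    }
    expect_lt(max(abs(mod$groups$residual)), 1e-9)
  }
})

test_that("predation mortality is the flow-summed per-biomass loss", {
  dc <- matrix(c(0, 0, 0.5, 0), 2, 2,
               dimnames = list(c("prey", "pred"), c("prey", "pred")))
  dm <- diet_matrix(dc, c("producer", "consumer"),
                    import = c(prey = 0, pred = 0.5))
  g <- data.frame(code = c("prey", "pred"), B = c(4, 2), QB = c(NA, 10))
  m2 <- predation_mortality(g, dm)
  expect_equal(m2[1], 2 * 10 * 0.5 / 4)      # 2.5 per year
  expect_equal(m2[2], 0)                     # nobody eats the predator
  g2 <- g; g2$B[2] <- 4
  expect_equal(predation_mortality(g2, dm)[1], 2 * m2[1])  # linear in B_j
})

test_that("PQ ratio matches the published parameter rows", {
  expect_equal(signif(pq_ratio(0.580, 1.619), 3), 0.358)
  expect_equal(signif(pq_ratio(0.480, 0.950), 3), 0.505)
  expect_equal(pq_ratio(2, 2), 1)
  expect_error(pq_ratio(1, 0), "positive")
})

test_that("omnivory index is the diet-weighted prey-TL variance", {
  chain <- toy_chain_diet()
  expect_equal(omnivory_index(chain), c(0, 0, 0))   # single-prey diets
  # equal diet on prey of TL 2 and TL 4 (imposed), predator TL 4
  dc2 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "X"), c("A", "B", "X")))
  dc2["A", "X"] <- 0.5
  dc2["B", "X"] <- 0.5
  dm2 <- diet_matrix(dc2, c("producer", "producer", "consumer"))
  oi <- omnivory_index(dm2, tls = c(2, 4, 4))
  expect_equal(oi[3], 0.5 * (2 - 3)^2 + 0.5 * (4 - 3)^2)   # = 1
})

test_that("flow bookkeeping matches a hand ledger on a small web", {
  toy <- toy_two(catch_P = 10)
  mod <- solve_balance(toy$groups, toy$diet, unassimilated = 0.2)
  fl <- flows(mod)
  g <- mod$groups
  # producer: B PB (1 - EE); consumer (solved EE 0) adds 0.2 B QB egestion
  expect_equal(fl$flow_detritus[1], 10 * 10 * (1 - 0.15), tolerance = 1e-12)
  expect_equal(fl$flow_detritus[2], 1 * 2 * 1 + 0.2 * 1 * 5,
               tolerance = 1e-12)
  expect_equal(fl$net_efficiency[2], 2 / (0.8 * 5), tolerance = 1e-12)
  expect_equal(fl$FZ[1], 10 / (10 * 10))
  expect_equal(fl$prop_M[1], 1 - 0.1)
  expect_equal(fl$FZ[2], 0)          # uncaught group
  expect_equal(fl$prop_M[2], 1)
})

test_that("PPR matches the exhaustive path oracle and scales in the catch", {
  toy <- toy_two()
  g0 <- toy$groups
  mod0 <- solve_balance(g0, toy$diet)
  expect_equal(ppr(mod0), 0)                      # no catches anywhere
  # single-link closed form: catch on the herbivore
  g1 <- group_params(c("P", "C"), c("producer", "consumer"),
                     B = c(10, 1), PB = c(10, 2), QB = c(NA, 5),
                     EE = c(0.5, 0.5), catch = c(0, 1))
  mod1 <- solve_balance(g1, toy$diet)
  expect_equal(ppr(mod1), (1 / 2) * (5 / 2) * 0.5, tolerance = 1e-12)
  expect_equal(ppr(mod1, convention = "raising"), 1 * (5 / 2),
               tolerance = 1e-12)
  expect_equal(ppr(mod1), ppr_oracle(mod1), tolerance = 1e-12)
  # doubling every catch doubles PPR; PPR nondecreasing in any single catch
  expect_equal(ppr(mod1, catches = c(C = 2)), 2 * ppr(mod1),
               tolerance = 1e-12)
  # multi-path webs against the oracle
  for (seed in 1:8) {
    web <- generate_foodweb(sample(5:9, 1), seed = 300 + seed)
    mod <- solve_balance(web$groups, web$diet)
    for (conv in c("printed", "raising")) {
      expect_equal(ppr(mod, convention = conv),
                   ppr_oracle(mod, convention = conv),
                   tolerance = 1e-8)
    }
  }
})

test_that("PPR on a pure chain is the product of its link factors", {
  chain <- toy_chain_diet()
  g <- group_params(c("P", "H", "C"), c("producer", "consumer", "consumer"),
                    B = c(100, 10, 1), PB = c(50, 5, 1),
                    QB = c(NA, 25, 5), EE = c(0.3, 0.6, 0.4),
                    catch = c(0, 0, 2))
  mod <- solve_balance(g, chain)
  # two links: C->H and H->P, each contributing Q/P * EE * DC
  hand <- (2 / (1 * 1)) * ((1 * 5) / (1 * 1) * 0.4 * 1) *
    ((10 * 25) / (10 * 5) * 0.6 * 1)
  expect_equal(ppr(mod), hand, tolerance = 1e-12)
})

test_that("detritus inputs are handled and supplied detritus PB warned", {
  expect_warning(
    group_params(c("DET", "P", "C"),
                 c("detritus", "producer", "consumer"),
                 B = c(100, 10, 1), PB = c(67.5, 10, 2),
                 QB = c(NA, NA, 5), EE = c(NA, 0.5, 0.5)),
    "ignored")
})
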