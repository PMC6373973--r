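test_that("community assembly merges exchange metabolites and builds plumbing", {
  ts <- make_toy_syntrophy()
  cm <- assemble_full_community(ts$models, ts$medium)
  ## balanced rows: internal mets of both species, merged externals, BM_c
  expect_true(all(c("A::BM_A", "B::BM_B", "S[e]", "P[e]", "BM_c")
                  %in% rownames(cm$S)))
  expect_equal(sum(rownames(cm$S) == "P[e]"), 1)   # shared id appears once
  ## P does not accumulate: no medium export column for it
  expect_false("EX::P[e]::acc" %in% colnames(cm$S))
  expect_true("EX::S[e]::up" %in% colnames(cm$S))
  ## growth columns feed BM_c (integration), community growth drains it
  expect_equal(cm$S["BM_c", "A::growth"], 1)
  expect_equal(cm$S["BM_c", "community_growth"], -1)
  ## config errors
  expect_error(assemble_full_community(ts$models,
                                       medium_config(substrates = "X[e]")),
               "unknown external")
  expect_error(assemble_full_community(list(ts$models[[1]], ts$models[[1]]),
                                       ts$medium), "duplicate")
})

test_that("a single-species community forces F = 1 with no coupling rows", {
  m <- make_toy_producer()
  med <- medium_config(substrates = "S[e]", accumulate = c("P[e]" = TRUE))
  cm <- assemble_full_community(list(m), med)
  lp <- linearize_fix_mu(cm, 0.1)
  ## n-1 = 0 balanced-growth rows: equality rows are stoichiometry + sum(F)=1
  expect_equal(nrow(lp$Aeq), nrow(cm$S) + 1)
  sol <- community_fba(lp, "community_growth")
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$F), 1)
})

test_that("linearized toy community has the hand-derived solutions", {
  ts <- make_toy_syntrophy()
  cm <- assemble_full_community(ts$models, ts$medium)
  lp <- linearize_fix_mu(cm, 0.1)
  sol <- community_fba(lp, "community_growth")
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$F), c(0.5, 0.5), tolerance = 1e-8)
  ## above capacity: infeasible
  lp2 <- linearize_fix_mu(cm, 2)
  expect_error(fva(lp2, "F::A"), "infeasible")
  ## mu_c = 0 with maintenance-free toys: any F on the simplex
  lp0 <- linearize_fix_mu(cm, 0)
  r0 <- fva(lp0, c("F::A", "F::B"))
  expect_equal(r0$min, c(0, 0), tolerance = 1e-9)
  expect_equal(r0$max, c(1, 1), tolerance = 1e-9)
})

test_that("biomass integration fluxes sum to the community growth rate", {
  ts <- make_toy_syntrophy(accumulate_P = TRUE)
  cm <- assemble_full_community(ts$models, ts$medium)
  lp <- linearize_fix_mu(cm, 0.1)
  set.seed(5)
  for (k in 1:5) {
    sol <- community_fba(lp, stats::setNames(stats::rnorm(length(lp$vars)),
                                             lp$vars))
    expect_equal(unname(sol$x["A::growth"] + sol$x["B::growth"]), 0.1,
                 tolerance = 1e-8)
    expect_equal(unname(sum(sol$F)), 1, tolerance = 1e-9)
  }
})

test_that("zero abundance forces zero flux through the scaled bounds", {
  ts <- make_toy_syntrophy(accumulate_P = TRUE)
  cm <- assemble_full_community(ts$models, ts$medium)
  lp <- linearize_fix_mu(cm, 0.1)
  ## push the consumer out of the community
  sol <- community_fba(lp, "F::B", maximize = FALSE)
  expect_equal(unname(sol$F["B"]), 0, tolerance = 1e-9)
  bcols <- grep("^B::", names(sol$x), value = TRUE)
  expect_lt(max(abs(sol$x[bcols])), 1e-8)
})

test_that("maximum community growth rate search reproduces the toy optimum", {
  ts <- make_toy_syntrophy()
  cm <- assemble_full_community(ts$models, ts$medium)
  mu <- find_mu_max(cm)
  expect_equal(mu, 1.0, tolerance = 1e-4)
  ## producer alone (byproduct may accumulate): same capacity
  cm1 <- assemble_full_community(
    list(make_toy_producer()),
    medium_config(substrates = "S[e]", accumulate = c("P[e]" = TRUE)))
  expect_equal(find_mu_max(cm1), 1.0, tolerance = 1e-4)
  ## monotone feasibility around the optimum (grid consistency)
  expect_true(redcom:::.lp_feasible(
    linearize_fix_mu(cm, 0.999)$Aeq, linearize_fix_mu(cm, 0.999)$beq,
    linearize_fix_mu(cm, 0.999)$Aub, linearize_fix_mu(cm, 0.999)$bub,
    linearize_fix_mu(cm, 0.999)$lb, linearize_fix_mu(cm, 0.999)$ub))
  lpx <- linearize_fix_mu(cm, 1.001)
  expect_false(redcom:::.lp_feasible(lpx$Aeq, lpx$beq, lpx$Aub, lpx$bub,
                                     lpx$lb, lpx$ub))
  ## maintenance demand without substrate: no feasible community at all
  mmod <- make_toy_producer(toy_spec(maintenance = 2))
  cm2 <- assemble_full_community(
    list(mmod), medium_config(substrates = character(0),
                              accumulate = c("P[e]" = TRUE)))
  expect_true(is.na(find_mu_max(cm2)))
})

test_that("FVA ranges match the hand LPs and contain the FBA optimum", {
  ts <- make_toy_syntrophy()
  cm <- assemble_full_community(ts$models, ts$medium)
  lp <- linearize_fix_mu(cm, 0.1)
  r <- fva(lp, c("F::A", "F::B"))
  expect_equal(r$min, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(r$max, c(0.5, 0.5), tolerance = 1e-8)
  ts2 <- make_toy_syntrophy(accumulate_P = TRUE)
  cm2 <- assemble_full_community(ts2$models, ts2$medium)
  lp2 <- linearize_fix_mu(cm2, 0.1)
  r2 <- fva(lp2, "F::A")
  expect_equal(c(r2$min, r2$max), c(0.5, 1.0), tolerance = 1e-8)
  ## FVA range at mu_max contains the FBA witness
  mu <- find_mu_max(cm)
  lpm <- linearize_fix_mu(cm, mu)
  sol <- community_fba(lpm, "EX::S[e]::up", maximize = FALSE)
  rng <- fva(lpm, "EX::S[e]::up")
  expect_gte(sol$objective, rng$min - 1e-8)
  expect_lte(sol$objective, rng$max + 1e-8)
})

test_that("linear-fractional yield optimization is exact on the toys", {
  ts2 <- make_toy_syntrophy(accumulate_P = TRUE)
  cm2 <- assemble_full_community(ts2$models, ts2$medium)
  lp2 <- linearize_fix_mu(cm2, 0.1)
  ## stoichiometry bounds P-export per S-uptake at 1, attained as F_A -> 1
  y <- maximize_yield(lp2, "EX::P[e]::acc", "EX::S[e]::up")
  expect_equal(y$value, 1.0, tolerance = 1e-8)
  ## witness satisfies the model constraints
  expect_lt(max(abs(lp2$Aeq %*% y$x - lp2$beq)), 1e-7)
  ## a flux over itself
  expect_equal(maximize_yield(lp2, "EX::S[e]::up", "EX::S[e]::up")$value, 1)
  ## vanishing denominator is refused with advice
  cmv <- assemble_full_community(
    ts2$models, medium_config(substrates = c("S[e]" = 0),
                              accumulate = c("P[e]" = TRUE)))
  lpv <- linearize_fix_mu(cmv, 0)
  expect_error(maximize_yield(lpv, "EX::P[e]::acc", "EX::S[e]::up"),
               "vanish")
})
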