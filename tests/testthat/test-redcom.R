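toy_efvs <- function(model, mu = 0.1) {
  enumerate_efvs(build_flux_polyhedron(
    model, stats::setNames(mu, model$biomass_id)))
}

test_that("projection keeps exchange dimensions plus growth, oriented", {
  m <- make_toy_producer()
  pm <- project_to_exchange(toy_efvs(m), m)
  expect_equal(nrow(pm$oriented), 1)
  expect_equal(unname(pm$oriented[1, c("uptS", "expP", "mu")]),
               c(1, 1, 0.1), tolerance = 1e-9)
  expect_true(all(pm$oriented >= -1e-12))
  expect_equal(pm$mu_fix, 0.1)
  mw <- make_toy_producer(toy_spec(wasteful = TRUE))
  pw <- project_to_exchange(toy_efvs(mw), mw)
  expect_equal(sort(pw$oriented[, "uptS"]), c(1, 10))
  ## EFVs not computed at fixed growth: error
  free <- enumerate_efvs(build_flux_polyhedron(m))
  expect_error(project_to_exchange(free, m), "fixed growth")
  ## no exchange reactions: error
  closed <- suppressWarnings(metabolic_model(
    "Z",
    data.frame(id = c("X", "BM"), external = FALSE),
    data.frame(id = c("cyc", "growth"), reversible = c(TRUE, FALSE),
               lb = c(-1, 0), ub = c(1, 1)),
    matrix(c(1, -1, 0, -1), 2, 2,
           dimnames = list(c("X", "BM"), c("cyc", "growth"))),
    "growth"))
  ev0 <- enumerate_efvs(build_flux_polyhedron(closed, c(growth = 0)))
  expect_error(project_to_exchange(ev0, closed), "no exchange")
})

test_that("identical projections collapse to the lowest source index", {
  pm <- make_projected(rbind(c(1, 1, 0.1),
                             c(1, 1, 0.1),            # exact duplicate
                             c(1 + 1e-8, 1, 0.1),     # within tolerance
                             c(10, 10, 0.1)))
  colnames(pm$oriented) <- colnames(pm$signed) <- c("up", "ex", "mu")
  dd <- deduplicate_conversions(pm)
  expect_equal(nrow(dd$oriented), 2)
  expect_equal(dd$source_index, c(1, 4))
  ## genuinely distinct rows survive
  mw <- make_toy_producer(toy_spec(wasteful = TRUE))
  pw <- deduplicate_conversions(project_to_exchange(toy_efvs(mw), mw))
  expect_equal(nrow(pw$oriented), 2)
})

test_that("the convex dominance filter discards wasteful conversions", {
  mw <- make_toy_producer(toy_spec(wasteful = TRUE))
  pw <- deduplicate_conversions(project_to_exchange(toy_efvs(mw), mw))
  ft <- filter_minimal_conversions(pw)
  expect_equal(nrow(ft$oriented), 1)
  expect_equal(unname(ft$oriented[1, "uptS"]), 1)
  certs <- attr(ft, "certificates")
  expect_length(certs, 1)
  ## certificate: weight 1 on the minimal conversion dominates the wasteful one
  expect_equal(unname(certs[[1]]$w), 1, tolerance = 1e-9)
  ## single candidate: kept
  p1 <- make_projected(matrix(c(1, 1, 0.1), 1))
  expect_equal(nrow(filter_minimal_conversions(p1)$oriented), 1)
  ## different products: both kept (one conversion per product survives)
  p2 <- make_projected(rbind(c(1, 1, 0, 0.1),
                             c(1, 0, 1, 0.1)))
  colnames(p2$oriented) <- colnames(p2$signed) <- c("up", "exP", "exQ", "mu")
  f2 <- filter_minimal_conversions(p2)
  expect_equal(nrow(f2$oriented), 2)
})

test_that("dominance filtering is order independent (50 shuffles)", {
  set.seed(99)
  E <- rbind(c(1.0, 1.0, 0, 0.1),
             c(2.0, 2.0, 0, 0.1),     # dominated by row 1
             c(1.0, 0, 1.0, 0.1),
             c(1.5, 0.5, 0.5, 0.1),   # dominated by mix of rows 1 and 3
             c(0.9, 1.2, 0, 0.1),
             c(3.0, 0.1, 0.1, 0.1))
  base <- make_projected(E)
  kept_ref <- sort(filter_minimal_conversions(base)$source_index)
  for (k in 1:50) {
    perm <- sample(nrow(E))
    pm <- make_projected(E[perm, ])
    pm$source_index <- perm            # remember original identities
    kept <- sort(filter_minimal_conversions(pm)$source_index)
    expect_equal(kept, kept_ref)
  }
  ## every discarded row has a stored certificate whose mix dominates it
  certs <- attr(filter_minimal_conversions(base), "certificates")
  expect_equal(sort(vapply(certs, `[[`, 0, "source_index")),
               setdiff(seq_len(nrow(E)), kept_ref))
  for (ce in certs) {
    w <- ce$w
    mix <- as.numeric(w %*% E[as.integer(names(w)), , drop = FALSE])
    expect_true(all(mix <= E[ce$source_index, ] + 1e-7))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
})

test_that("kept conversions contain the biomass-yield optimum per pattern", {
  ## wasteful producer: the (1 S, 1 P, mu) conversion is the yield optimum
  ## for the S->P pattern and must survive
  mw <- make_toy_producer(toy_spec(wasteful = TRUE))
  pw <- deduplicate_conversions(project_to_exchange(toy_efvs(mw), mw))
  ft <- filter_minimal_conversions(pw)
  yields <- ft$oriented[, "mu"] / ft$oriented[, "uptS"]
  expect_equal(max(yields), 0.1 / 1, tolerance = 1e-9)
})

test_that("reduced species models realize N^red = N^EX E", {
  m <- make_toy_producer()
  ft <- filter_minimal_conversions(
    deduplicate_conversions(project_to_exchange(toy_efvs(m), m)))
  rs <- build_reduced_species(m, ft)
  expect_equal(ncol(rs$Nred), 1)
  expect_equal(rs$Nred["S[e]", 1], -1)
  expect_equal(rs$Nred["P[e]", 1], 1)
  ## column-by-column identity with the defining product
  Nex <- exchange_stoichiometry(m)[, ft$exchange_ids]
  expect_equal(unname(rs$Nred),
               unname(Nex %*% t(ft$signed[, ft$exchange_ids, drop = FALSE])))
  mc <- make_toy_consumer()
  fc <- filter_minimal_conversions(
    deduplicate_conversions(project_to_exchange(toy_efvs(mc), mc)))
  rc <- build_reduced_species(mc, fc)
  expect_equal(rc$Nred["P[e]", 1], -1)
  ## infeasible growth rate: explicit error
  mm <- make_toy_producer(toy_spec(maintenance = 2))
  em <- toy_efvs(mm, 0.05)
  pmn <- project_to_exchange(em, mm)
  expect_error(build_reduced_species(mm, filter_minimal_conversions(pmn)),
               "infeasible")
})

test_that("reduced community reproduces the toy solutions and stays linear", {
  ts <- make_toy_syntrophy()
  res <- redcom_pipeline(ts$models, ts$medium, 0.1)
  rcm <- res$rcm
  sol <- community_fba(rcm, "community_growth")
  lamA <- sol$x[grep("^A::conv", names(sol$x))]
  lamB <- sol$x[grep("^B::conv", names(sol$x))]
  expect_equal(unname(c(sum(lamA), sum(lamB))), c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(unname(sol$F), c(0.5, 0.5), tolerance = 1e-8)
  ## mu mismatch across members is refused
  fa <- filter_minimal_conversions(deduplicate_conversions(
    project_to_exchange(toy_efvs(ts$models[[1]], 0.1), ts$models[[1]])))
  fb <- filter_minimal_conversions(deduplicate_conversions(
    project_to_exchange(toy_efvs(ts$models[[2]], 0.2), ts$models[[2]])))
  expect_error(assemble_reduced_community(
    list(build_reduced_species(ts$models[[1]], fa),
         build_reduced_species(ts$models[[2]], fb)),
    ts$medium, 0.1), "mu")
})

test_that("community EFVs of the reduced toys match the hand enumeration", {
  ts <- make_toy_syntrophy()
  res <- redcom_pipeline(ts$models, ts$medium, 0.1)
  expect_equal(res$report$community_efvs, 1)
  ann <- attr(res$efvs, "annotation")
  expect_equal(ann[["F::A"]], 0.5, tolerance = 1e-8)
  ts2 <- make_toy_syntrophy(accumulate_P = TRUE)
  res2 <- redcom_pipeline(ts2$models, ts2$medium, 0.1)
  expect_equal(res2$report$community_efvs, 2)
  FA <- sort(attr(res2$efvs, "annotation")[["F::A"]])
  expect_equal(FA, c(0.5, 1.0), tolerance = 1e-8)   # balanced and pure-A
})

test_that("unpacking reproduces full fluxes and the scaled constraints", {
  ts <- make_toy_syntrophy()
  res <- redcom_pipeline(ts$models, ts$medium, 0.1)
  sol <- community_fba(res$rcm, "community_growth")
  up <- unpack_solution(res$rcm, sol$x, ts$models)
  expect_equal(unname(up$A$flux[c("uptS", "R1", "expP", "growth")]),
               c(0.5, 0.5, 0.5, 0.05), tolerance = 1e-8)
  expect_equal(up$A$F, 0.5, tolerance = 1e-8)
  expect_lt(up$A$max_violation, 1e-8)
  ## community EFV rows unpack feasibly too
  B <- res$efvs$vectors[res$efvs$bounded, , drop = FALSE]
  upe <- unpack_solution(res$rcm, B[1, ], ts$models)
  expect_lt(max(vapply(upe, `[[`, 0, "max_violation")), 1e-8)
})

test_that("random reduced-community solutions satisfy the scaled single-species constraints", {
  ## the consistency property that lets the reduced model drop the scaled bounds
  ts <- make_toy_syntrophy(accumulate_P = TRUE)
  models <- list(make_toy_producer(toy_spec(wasteful = TRUE,
                                            maintenance = 0.5), "A"),
                 make_toy_consumer(toy_spec(), "B"))
  res <- redcom_pipeline(models, ts$medium, 0.1)
  set.seed(31)
  worst <- 0
  for (k in 1:100) {
    obj <- stats::setNames(stats::rnorm(length(res$rcm$vars)), res$rcm$vars)
    sol <- community_fba(res$rcm, obj)
    expect_equal(sol$status, "optimal")
    up <- unpack_solution(res$rcm, sol$x, models)
    for (s in names(up)) {
      worst <- max(worst, up[[s]]$max_violation)
      lam <- sol$x[res$rcm$reduced[[s]]$conv_ids]
      expect_equal(unname(sum(lam)), unname(sol$F[s]), tolerance = 1e-8)
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("reduced-model ranges are contained in the full linearized ranges", {
  fixtures <- list(
    make_toy_syntrophy(),
    make_toy_syntrophy(accumulate_P = TRUE),
    list(models = list(make_toy_producer(toy_spec(wasteful = TRUE), "A"),
                       make_toy_consumer(toy_spec(), "B")),
         medium = medium_config(substrates = "S[e]",
                                accumulate = c("P[e]" = TRUE))))
  for (fx in fixtures) {
    for (mu in c(0.05, 0.1)) {
      res <- redcom_pipeline(fx$models, fx$medium, mu, compute_efvs = FALSE)
      lp_full <- linearize_fix_mu(assemble_full_community(fx$models, fx$medium),
                                  mu)
      qs <- c(grep("^F::", res$rcm$vars, value = TRUE),
              grep("^EX::", res$rcm$vars, value = TRUE))
      r_red <- fva(res$rcm, qs)
      r_full <- fva(lp_full, qs)
      expect_true(all(r_red$min >= r_full$min - 1e-6))
      expect_true(all(r_red$max <= r_full$max + 1e-6))
    }
  }
})

test_that("maximum growth rates agree between reduced and full models", {
  fixtures <- list(
    make_toy_syntrophy(),
    make_toy_syntrophy(accumulate_P = TRUE))
  for (fx in fixtures) {
    mu_full <- find_mu_max(assemble_full_community(fx$models, fx$medium))
    mu_red <- find_mu_max(function(mu)
      redcom_pipeline(fx$models, fx$medium, mu, compute_efvs = FALSE)$rcm)
    expect_equal(mu_red, mu_full, tolerance = 1e-4)
  }
})

test_that("the pipeline report tracks stage counts and failures", {
  ts <- make_toy_syntrophy()
  res <- redcom_pipeline(ts$models, ts$medium, 0.1)
  expect_equal(res$report$species$A$efvs_bounded, 1)
  expect_equal(res$report$species$B$kept, 1)
  expect_equal(res$report$community_efvs, 1)
  mw <- list(make_toy_producer(toy_spec(wasteful = TRUE), "A"),
             make_toy_consumer(toy_spec(), "B"))
  resw <- redcom_pipeline(mw, ts$medium, 0.1)
  expect_equal(resw$report$species$A$projected, 2)
  expect_equal(resw$report$species$A$kept, 1)
  expect_length(resw$report$species$A$certificates, 1)
  ## stage errors carry the stage name
  expect_error(redcom_pipeline(ts$models, ts$medium, 2),
               "build_flux_polyhedron")
})
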