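## Toy fixture species with analytically known behavior.
##
## The toys are maintenance-free by default so that every downstream number
## (EFV counts, community compositions, maximum growth rates) can be derived
## by hand; the `maintenance` option adds an ATP drain to exercise
## inhomogeneous constraints.

#' Specification of a toy species
#'
#' @param biomass_yield gDW biomass formed per mmol substrate (default 0.1).
#' @param uptake_bound substrate uptake capacity, mmol/gDW/h (default 10).
#' @param wasteful add a growth-independent substrate->byproduct reaction.
#' @param maintenance ATP-maintenance demand, mmol/gDW/h (0 = none).
#' @return list of class `toy_spec`.
#' @export
toy_spec <- function(biomass_yield = 0.1, uptake_bound = 10,
                     wasteful = FALSE, maintenance = 0) {
  if (biomass_yield <= 0) stop("biomass_yield must be > 0")
  if (uptake_bound <= 0) stop("uptake_bound must be > 0")
  structure(list(biomass_yield = biomass_yield, uptake_bound = uptake_bound,
                 wasteful = wasteful, maintenance = maintenance),
            class = "toy_spec")
}

#' Toy producer species
#'
#' Converts substrate S 1:1 to byproduct P while forming biomass:
#' `uptS: S[e] -> S`, `R1: S -> yield BM_A + P`, `expP: P -> P[e]`,
#' `growth: BM_A ->` (the growth-rate drain).  The wasteful variant adds
#' `R2: S -> P` (substrate burned without growth), which the
#' minimal-conversion filter must discard from the reduced model.
#'
#' @param spec a [toy_spec()].
#' @param species_id identifier (default "A").
#' @return a `metabolic_model`.
#' @export
make_toy_producer <- function(spec = toy_spec(), species_id = "A") {
  y <- spec$biomass_yield
  u <- spec$uptake_bound
  bm <- paste0("BM_", species_id)
  mets <- data.frame(
    id = c("S[e]", "P[e]", "S", "P", bm),
    external = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  rxn_ids <- c("uptS", "R1", "expP", "growth")
  S <- matrix(0, 5, 4, dimnames = list(mets$id, rxn_ids))
  S["S[e]", "uptS"] <- -1; S["S", "uptS"] <- 1
  S["S", "R1"] <- -1; S[bm, "R1"] <- y; S["P", "R1"] <- 1
  S["P", "expP"] <- -1; S["P[e]", "expP"] <- 1
  S[bm, "growth"] <- -1
  rxns <- data.frame(id = rxn_ids, reversible = FALSE,
                     lb = 0, ub = c(u, u, 2 * u, u * y),
                     stringsAsFactors = FALSE)
  if (spec$wasteful) {
    S <- cbind(S, R2 = 0)
    S["S", "R2"] <- -1; S["P", "R2"] <- 1
    rxns <- rbind(rxns, data.frame(id = "R2", reversible = FALSE,
                                   lb = 0, ub = u))
  }
  if (spec$maintenance > 0) {
    S <- rbind(S, ATP = 0)
    S["ATP", "R1"] <- 1
    S <- cbind(S, atp_maint = 0)
    S["ATP", "atp_maint"] <- -1
    rxns <- rbind(rxns, data.frame(id = "atp_maint", reversible = FALSE,
                                   lb = spec$maintenance, ub = 2 * u))
    mets <- rbind(mets, data.frame(id = "ATP", external = FALSE))
  }
  metabolic_model(species_id = species_id, mets = mets, rxns = rxns, S = S,
                  biomass_id = "growth",
                  atp_maintenance_id = if (spec$maintenance > 0) "atp_maint")
}

#' Toy consumer species
#'
#' Grows on the producer's byproduct: `uptP: P[e] -> P`,
#' `R3: P -> yield BM_B`, `growth: BM_B ->`.
#'
#' @param spec a [toy_spec()].
#' @param species_id identifier (default "B").
#' @return a `metabolic_model`.
#' @export
make_toy_consumer <- function(spec = toy_spec(), species_id = "B") {
  y <- spec$biomass_yield
  u <- spec$uptake_bound
  bm <- paste0("BM_", species_id)
  mets <- data.frame(
    id = c("P[e]", "P", bm),
    external = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  rxn_ids <- c("uptP", "R3", "growth")
  S <- matrix(0, 3, 3, dimnames = list(mets$id, rxn_ids))
  S["P[e]", "uptP"] <- -1; S["P", "uptP"] <- 1
  S["P", "R3"] <- -1; S[bm, "R3"] <- y
  S[bm, "growth"] <- -1
  rxns <- data.frame(id = rxn_ids, reversible = FALSE,
                     lb = 0, ub = c(u, u, u * y),
                     stringsAsFactors = FALSE)
  metabolic_model(species_id = species_id, mets = mets, rxns = rxns, S = S,
                  biomass_id = "growth")
}

#' The canonical two-species toy community
#'
#' Producer A (S -> P + biomass) feeding consumer B (P -> biomass).  With the
#' byproduct P not allowed to accumulate, the community composition at any
#' feasible growth rate is uniquely F = (0.5, 0.5) and the maximum community
#' growth rate is `uptake_bound * biomass_yield` (1.0 1/h at the defaults).
#'
#' @param spec a [toy_spec()] applied to both members.
#' @param accumulate_P may the byproduct accumulate in the medium?
#' @return list with `models` (two `metabolic_model`s) and `medium`
#'   (a [medium_config()]).
#' @export
make_toy_syntrophy <- function(spec = toy_spec(), accumulate_P = FALSE) {
  list(models = list(make_toy_producer(spec, "A"),
                     make_toy_consumer(spec, "B")),
       medium = medium_config(substrates = "S[e]",
                              accumulate = c("P[e]" = accumulate_P)))
}

#' Random small flux polyhedron (property-test fixture)
#'
#' Generates a random stoichiometric toy with small integer coefficients,
#' mostly irreversible reactions and finite bounds, plus an optional fixed
#' flux and extra inequality row — the instance class used to cross-validate
#' the double-description enumerator against the exact brute-force oracle.
#'
#' @param seed integer seed.
#' @return a `flux_polyhedron` with at most 6 reactions.
#' @export
random_toy_polyhedron <- function(seed) {
  set.seed(seed)
  n <- sample(3:6, 1)
  m <- sample(1:3, 1)
  repeat {
    N <- matrix(sample(c(-2, -1, -1, 0, 0, 0, 1, 1, 2), m * n, replace = TRUE),
                m, n)
    if (all(rowSums(N != 0) > 0)) break
  }
  rev <- stats::runif(n) < 0.25
  lb <- ifelse(rev, -sample(1:5, n, replace = TRUE), 0)
  ub <- sample(2:10, n, replace = TRUE)
  Aub <- NULL; bub <- NULL
  if (stats::runif(1) < 0.4) {
    Aub <- matrix(sample(0:2, n, replace = TRUE), 1, n)
    bub <- sample(3:12, 1)
  }
  ids <- paste0("r", seq_len(n))
  colnames(N) <- ids
  Aeq <- N; beq <- rep(0, m)
  if (stats::runif(1) < 0.5) {
    j <- sample(n, 1)
    val <- sample(0:2, 1) / 2
    if (val >= lb[j] && val <= ub[j]) {
      row <- rep(0, n); row[j] <- 1
      Aeq <- rbind(Aeq, row); beq <- c(beq, val)
    }
  }
  .polyhedron(ids, Aeq, beq, lb, ub, Aub, bub, irrev = which(!rev))
}
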