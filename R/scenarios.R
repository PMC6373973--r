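## Built-in analysis scenarios.
##
## The biogas case study couples up to nine curated core models (primary and
## secondary fermenters plus two methanogens).  Those SBML files are not
## bundled with the package; scenarios referencing them name the files they
## expect and fail with an explicit listing when absent.  The toy scenarios
## are self-contained.
##
## Constraint patches use the reaction ids of the curated model collection
## (r_ATPmaint, r_Acex, r_SO4up, ...); maintenance coefficients are encoded
## as lower bounds on the ATP-maintenance reaction, uptake/export caps as
## upper bounds, in mmol/gDW/h.

.SPECIES_CONSTRAINTS <- list(
  EC = list(c("r_ATPmaint", "lb", 3.15), c("r_Glcup", "ub", 18.5),
            c("r_Glycup", "eq", 0), c("r_Glucup", "eq", 0),
            c("r_O2up", "eq", 0)),
  AW = list(c("r_ATPmaint", "lb", 0.29), c("r_Glcup", "ub", 2.75),
            c("r_Frucup", "eq", 0), c("r_Lacup", "ub", 3),
            c("r_Ethup", "ub", 9), c("r_MeOHup", "eq", 0),
            c("r_H2up", "ub", 19.5), c("r_Formup", "ub", 19.5),
            c("growth", "ub", 0.162)),
  PF = list(c("r_ATPmaint", "lb", 0.76), c("r_Glcup", "ub", 4),
            c("r_Lacup", "ub", 11), c("r_Ethup", "ub", 11),
            c("growth", "ub", 0.16)),
  CA = list(c("r_ATPmaint", "lb", 1), c("r_Glcup", "ub", 12.75),
            c("r_Glycup", "eq", 0), c("r_Aconex", "eq", 0),
            c("r_Butolex", "eq", 0)),
  SF = list(c("r_ATPmaint", "lb", 0.14), c("r_Propup", "ub", 1.6),
            c("r_Fumup", "ub", 0.5), c("r_SO4up", "eq", 0)),
  SW = list(c("r_ATPmaint", "lb", 0.14), c("r_Butup", "ub", 4.25),
            c("r_Crotup", "ub", 2.85)),
  DV = list(c("r_ATPmaint", "lb", 4.3), c("r_Acex", "ub", 50),
            c("r_SO4up", "eq", 0)),
  MB = list(c("r_ATPmaint", "lb", 2.5), c("r_CH4ex", "ub", 15)),
  MH = list(c("r_ATPmaint", "lb", 0.9), c("r_CH4ex", "ub", 15))
)

.SCENARIOS <- list(
  three_species_ethanol = list(
    species = c("DV", "MB", "MH"),
    substrates = c("Eth[e]", "CO2[e]"),
    accumulate = c("Ac[e]" = TRUE, "CH4[e]" = TRUE, "CO2[e]" = TRUE),
    co2_uptake = TRUE, mu_c = 0.026),
  two_species_lactate = list(
    species = c("DV", "MH"),
    substrates = "Lac[e]",
    accumulate = c("Ac[e]" = TRUE, "CH4[e]" = TRUE, "CO2[e]" = TRUE),
    co2_uptake = FALSE, mu_c = 0.008),
  six_species_ethanol = list(
    species = c("AW", "PF", "SF", "DV", "MB", "MH"),
    substrates = "Eth[e]",
    accumulate = c("CH4[e]" = TRUE, "CO2[e]" = TRUE,
                   "Ac[e]" = FALSE, "Prop[e]" = FALSE, "Buty[e]" = FALSE),
    co2_uptake = FALSE, mu_c = 0.001),
  nine_species_glucose = list(
    species = c("EC", "AW", "PF", "CA", "SF", "SW", "DV", "MB", "MH"),
    substrates = "Glc[e]",
    accumulate = c("CH4[e]" = TRUE, "CO2[e]" = TRUE,
                   "Ac[e]" = FALSE, "Prop[e]" = FALSE, "Buty[e]" = FALSE,
                   "Mal[e]" = TRUE),
    co2_uptake = FALSE, mu_c = 0.00067),
  ## ethanol culture constrained by metaproteomic observations: only the
  ## DV/MB/MH guilds remain active and the acetoclastic methanogen loses its
  ## hydrogenotrophic route (Methanosaeta-like behavior)
  metaproteome_constrained = list(
    species = c("DV", "MB", "MH"),
    substrates = "Eth[e]",
    accumulate = c("CH4[e]" = TRUE, "CO2[e]" = TRUE, "Ac[e]" = FALSE),
    co2_uptake = FALSE, mu_c = 0.001,
    disabled_uptakes = list(MB = "r_H2up")),
  toy_syntrophy = list(toy = "syntrophy", mu_c = 0.1),
  toy_syntrophy_accumulate = list(toy = "syntrophy_accumulate", mu_c = 0.1),
  toy_wasteful = list(toy = "wasteful", mu_c = 0.1)
)

#' List the built-in scenarios
#'
#' @return character vector of scenario names.
#' @export
list_scenarios <- function() names(.SCENARIOS)

#' Load a scenario configuration
#'
#' Resolves a built-in scenario (or an equivalent config list) into patched
#' member models plus a medium configuration.  Curated-model scenarios read
#' one file per species from `model_dir` (`<code>.xml`, `<code>.sbml` or
#' `<code>.tsv`) and then apply the scenario's bound patches: maintenance
#' coefficients as ATP-maintenance lower bounds, uptake/export caps as upper
#' bounds (never widening a declared bound), disabled uptakes pinned to zero,
#' and optional per-species maintenance overrides.
#'
#' @param scenario scenario name (see [list_scenarios()]) or a config list
#'   with the same fields.
#' @param model_dir directory holding the curated single-species model files
#'   (unused by toy scenarios).
#' @param maintenance_override optional named numeric: species code ->
#'   replacement ATP-maintenance lower bound (e.g. a uniform 1 mmol/gDW/h).
#' @return list with `models`, `medium`, `mu_c`, `name`.
#' @export
load_scenario <- function(scenario, model_dir = NULL,
                          maintenance_override = NULL) {
  if (is.character(scenario)) {
    if (!scenario %in% names(.SCENARIOS)) {
      stop("unknown scenario '", scenario, "'; available: ",
           paste(names(.SCENARIOS), collapse = ", "))
    }
    cfg <- .SCENARIOS[[scenario]]
    cfg$name <- scenario
  } else {
    cfg <- scenario
    if (is.null(cfg$name)) cfg$name <- "custom"
  }
  if (!is.null(cfg$toy)) {
    out <- switch(cfg$toy,
      syntrophy = make_toy_syntrophy(),
      syntrophy_accumulate = make_toy_syntrophy(accumulate_P = TRUE),
      wasteful = {
        ts <- make_toy_syntrophy()
        ts$models[[1]] <- make_toy_producer(toy_spec(wasteful = TRUE), "A")
        ts
      },
      stop("unknown toy scenario: ", cfg$toy))
    return(list(models = out$models, medium = out$medium,
                mu_c = cfg$mu_c, name = cfg$name))
  }
  if (is.null(model_dir)) {
    stop("scenario '", cfg$name, "' needs model_dir with the curated ",
         "single-species model files")
  }
  paths <- vapply(cfg$species, function(sp) {
    for (ext in c(".xml", ".sbml", ".tsv")) {
      p <- file.path(model_dir, paste0(sp, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }, "")
  if (anyNA(paths)) {
    miss <- cfg$species[is.na(paths)]
    stop("curated model files required but not found in ", model_dir, ": ",
         paste(file.path(model_dir, paste0(miss, ".xml")), collapse = ", "),
         ". These single-species core models are distributed with the ",
         "original curated collection and are not bundled with this package.")
  }
  models <- lapply(seq_along(cfg$species), function(i) {
    m <- read_model(paths[i], species_id = cfg$species[i])
    m <- .apply_patches(m, .SPECIES_CONSTRAINTS[[cfg$species[i]]])
    sp <- cfg$species[i]
    if (!is.null(maintenance_override) && sp %in% names(maintenance_override)) {
      j <- match("r_ATPmaint", m$rxns$id)
      if (is.na(j)) stop("species ", sp, " has no r_ATPmaint reaction")
      m$rxns$lb[j] <- maintenance_override[[sp]]
    }
    if (!is.null(cfg$disabled_uptakes) && sp %in% names(cfg$disabled_uptakes)) {
      for (rid in cfg$disabled_uptakes[[sp]]) {
        j <- match(rid, m$rxns$id)
        if (is.na(j)) stop("species ", sp, ": cannot disable unknown reaction ", rid)
        m$rxns$lb[j] <- 0; m$rxns$ub[j] <- 0
      }
    }
    m
  })
  substrates <- cfg$substrates
  accumulate <- cfg$accumulate
  if (isTRUE(cfg$co2_uptake) && !"CO2[e]" %in% substrates) {
    substrates <- c(substrates, "CO2[e]")
  }
  list(models = models,
       medium = medium_config(substrates = substrates,
                              accumulate = accumulate,
                              co2_uptake_allowed = isTRUE(cfg$co2_uptake)),
       mu_c = cfg$mu_c, name = cfg$name)
}

## bound patches never widen a declared bound: caps take the min of declared
## and patch upper bound; maintenance lower bounds take the max
.apply_patches <- function(m, patches) {
  for (p in patches) {
    rid <- p[1]; kind <- p[2]; val <- as.numeric(p[3])
    j <- match(rid, m$rxns$id)
    if (is.na(j)) next      # constraint refers to a reaction this model lacks
    if (kind == "lb") m$rxns$lb[j] <- max(m$rxns$lb[j], val)
    if (kind == "ub") m$rxns$ub[j] <- min(m$rxns$ub[j], val)
    if (kind == "eq") { m$rxns$lb[j] <- val; m$rxns$ub[j] <- val }
  }
  m
}
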