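## Single-species stoichiometric models.

.BIG_M_DEFAULT <- 1000

#' Construct a single-species metabolic model
#'
#' A `metabolic_model` holds the stoichiometry `S` (all metabolites, external
#' ones included, one column per reaction), reversibilities, flux bounds, the
#' biomass reaction and optional extra linear constraints `A r <= b`.
#' External metabolites are unbalanced in single-species mode: the
#' steady-state condition `N r = 0` applies to internal metabolites only.
#'
#' Every flux must be bounded so that, in a community, zero abundance forces
#' zero flux.  Infinite declared bounds are replaced by `+/- big_m` with a
#' warning.
#'
#' @param species_id short identifier, e.g. "DV".
#' @param mets data.frame with columns `id`, `name`, `external` (logical).
#' @param rxns data.frame with columns `id`, `reversible` (logical),
#'   `lb`, `ub` (mmol/gDW/h; 1/h for the growth reaction).
#' @param S numeric stoichiometry matrix, rows = `mets$id`, cols = `rxns$id`.
#' @param biomass_id id of the growth reaction; it must produce the single
#'   biomass metabolite with coefficient +1.
#' @param exchange_ids reaction ids transferring external metabolites; if
#'   NULL, auto-detected as reactions touching at least one external
#'   metabolite.
#' @param constraints optional list(A = matrix with reaction-id columns,
#'   b = numeric) for extra inequalities `A r <= b`.
#' @param atp_maintenance_id optional id of the ATP-maintenance reaction
#'   (its lower bound encodes the maintenance coefficient).
#' @param big_m replacement magnitude for infinite bounds (mmol/gDW/h);
#'   `NA` forbids unbounded reactions (validation error instead).
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(species_id, mets, rxns, S, biomass_id,
                            exchange_ids = NULL, constraints = NULL,
                            atp_maintenance_id = NULL,
                            big_m = .BIG_M_DEFAULT) {
  mets <- as.data.frame(mets)
  rxns <- as.data.frame(rxns)
  if (is.null(mets$name)) mets$name <- mets$id
  S <- as.matrix(S)
  rownames(S) <- mets$id
  colnames(S) <- rxns$id
  if (any(!is.finite(rxns$lb)) || any(!is.finite(rxns$ub))) {
    if (is.na(big_m)) {
      stop("model '", species_id, "' has unbounded reactions and big_m is disabled")
    }
    warning("model '", species_id,
            "': replacing infinite flux bounds by big-M = ", big_m)
    rxns$lb[!is.finite(rxns$lb)] <- -big_m
    rxns$ub[!is.finite(rxns$ub)] <- big_m
  }
  if (is.null(exchange_ids)) {
    touches_ext <- colSums(abs(S[mets$external, , drop = FALSE])) > 0
    exchange_ids <- rxns$id[touches_ext]
  }
  obj <- structure(list(
    species_id = species_id,
    mets = mets,
    rxns = rxns,
    S = S,
    biomass_id = biomass_id,
    exchange_ids = exchange_ids,
    constraints = constraints,
    atp_maintenance_id = atp_maintenance_id
  ), class = "metabolic_model")
  rep <- validate_model(obj)
  if (length(rep) > 0) {
    stop("invalid model '", species_id, "': ",
         paste(vapply(rep, `[[`, "", "message"), collapse = "; "))
  }
  obj
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: stoichiometry references declared
#' metabolites only, `lb <= ub`, irreversible implies `lb >= 0`, exactly one
#' biomass metabolite produced by the biomass reaction with coefficient +1,
#' and all bounds finite.
#'
#' @param model a `metabolic_model` (or an unclassed list with its fields,
#'   so that broken candidates can be inspected).
#' @return list of violations; each has elements `invariant`, `ids`,
#'   `message`.  Empty list iff the model is valid.
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(invariant, ids, message) {
    v[[length(v) + 1L]] <<- list(invariant = invariant, ids = ids,
                                 message = message)
  }
  mets <- model$mets; rxns <- model$rxns; S <- model$S
  if (!setequal(rownames(S), mets$id) || !setequal(colnames(S), rxns$id)) {
    add("stoichiometry_ids", character(0),
        "stoichiometry rows/cols do not match declared metabolites/reactions")
    return(v)
  }
  bad <- rxns$id[rxns$lb > rxns$ub]
  if (length(bad)) {
    add("bound_order", bad,
        paste0("lower bound exceeds upper bound: ", paste(bad, collapse = ", ")))
  }
  bad <- rxns$id[!rxns$reversible & rxns$lb < 0]
  if (length(bad)) {
    add("irreversible_sign", bad,
        paste0("irreversible reaction with negative lower bound: ",
               paste(bad, collapse = ", ")))
  }
  bad <- rxns$id[!is.finite(rxns$lb) | !is.finite(rxns$ub)]
  if (length(bad)) {
    add("finite_bounds", bad,
        paste0("unbounded flux (finite bounds required): ",
               paste(bad, collapse = ", ")))
  }
  ## growth-drain convention: the biomass reaction consumes exactly one
  ## internal biomass metabolite with unit coefficient; its rate is the
  ## specific growth rate
  if (!model$biomass_id %in% rxns$id) {
    add("biomass_present", model$biomass_id, "biomass reaction not found")
  } else {
    col <- S[, model$biomass_id]
    nz <- which(col != 0)
    if (length(nz) != 1L || col[nz] > 0) {
      add("biomass_metabolite", rownames(S)[nz],
          "biomass reaction must drain exactly one biomass metabolite")
    } else if (abs(abs(col[nz]) - 1) > 1e-12) {
      add("biomass_normalization", rownames(S)[nz],
          "biomass metabolite coefficient in the growth reaction must be 1")
    } else if (mets$external[match(rownames(S)[nz], mets$id)]) {
      add("biomass_internal", rownames(S)[nz],
          "biomass metabolite must be internal")
    }
  }
  if (!is.null(model$constraints)) {
    A <- model$constraints$A
    if (!all(colnames(A) %in% rxns$id)) {
      add("constraint_ids", setdiff(colnames(A), rxns$id),
          "extra-constraint columns reference unknown reactions")
    }
    if (nrow(A) != length(model$constraints$b)) {
      add("constraint_rows", character(0),
          "extra-constraint matrix and rhs length differ")
    }
  }
  if (!all(model$exchange_ids %in% rxns$id)) {
    add("exchange_ids", setdiff(model$exchange_ids, rxns$id),
        "exchange reaction ids not declared")
  }
  v
}

#' Biomass metabolite id of a model
#'
#' @param model a `metabolic_model`.
#' @return the id of the metabolite drained by the growth reaction.
#' @export
biomass_met <- function(model) {
  col <- model$S[, model$biomass_id]
  rownames(model$S)[which(col != 0)]
}

#' Stoichiometric matrix of the internal (balanced) metabolites
#'
#' External metabolites are unbalanced in single-species mode and produce no
#' row.
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix, rows = internal metabolite ids, cols = reaction ids.
#' @export
internal_stoichiometry <- function(model) {
  model$S[!model$mets$external, , drop = FALSE]
}

#' Exchange sub-matrix N^EX
#'
#' Rows are the external metabolites, columns the exchange reactions: the part
#' of the stoichiometry visible to the outside, used to turn projected EFVs
#' into net-conversion reactions.
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix, rows = external metabolite ids,
#'   cols = exchange reaction ids.
#' @export
exchange_stoichiometry <- function(model) {
  model$S[model$mets$external, model$exchange_ids, drop = FALSE]
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$species_id, "': ",
      nrow(x$mets), " metabolites (", sum(!x$mets$external), " internal), ",
      nrow(x$rxns), " reactions, biomass = ", x$biomass_id, "\n", sep = "")
  invisible(x)
}
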