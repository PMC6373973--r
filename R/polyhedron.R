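## Flux polyhedra: {r : N r = 0, fixed fluxes, lb <= r <= ub, A r <= b}.

#' Build the flux polyhedron of a model
#'
#' The feasible set is `{r : N r = 0, lb <= r <= ub, A r <= b, r_j = v_j}`
#' for the requested fixed fluxes (typically the growth reaction pinned to the
#' community growth rate).  `N` covers internal metabolites only.
#'
#' @param model a `metabolic_model`.
#' @param fixed_fluxes named numeric vector or list, reaction id -> value.
#' @return object of class `flux_polyhedron` with fields `reaction_ids`,
#'   `Aeq`/`beq` (stoichiometry plus one row per fixed flux), `lb`, `ub`,
#'   `Aub`/`bub` (extra inequalities), `irrev` (indices), `fixed_fluxes`.
#' @export
build_flux_polyhedron <- function(model, fixed_fluxes = NULL) {
  N <- internal_stoichiometry(model)
  ids <- model$rxns$id
  n <- length(ids)
  Aeq <- N
  beq <- rep(0, nrow(N))
  fixed <- unlist(fixed_fluxes)
  if (length(fixed)) {
    miss <- setdiff(names(fixed), ids)
    if (length(miss)) stop("fixed flux for unknown reaction: ",
                           paste(miss, collapse = ", "))
    for (id in names(fixed)) {
      j <- match(id, ids)
      if (fixed[[id]] < model$rxns$lb[j] - 1e-12 ||
          fixed[[id]] > model$rxns$ub[j] + 1e-12) {
        stop("infeasible fix: ", id, " = ", fixed[[id]],
             " outside declared bounds [", model$rxns$lb[j], ", ",
             model$rxns$ub[j], "]")
      }
      row <- rep(0, n); row[j] <- 1
      Aeq <- rbind(Aeq, row)
      beq <- c(beq, fixed[[id]])
      rownames(Aeq)[nrow(Aeq)] <- paste0("fix_", id)
    }
  }
  Aub <- NULL; bub <- NULL
  if (!is.null(model$constraints)) {
    Aub <- matrix(0, nrow(model$constraints$A), n)
    colnames(Aub) <- ids
    Aub[, colnames(model$constraints$A)] <- model$constraints$A
    bub <- model$constraints$b
  }
  .polyhedron(ids, Aeq, beq, model$rxns$lb, model$rxns$ub, Aub, bub,
              irrev = which(!model$rxns$reversible),
              fixed_fluxes = fixed)
}

.polyhedron <- function(reaction_ids, Aeq, beq, lb, ub, Aub = NULL,
                        bub = NULL, irrev = integer(0),
                        fixed_fluxes = NULL) {
  structure(list(reaction_ids = reaction_ids,
                 Aeq = Aeq, beq = beq, lb = lb, ub = ub,
                 Aub = Aub, bub = bub, irrev = irrev,
                 fixed_fluxes = fixed_fluxes),
            class = "flux_polyhedron")
}

#' @export
print.flux_polyhedron <- function(x, ...) {
  cat("Flux polyhedron: ", length(x$reaction_ids), " reactions, ",
      nrow(x$Aeq), " equality rows, ",
      if (is.null(x$Aub)) 0 else nrow(x$Aub), " extra inequality rows\n",
      sep = "")
  invisible(x)
}

#' Homogenize a flux polyhedron
#'
#' Standard lifting: append a coordinate `xi >= 0`; every inhomogeneous
#' constraint `a r <= b` becomes `a r - b xi <= 0` and fixed fluxes become
#' `r_j - v_j xi = 0`.  Points of the polyhedron correspond to cone elements
#' with `xi = 1`, homogeneous (recession) directions to `xi = 0`.
#'
#' @param poly a `flux_polyhedron`.
#' @return list with `Heq` (equalities over `(r, xi)`), `Hub`
#'   (inequalities `H (r, xi) <= 0`), `irrev`, `n` (reaction count).
#' @export
homogenize <- function(poly) {
  n <- length(poly$reaction_ids)
  Heq <- cbind(poly$Aeq, -poly$beq)
  rows <- list()
  for (j in seq_len(n)) {
    if (is.finite(poly$ub[j])) {
      row <- rep(0, n + 1); row[j] <- 1; row[n + 1] <- -poly$ub[j]
      rows[[length(rows) + 1L]] <- row
    }
    skip_lb <- (j %in% poly$irrev) && poly$lb[j] == 0
    if (is.finite(poly$lb[j]) && !skip_lb) {
      row <- rep(0, n + 1); row[j] <- -1; row[n + 1] <- poly$lb[j]
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!is.null(poly$Aub)) {
    for (i in seq_len(nrow(poly$Aub))) {
      rows[[length(rows) + 1L]] <- c(poly$Aub[i, ], -poly$bub[i])
    }
  }
  Hub <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0, n + 1)
  list(Heq = Heq, Hub = Hub, irrev = poly$irrev, n = n)
}
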