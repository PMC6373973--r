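## RedCom: reduced community models from minimal net conversions.
##
## Each species' bounded EFVs (computed at the fixed community growth rate)
## are projected onto its exchange reactions plus growth, redundant
## projections are collapsed, conversions dominated by a convex combination
## of the others are discarded (the minimality filter), and the survivors
## become irreversible net-conversion reactions of a two-compartment linear
## community model.

#' Project EFVs onto the exchange reactions
#'
#' Restricts each bounded EFV to the q exchange dimensions including the
#' growth rate.  Every exchange dimension is expressed as a non-negative
#' turnover: reversible exchange reactions contribute separate forward and
#' backward columns, so that "smaller or equal" in the dominance test
#' uniformly means no greater consumption and no greater secretion.
#'
#' @param efvs an `efv_set` computed at a fixed growth rate (the polyhedron
#'   must have pinned the biomass reaction).
#' @param model the `metabolic_model` the EFVs belong to.
#' @return object of class `projected_efvs`: `oriented` (rows = conversions,
#'   non-negative turnover columns plus `mu`), `signed` (exchange fluxes with
#'   sign, plus `mu`), `source_index`, `full_vectors` (the originating full
#'   EFVs, for unpacking), `species_id`, `mu_fix`.
#' @export
project_to_exchange <- function(efvs, model) {
  fixed <- efvs$fixed_fluxes
  if (is.null(fixed) || !model$biomass_id %in% names(fixed)) {
    stop("EFV set was not computed at a fixed growth rate; ",
         "fix the biomass reaction before enumeration")
  }
  mu_fix <- unname(fixed[[model$biomass_id]])
  exch <- setdiff(model$exchange_ids, model$biomass_id)
  if (length(exch) == 0L) stop("model '", model$species_id,
                               "' has no exchange reactions to project onto")
  B <- efvs$vectors[efvs$bounded, , drop = FALSE]
  signed <- cbind(B[, exch, drop = FALSE],
                  mu = B[, model$biomass_id])
  rev_flag <- !model$rxns$reversible[match(exch, model$rxns$id)]
  cols <- list(); ocols <- list()
  for (k in seq_along(exch)) {
    j <- exch[k]
    v <- B[, j]
    if (rev_flag[k]) {                      # irreversible: one turnover column
      ocols[[j]] <- pmax(v, 0)
    } else {
      ocols[[paste0(j, "__f")]] <- pmax(v, 0)
      ocols[[paste0(j, "__r")]] <- pmax(-v, 0)
    }
  }
  ocols[["mu"]] <- B[, model$biomass_id]
  oriented <- do.call(cbind, ocols)
  rownames(oriented) <- NULL
  structure(list(oriented = oriented, signed = signed,
                 exchange_ids = exch,
                 source_index = seq_len(nrow(B)),
                 full_vectors = B,
                 species_id = model$species_id, mu_fix = mu_fix),
            class = "projected_efvs")
}

#' @export
print.projected_efvs <- function(x, ...) {
  cat("Projected EFVs of '", x$species_id, "': ", nrow(x$oriented),
      " conversions at mu = ", x$mu_fix, "\n", sep = "")
  invisible(x)
}

.pm_subset <- function(pm, keep) {
  pm$oriented <- pm$oriented[keep, , drop = FALSE]
  pm$signed <- pm$signed[keep, , drop = FALSE]
  pm$source_index <- pm$source_index[keep]
  pm$full_vectors <- pm$full_vectors[keep, , drop = FALSE]
  pm
}

#' Collapse EFVs with identical exchange projection
#'
#' Rows equal within a relative max-norm tolerance are collapsed to one; the
#' one with the lowest source EFV index survives (deterministic given
#' deterministic enumeration order).
#'
#' @param pm a `projected_efvs`.
#' @param rel_tol relative tolerance for row identity.
#' @return the deduplicated `projected_efvs`.
#' @export
deduplicate_conversions <- function(pm, rel_tol = 1e-6) {
  n <- nrow(pm$oriented)
  if (n <= 1L) return(pm)
  ord <- order(pm$source_index)
  keep <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (k in keep) {
      d <- max(abs(pm$oriented[i, ] - pm$oriented[k, ]))
      if (d <= rel_tol * max(1, abs(pm$oriented[k, ]))) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  .pm_subset(pm, sort(keep))
}

#' Discard non-minimal conversions (convex dominance test)
#'
#' A projected EFV is discarded when a convex combination of the other
#' candidates has no larger turnover in every exchange dimension (growth
#' included): feasibility of `E* w <= e_k, sum(w) = 1, w >= 0`.  Because
#' convex dominations substitute transitively, a single pass testing each row
#' against all other candidates is order independent.
#'
#' @param pm a deduplicated `projected_efvs`.
#' @return the filtered `projected_efvs`, with attribute `certificates`: a
#'   list, one entry per discarded row, holding `source_index` and the
#'   dominating weights `w` (named by the source indices of the dominators).
#' @export
filter_minimal_conversions <- function(pm) {
  n <- nrow(pm$oriented)
  if (n <= 1L) {
    attr(pm, "certificates") <- list()
    return(pm)
  }
  E <- pm$oriented
  discard <- logical(n)
  certs <- list()
  for (k in seq_len(n)) {
    others <- setdiff(seq_len(n), k)
    ## feasibility LP in w: t(E[others,]) w <= E[k,], 1'w = 1, w >= 0
    res <- solve_lp(rep(0, length(others)),
                    Aeq = matrix(1, 1, length(others)), beq = 1,
                    Aub = t(E[others, , drop = FALSE]), bub = E[k, ],
                    lb = 0, ub = Inf)
    if (res$status == "optimal") {
      discard[k] <- TRUE
      certs[[length(certs) + 1L]] <- list(
        source_index = pm$source_index[k],
        w = stats::setNames(res$x, pm$source_index[others]))
    }
  }
  out <- .pm_subset(pm, which(!discard))
  attr(out, "certificates") <- certs
  out
}

#' Build the reduced single-species model N^red = N^EX E
#'
#' Each kept conversion becomes one irreversible reaction over the external
#' metabolites; unit flux reproduces the conversion's exchange turnovers and
#' produces the species biomass at rate `mu_fix`.
#'
#' @param model the original `metabolic_model`.
#' @param kept a filtered `projected_efvs`.
#' @return object of class `reduced_species_model`: `Nred` (external
#'   metabolites x conversions), `conv_ids`, `provenance` (full source EFVs),
#'   `species_id`, `mu_fix`, `biomass_met`.
#' @export
build_reduced_species <- function(model, kept) {
  if (nrow(kept$oriented) == 0L) {
    stop("species '", model$species_id, "' infeasible at mu_fix = ",
         kept$mu_fix, ": no conversions kept")
  }
  Nex <- exchange_stoichiometry(model)
  Nex <- Nex[, kept$exchange_ids, drop = FALSE]
  E <- t(kept$signed[, kept$exchange_ids, drop = FALSE])
  Nred <- Nex %*% E
  conv_ids <- paste0(model$species_id, "::conv", seq_len(ncol(Nred)))
  colnames(Nred) <- conv_ids
  structure(list(species_id = model$species_id,
                 mu_fix = kept$mu_fix,
                 Nred = Nred,
                 conv_ids = conv_ids,
                 ext_mets = rownames(Nred),
                 biomass_met = biomass_met(model),
                 provenance = list(rxn_ids = colnames(kept$full_vectors),
                                   full = kept$full_vectors,
                                   source_index = kept$source_index),
                 reversible = rep(FALSE, ncol(Nred))),
            class = "reduced_species_model")
}

#' @export
print.reduced_species_model <- function(x, ...) {
  cat("Reduced species model '", x$species_id, "': ", ncol(x$Nred),
      " net conversions over ", nrow(x$Nred), " exchange metabolites (mu = ",
      x$mu_fix, ")\n", sep = "")
  invisible(x)
}

#' Assemble the reduced community model
#'
#' Two compartments only — exchange and medium.  Conversion fluxes lambda are
#' the reactions; every exchange metabolite not allowed to accumulate is
#' balanced; biomass plumbing (BM_i -> BM_c -> export at mu_c) is retained so
#' the abundances are readable as F_i = sum of the species' conversion
#' fluxes.  Explicit F variables (with rows `sum lambda_i - F_i = 0` and
#' `sum F = 1`) make the mu_c = 0 case well-posed with the same construction;
#' for mu_c > 0 these rows are implied by the biomass balance.
#'
#' No abundance-scaled flux bounds are re-imposed: conversions inherit them
#' from the single-species EFVs (see [unpack_solution()]).
#'
#' @param reduced list of `reduced_species_model`s, all built at the same
#'   `mu_fix`.
#' @param medium a [medium_config()].
#' @param mu_c community growth rate; must equal the shared `mu_fix`.
#' @param big_m bound for uncapped medium exchanges.
#' @return object of class `reduced_community_model`; also a ready LP
#'   (`Aeq`, `beq`, `Aub`, `bub`, `lb`, `ub`, `vars`, `mu_c`) usable with
#'   [community_fba()], [fva()] and [maximize_yield()].
#' @export
assemble_reduced_community <- function(reduced, medium, mu_c,
                                       big_m = .BIG_M_DEFAULT) {
  mus <- vapply(reduced, `[[`, 0, "mu_fix")
  if (any(abs(mus - mu_c) > 1e-9)) {
    stop("reduced models were built at mu = ", paste(mus, collapse = ", "),
         " but the community growth rate is ", mu_c)
  }
  sids <- vapply(reduced, `[[`, "", "species_id")
  ext <- unique(unlist(lapply(reduced, `[[`, "ext_mets")))
  bad <- setdiff(c(medium$substrates, names(medium$accumulate)), ext)
  if (length(bad)) stop("medium references unknown exchange metabolites: ",
                        paste(bad, collapse = ", "))
  rows <- c(ext, paste0("BM::", sids), "BM_c")
  cols <- list(); meta <- list()
  for (r in reduced) {
    for (j in seq_along(r$conv_ids)) {
      v <- stats::setNames(rep(0, length(rows)), rows)
      v[rownames(r$Nred)] <- r$Nred[, j]
      v[paste0("BM::", r$species_id)] <- mu_c
      cols[[r$conv_ids[j]]] <- v
      meta[[r$conv_ids[j]]] <- data.frame(
        id = r$conv_ids[j], species = r$species_id, kind = "conversion",
        lb = 0, ub = Inf, stringsAsFactors = FALSE)
    }
  }
  for (s in sids) {                      # BM_i -> BM_c integration
    cid <- paste0("int::", s)
    v <- stats::setNames(rep(0, length(rows)), rows)
    v[paste0("BM::", s)] <- -1; v["BM_c"] <- 1
    cols[[cid]] <- v
    meta[[cid]] <- data.frame(id = cid, species = s, kind = "integration",
                              lb = 0, ub = Inf, stringsAsFactors = FALSE)
  }
  v <- stats::setNames(rep(0, length(rows)), rows)
  v["BM_c"] <- -1
  cols[["community_growth"]] <- v
  meta[["community_growth"]] <- data.frame(
    id = "community_growth", species = NA, kind = "community_growth",
    lb = mu_c, ub = mu_c, stringsAsFactors = FALSE)
  for (k in seq_along(medium$substrates)) {
    s <- medium$substrates[k]
    v <- stats::setNames(rep(0, length(rows)), rows)
    v[s] <- 1
    cid <- paste0("EX::", s, "::up")
    cap <- medium$uptake_caps[k]
    cols[[cid]] <- v
    meta[[cid]] <- data.frame(id = cid, species = NA, kind = "medium", lb = 0,
                              ub = if (is.finite(cap)) cap else big_m,
                              stringsAsFactors = FALSE)
  }
  for (p in names(medium$accumulate)[unlist(medium$accumulate)]) {
    v <- stats::setNames(rep(0, length(rows)), rows)
    v[p] <- -1
    cid <- paste0("EX::", p, "::acc")
    cols[[cid]] <- v
    meta[[cid]] <- data.frame(id = cid, species = NA, kind = "medium", lb = 0,
                              ub = big_m, stringsAsFactors = FALSE)
  }
  S <- do.call(cbind, cols)
  rownames(S) <- rows
  meta <- do.call(rbind, meta)
  ## LP view with explicit abundance variables
  ns <- length(sids)
  nc <- ncol(S)
  vars <- c(colnames(S), paste0("F::", sids))
  Aeq <- cbind(S, matrix(0, nrow(S), ns))
  beq <- rep(0, nrow(S))
  fidx <- nc + seq_len(ns)
  for (i in seq_len(ns)) {               # sum of conversions = F_i
    row <- rep(0, nc + ns)
    row[which(meta$kind == "conversion" & meta$species == sids[i])] <- 1
    row[fidx[i]] <- -1
    Aeq <- rbind(Aeq, row); beq <- c(beq, 0)
  }
  row <- rep(0, nc + ns); row[fidx] <- 1   # sum F = 1 (normalization)
  Aeq <- rbind(Aeq, row); beq <- c(beq, 1)
  rownames(Aeq) <- NULL
  lb <- c(meta$lb, rep(0, ns))
  ub <- c(meta$ub, rep(1, ns))
  structure(list(species_ids = sids, reduced = reduced, medium = medium,
                 S = S, meta = meta, mu_c = mu_c,
                 Aeq = Aeq, beq = beq, Aub = NULL, bub = NULL,
                 lb = lb, ub = ub, vars = vars, F_idx = fidx),
            class = "reduced_community_model")
}

#' @export
print.reduced_community_model <- function(x, ...) {
  cat("Reduced community model: ", length(x$species_ids), " species, ",
      sum(x$meta$kind == "conversion"), " net conversions, mu_c = ",
      x$mu_c, "\n", sep = "")
  invisible(x)
}

#' Community EFVs of a reduced model
#'
#' Elementary flux vectors of the reduced community polyhedron (not to be
#' confused with the single-species EFVs the model was built from).  Each
#' bounded community EFV is annotated with its abundance vector and medium
#' exchange rates.
#'
#' @param rcm a `reduced_community_model`.
#' @param ... passed to [enumerate_efvs()].
#' @return an `efv_set` with an `annotation` attribute (data.frame: one row
#'   per bounded EFV with `F::*` and `EX::*` columns).
#' @export
community_efvs <- function(rcm, ...) {
  poly <- .polyhedron(rcm$vars, rcm$Aeq, rcm$beq, rcm$lb, rcm$ub,
                      rcm$Aub, rcm$bub,
                      irrev = which(rcm$lb >= 0),
                      fixed_fluxes = stats::setNames(rcm$mu_c,
                                                     "community_growth"))
  ev <- enumerate_efvs(poly, ...)
  B <- ev$vectors[ev$bounded, , drop = FALSE]
  keep <- grep("^(F::|EX::)", colnames(B), value = TRUE)
  ann <- as.data.frame(B[, keep, drop = FALSE])
  attr(ev, "annotation") <- ann
  ev
}

#' Unpack a reduced-community solution into full flux vectors
#'
#' Reconstructs, for every species, the community-scale flux distribution
#' `r_i = sum_j lambda_j e_j` from the stored full EFVs behind each kept
#' conversion, and checks that it satisfies the abundance-scaled constraints
#' (bounds, extra inequalities, irreversibilities) at `F_i = sum lambda_j` —
#' the consistency property that lets the reduced model drop those
#' constraints.
#'
#' @param rcm a `reduced_community_model`.
#' @param solution named flux vector over `rcm$vars` (e.g. `community_fba()$x`
#'   or a row of [community_efvs()] vectors).
#' @param models the original `metabolic_model`s (named or in species order).
#' @return list per species: `flux` (named, community scale), `F`,
#'   `max_violation` (largest constraint violation, should be ~0).
#' @export
unpack_solution <- function(rcm, solution, models) {
  stopifnot(!is.null(names(solution)))
  mods <- stats::setNames(models, vapply(models, `[[`, "", "species_id"))
  out <- list()
  for (r in rcm$reduced) {
    if (is.null(r$provenance$full)) {
      stop("no stored full EFVs for species '", r$species_id,
           "'; re-run the pipeline with keep_full_efvs = TRUE")
    }
    lam <- solution[r$conv_ids]
    if (anyNA(lam)) stop("solution lacks conversion fluxes for ",
                         r$species_id)
    flux <- as.numeric(lam %*% r$provenance$full)
    names(flux) <- r$provenance$rxn_ids
    Fi <- sum(lam)
    m <- mods[[r$species_id]]
    viol <- max(0,
                m$rxns$lb[match(names(flux), m$rxns$id)] * Fi - flux,
                flux - m$rxns$ub[match(names(flux), m$rxns$id)] * Fi)
    if (!is.null(m$constraints)) {
      lhs <- as.numeric(m$constraints$A %*%
                          flux[colnames(m$constraints$A)])
      viol <- max(viol, lhs - m$constraints$b * Fi)
    }
    irr <- m$rxns$id[!m$rxns$reversible]
    viol <- max(viol, -flux[irr])
    out[[r$species_id]] <- list(flux = flux, F = Fi, max_violation = viol)
  }
  out
}

#' Run the full RedCom reduction pipeline
#'
#' enumerate -> project -> deduplicate -> filter -> build reduced species ->
#' assemble reduced community -> analyze.  Stage failures are re-signalled
#' with the stage name.
#'
#' @param models list of `metabolic_model`s.
#' @param medium a [medium_config()].
#' @param mu_c community growth rate the reduction is built for.
#' @param compute_efvs also enumerate the community EFVs of the reduced model.
#' @param fva_quantities quantities for reduced-model FVA (default: all
#'   abundances and medium exchanges).
#' @param ... passed to [enumerate_efvs()] for the single-species stage.
#' @return list with `rcm`, `efvs` (or NULL), `ranges`, and `report` (stage
#'   counts, per-species discard certificates, tolerances).
#' @export
redcom_pipeline <- function(models, medium, mu_c, compute_efvs = TRUE,
                            fva_quantities = NULL, ...) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  t0 <- Sys.time()
  report <- list(mu_c = mu_c, zero_tolerance = .EFV_ZERO_TOL,
                 dedup_tolerance = 1e-6, species = list())
  reduced <- list()
  for (m in models) {
    poly <- stage(paste0("build_flux_polyhedron (", m$species_id, ")"),
                  build_flux_polyhedron(m, stats::setNames(mu_c, m$biomass_id)))
    ev <- stage(paste0("enumerate_efvs (", m$species_id, ")"),
                enumerate_efvs(poly, ...))
    pm <- stage(paste0("project_to_exchange (", m$species_id, ")"),
                project_to_exchange(ev, m))
    dd <- stage(paste0("deduplicate (", m$species_id, ")"),
                deduplicate_conversions(pm))
    ft <- stage(paste0("filter_minimal_conversions (", m$species_id, ")"),
                filter_minimal_conversions(dd))
    rs <- stage(paste0("build_reduced_species (", m$species_id, ")"),
                build_reduced_species(m, ft))
    reduced[[m$species_id]] <- rs
    report$species[[m$species_id]] <- list(
      efvs_bounded = sum(ev$bounded), efvs_unbounded = sum(!ev$bounded),
      projected = nrow(pm$oriented), deduplicated = nrow(dd$oriented),
      kept = nrow(ft$oriented),
      certificates = attr(ft, "certificates"))
  }
  rcm <- stage("assemble_reduced_community",
               assemble_reduced_community(reduced, medium, mu_c))
  efvs <- NULL
  if (compute_efvs) {
    efvs <- stage("community_efvs", community_efvs(rcm))
    report$community_efvs <- sum(efvs$bounded)
  }
  if (is.null(fva_quantities)) {
    fva_quantities <- c(grep("^F::", rcm$vars, value = TRUE),
                        grep("^EX::", rcm$vars, value = TRUE))
  }
  ranges <- stage("fva", fva(rcm, fva_quantities))
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(rcm = rcm, efvs = efvs, ranges = ranges, report = report)
}
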