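## Compartmented full community models under balanced growth.
##
## Each species is a compartment; former external metabolites are merged by
## id into a shared exchange compartment and become balanced.  The growth
## drain of species i is retargeted to produce community biomass BM_c (its
## flux is r_BMi->BMc = mu~_i), and one community growth reaction exports
## BM_c at rate mu_c.  Abundances F_i and mu_c make the model bilinear; it is
## analyzed through the mu_c-fixed linearization.

#' Medium configuration
#'
#' @param substrates character vector of external metabolite ids with
#'   community uptake allowed; optionally named numeric to cap the
#'   community-level uptake rate (mmol/gDW_c/h).
#' @param accumulate named logical: may the metabolite accumulate in
#'   (leave to) the medium?  Metabolites not listed default to `FALSE`
#'   (strict mass balance).
#' @param co2_uptake_allowed convenience flag kept alongside (scenario
#'   builders translate it into `substrates`).
#' @return object of class `medium_config`.
#' @export
medium_config <- function(substrates = character(0),
                          accumulate = logical(0),
                          co2_uptake_allowed = FALSE) {
  caps <- rep(Inf, length(substrates))
  if (is.numeric(substrates)) {
    caps <- unname(substrates)
    substrates <- names(substrates)
  }
  structure(list(substrates = substrates, uptake_caps = caps,
                 accumulate = accumulate,
                 co2_uptake_allowed = co2_uptake_allowed),
            class = "medium_config")
}

#' Assemble the full (compartmented) community model
#'
#' @param models list of `metabolic_model`s with distinct `species_id`s.
#' @param medium a [medium_config()]; every referenced metabolite must be an
#'   external metabolite of at least one member.
#' @param big_m bound magnitude for medium exchange reactions without caps.
#' @return object of class `community_model`: merged stoichiometry `S`
#'   (rows: species-prefixed internal metabolites, exchange-compartment
#'   metabolites, `BM_c`), a `cols` table describing every column (species
#'   reactions, community growth, medium exchanges) with species-scale
#'   bounds, and per-species extra constraints.
#' @export
assemble_full_community <- function(models, medium, big_m = .BIG_M_DEFAULT) {
  stopifnot(length(models) >= 1)
  sids <- vapply(models, `[[`, "", "species_id")
  if (anyDuplicated(sids)) stop("duplicate species_id: ",
                                paste(sids[duplicated(sids)], collapse = ", "))
  all_ext <- unique(unlist(lapply(models, function(m) m$mets$id[m$mets$external])))
  bad <- setdiff(c(medium$substrates, names(medium$accumulate)), all_ext)
  if (length(bad)) stop("medium references unknown external metabolites: ",
                        paste(bad, collapse = ", "))
  rows <- c(unlist(lapply(models, function(m)
    paste0(m$species_id, "::", m$mets$id[!m$mets$external]))),
    all_ext, "BM_c")
  cols <- list(); Scols <- list()
  for (m in models) {
    internal <- paste0(m$species_id, "::", m$mets$id[!m$mets$external])
    for (j in seq_len(nrow(m$rxns))) {
      cid <- paste0(m$species_id, "::", m$rxns$id[j])
      v <- stats::setNames(rep(0, length(rows)), rows)
      sj <- m$S[, j]
      nz <- which(sj != 0)
      for (i in nz) {
        met <- rownames(m$S)[i]
        key <- if (m$mets$external[i]) met else paste0(m$species_id, "::", met)
        v[key] <- v[key] + sj[i]
      }
      is_growth <- m$rxns$id[j] == m$biomass_id
      if (is_growth) v["BM_c"] <- v["BM_c"] + 1   # biomass integration BM_i -> BM_c
      cols[[cid]] <- data.frame(
        id = cid, species = m$species_id, rxn = m$rxns$id[j],
        lb = m$rxns$lb[j], ub = m$rxns$ub[j],
        irrev = !m$rxns$reversible[j], kind = if (is_growth) "growth" else "species",
        stringsAsFactors = FALSE)
      Scols[[cid]] <- v
    }
  }
  ## community growth reaction: exports BM_c at rate mu_c
  v <- stats::setNames(rep(0, length(rows)), rows)
  v["BM_c"] <- -1
  cols[["community_growth"]] <- data.frame(
    id = "community_growth", species = NA, rxn = NA, lb = 0, ub = Inf,
    irrev = TRUE, kind = "community_growth", stringsAsFactors = FALSE)
  Scols[["community_growth"]] <- v
  ## medium exchange reactions: uptake for substrates, export for accumulants
  for (k in seq_along(medium$substrates)) {
    s <- medium$substrates[k]
    v <- stats::setNames(rep(0, length(rows)), rows)
    v[s] <- 1
    cid <- paste0("EX::", s, "::up")
    cap <- medium$uptake_caps[k]
    cols[[cid]] <- data.frame(id = cid, species = NA, rxn = NA, lb = 0,
                              ub = if (is.finite(cap)) cap else big_m,
                              irrev = TRUE, kind = "medium",
                              stringsAsFactors = FALSE)
    Scols[[cid]] <- v
  }
  for (p in names(medium$accumulate)[unlist(medium$accumulate)]) {
    v <- stats::setNames(rep(0, length(rows)), rows)
    v[p] <- -1
    cid <- paste0("EX::", p, "::acc")
    cols[[cid]] <- data.frame(id = cid, species = NA, rxn = NA, lb = 0,
                              ub = big_m, irrev = TRUE, kind = "medium",
                              stringsAsFactors = FALSE)
    Scols[[cid]] <- v
  }
  S <- do.call(cbind, Scols)
  rownames(S) <- rows
  colnames(S) <- names(Scols)
  structure(list(members = models, medium = medium,
                 species_ids = sids,
                 S = S, cols = do.call(rbind, cols),
                 exchange_mets = all_ext, big_m = big_m),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("Community model: ", length(x$members), " species (",
      paste(x$species_ids, collapse = ", "), "), ",
      nrow(x$S), " balanced metabolites, ", ncol(x$S), " reactions\n",
      sep = "")
  invisible(x)
}

#' Linearize the community model at a fixed community growth rate
#'
#' With mu_c fixed, the balanced-growth coupling rows (one per species except
#' the last, whose row is implied) and the abundance-scaled bounds become
#' linear in the joint variable vector (fluxes, F).  At mu_c = 0 the coupling
#' rows degenerate to zero growth flux while `sum(F) = 1` is retained.
#'
#' @param cm a `community_model`.
#' @param mu_c community growth rate, 1/h (>= 0).
#' @return object of class `community_lp`: fields `Aeq`, `beq`, `Aub`,
#'   `bub`, `lb`, `ub`, `vars` (column ids, then `F::<species>`), `mu_c`.
#' @export
linearize_fix_mu <- function(cm, mu_c) {
  stopifnot(mu_c >= 0)
  nc <- ncol(cm$S)
  ns <- length(cm$members)
  vars <- c(colnames(cm$S), paste0("F::", cm$species_ids))
  fidx <- nc + seq_len(ns)
  Aeq <- cbind(cm$S, matrix(0, nrow(cm$S), ns))
  beq <- rep(0, nrow(cm$S))
  ## balanced-growth coupling for the first n-1 species (the n-th is implied)
  if (ns > 1) {
    for (i in seq_len(ns - 1)) {
      gcol <- which(cm$cols$kind == "growth" &
                      cm$cols$species == cm$species_ids[i])
      row <- rep(0, nc + ns)
      row[gcol] <- 1
      row[fidx[i]] <- -mu_c
      Aeq <- rbind(Aeq, row)
      beq <- c(beq, 0)
    }
  }
  ## sum F = 1
  row <- rep(0, nc + ns); row[fidx] <- 1
  Aeq <- rbind(Aeq, row); beq <- c(beq, 1)
  rownames(Aeq) <- NULL
  ## abundance-scaled bounds and extra constraints
  Aub <- NULL; bub <- NULL
  sp_cols <- which(cm$cols$kind %in% c("species", "growth"))
  nrows <- 2L * length(sp_cols)
  Aub <- matrix(0, 0, nc + ns)
  bub <- numeric(0)
  for (j in sp_cols) {
    fi <- fidx[match(cm$cols$species[j], cm$species_ids)]
    r1 <- rep(0, nc + ns); r1[j] <- 1; r1[fi] <- -cm$cols$ub[j]
    r2 <- rep(0, nc + ns); r2[j] <- -1; r2[fi] <- cm$cols$lb[j]
    Aub <- rbind(Aub, r1, r2)
    bub <- c(bub, 0, 0)
  }
  for (m in cm$members) {
    if (is.null(m$constraints)) next
    A <- m$constraints$A
    fi <- fidx[match(m$species_id, cm$species_ids)]
    for (i in seq_len(nrow(A))) {
      row <- rep(0, nc + ns)
      for (rid in colnames(A)) {
        row[match(paste0(m$species_id, "::", rid), vars)] <- A[i, rid]
      }
      row[fi] <- -m$constraints$b[i]
      Aub <- rbind(Aub, row)
      bub <- c(bub, 0)
    }
  }
  rownames(Aub) <- NULL
  ## variable boxes: species fluxes live within their unscaled bounds
  ## (F <= 1), medium/community columns use their own bounds
  lb <- c(pmin(cm$cols$lb, 0), rep(0, ns))
  ub <- c(pmax(cm$cols$ub, 0), rep(1, ns))
  gc <- which(cm$cols$kind == "community_growth")
  lb[gc] <- mu_c; ub[gc] <- mu_c
  med <- which(cm$cols$kind == "medium")
  lb[med] <- cm$cols$lb[med]; ub[med] <- cm$cols$ub[med]
  structure(list(Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
                 lb = lb, ub = ub, vars = vars, mu_c = mu_c,
                 F_idx = fidx, cm = cm),
            class = "community_lp")
}

## resolve a quantity (variable id or named coefficient vector) to an
## objective vector over lp$vars
.quantity_vec <- function(lp, q) {
  v <- rep(0, length(lp$vars))
  if (is.character(q) && length(q) == 1L) {
    j <- match(q, lp$vars)
    if (is.na(j)) stop("unknown quantity: ", q)
    v[j] <- 1
  } else if (is.numeric(q) && !is.null(names(q))) {
    j <- match(names(q), lp$vars)
    if (anyNA(j)) stop("unknown quantity ids: ",
                       paste(names(q)[is.na(j)], collapse = ", "))
    v[j] <- q
  } else stop("quantity must be a variable id or a named numeric vector")
  v
}

#' Community flux balance analysis
#'
#' Optimizes a linear objective over the linearized community model.
#'
#' @param lp a `community_lp` (or `reduced_community_model` LP view).
#' @param objective variable id or named coefficient vector.
#' @param maximize direction (default TRUE).
#' @return list with `status`, `objective`, `x` (named fluxes), `F`
#'   (named abundances) and `mu_c`.
#' @export
community_fba <- function(lp, objective, maximize = TRUE) {
  obj <- .quantity_vec(lp, objective)
  res <- solve_lp(obj, lp$Aeq, lp$beq, lp$Aub, lp$bub, lp$lb, lp$ub,
                  maximize = maximize)
  x <- stats::setNames(res$x, lp$vars)
  Fv <- x[grep("^F::", lp$vars)]
  names(Fv) <- sub("^F::", "", names(Fv))
  list(status = res$status, objective = res$obj, x = x, F = Fv,
       mu_c = lp$mu_c)
}

#' Maximum community growth rate (doubling/bisection scheme)
#'
#' Starts at 0.005 1/h, doubles while the mu_c-fixed linearization stays
#' feasible, then repeatedly averages the last feasible and infeasible values
#' until they differ by less than `tol`.  Feasibility is checked with a zero
#' objective.
#'
#' @param cm a `community_model`, or a function(mu) returning an LP-like list
#'   (used by the reduced-model route).
#' @param tol termination tolerance, 1/h (default 1e-5).
#' @param mu_start first probed growth rate (default 0.005 1/h).
#' @return the maximum feasible mu_c (last feasible value), or `NA_real_`
#'   when even mu_c = 0 is infeasible (no feasible community).
#' @export
find_mu_max <- function(cm, tol = 1e-5, mu_start = 0.005) {
  make_lp <- if (is.function(cm)) cm else function(mu) linearize_fix_mu(cm, mu)
  feasible <- function(mu) {
    ## a model that cannot even be built at this rate (growth pinned above a
    ## species' capacity) counts as infeasible
    lp <- tryCatch(make_lp(mu), error = function(e) NULL)
    if (is.null(lp)) return(FALSE)
    .lp_feasible(lp$Aeq, lp$beq, lp$Aub, lp$bub, lp$lb, lp$ub)
  }
  mu <- mu_start
  if (!feasible(mu)) {
    if (!feasible(0)) return(NA_real_)
    lo <- 0; hi <- mu
  } else {
    repeat {
      mu2 <- 2 * mu
      if (!feasible(mu2)) { lo <- mu; hi <- mu2; break }
      mu <- mu2
      if (mu > 1e6) stop("growth rate appears unbounded; check flux bounds")
    }
  }
  while (hi - lo >= tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Flux variability analysis
#'
#' Minimizes and maximizes each requested quantity over the feasible set of a
#' linearized community model.
#'
#' @param lp a `community_lp`.
#' @param quantities character vector of variable ids (fluxes or
#'   `F::<species>`) and/or a named list of coefficient vectors.
#' @return data.frame with columns `quantity`, `min`, `max`.
#' @export
fva <- function(lp, quantities) {
  if (is.character(quantities)) quantities <- as.list(quantities)
  qnames <- vapply(seq_along(quantities), function(i) {
    if (!is.null(names(quantities)[i]) && nzchar(names(quantities)[i]))
      names(quantities)[i]
    else if (is.character(quantities[[i]])) quantities[[i]]
    else paste0("q", i)
  }, "")
  out <- data.frame(quantity = qnames, min = NA_real_, max = NA_real_)
  for (i in seq_along(quantities)) {
    obj <- .quantity_vec(lp, quantities[[i]])
    lo <- solve_lp(obj, lp$Aeq, lp$beq, lp$Aub, lp$bub, lp$lb, lp$ub)
    hi <- solve_lp(obj, lp$Aeq, lp$beq, lp$Aub, lp$bub, lp$lb, lp$ub,
                   maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA infeasible at mu_c = ", lp$mu_c)
    }
    out$min[i] <- lo$obj; out$max[i] <- hi$obj
  }
  out
}

#' Maximize a linear-fractional yield
#'
#' Optimum of `(num' x) / (den' x)` over the linearized model via the
#' Charnes-Cooper transformation.  The denominator must be sign-definite over
#' the feasible set (checked with two auxiliary LPs).
#'
#' @param lp a `community_lp`.
#' @param numerator,denominator variable ids or named coefficient vectors.
#' @param maximize direction.
#' @return list with `value` and `x` (witness solution in original scale).
#' @export
maximize_yield <- function(lp, numerator, denominator, maximize = TRUE) {
  cnum <- .quantity_vec(lp, numerator)
  cden <- .quantity_vec(lp, denominator)
  dmin <- solve_lp(cden, lp$Aeq, lp$beq, lp$Aub, lp$bub, lp$lb, lp$ub)
  dmax <- solve_lp(cden, lp$Aeq, lp$beq, lp$Aub, lp$bub, lp$lb, lp$ub,
                   maximize = TRUE)
  if (dmin$status != "optimal") stop("yield: model infeasible at mu_c = ", lp$mu_c)
  sgn <- if (dmin$obj > 1e-9) 1 else if (dmax$obj < -1e-9) -1 else
    stop("yield denominator can vanish over the feasible set; ",
         "add a lower bound on the denominator flux")
  ## Charnes-Cooper: z = t x, t > 0, den' z = sgn (so t = sgn / (den' x) > 0)
  n <- length(lp$vars)
  nz <- n + 1L
  Aeq <- cbind(lp$Aeq, -lp$beq)
  beq <- rep(0, nrow(lp$Aeq))
  Aeq <- rbind(Aeq, c(cden, 0))
  beq <- c(beq, sgn)
  Aub <- if (!is.null(lp$Aub)) cbind(lp$Aub, -lp$bub) else NULL
  bub <- if (!is.null(lp$Aub)) rep(0, nrow(lp$Aub)) else NULL
  ## variable boxes become rows z - ub t <= 0, -z + lb t <= 0
  for (j in seq_len(n)) {
    if (is.finite(lp$ub[j])) {
      row <- rep(0, nz); row[j] <- 1; row[nz] <- -lp$ub[j]
      Aub <- rbind(Aub, row); bub <- c(bub, 0)
    }
    if (is.finite(lp$lb[j])) {
      row <- rep(0, nz); row[j] <- -1; row[nz] <- lp$lb[j]
      Aub <- rbind(Aub, row); bub <- c(bub, 0)
    }
  }
  res <- solve_lp(c(cnum * sgn, 0), Aeq, beq, Aub, bub,
                  lb = c(rep(-Inf, n), 0), ub = Inf, maximize = maximize)
  if (res$status != "optimal") stop("yield optimization failed: ", res$status)
  t <- res$x[nz]
  x <- if (t > 1e-12) stats::setNames(res$x[seq_len(n)] / t, lp$vars) else NULL
  list(value = res$obj * sgn, x = x)
}
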