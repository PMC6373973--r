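## Elementary flux vectors.
##
## Bounded EFVs are the vertices of the homogenized, reversible-split
## polyhedron (xi = 1 after rescaling), unbounded EFVs the extreme rays of its
## recession cone (xi = 0).  Elementarity is support-minimality in the split,
## homogenized coordinate system.

.EFV_ZERO_TOL <- 1e-9

#' Enumerate the elementary flux vectors of a flux polyhedron
#'
#' Double description on the homogenized cone: reversible reactions are split
#' into forward/backward parts, inequality rows receive slack coordinates, the
#' extreme rays of the resulting pointed cone `{z >= 0 : M z = 0}` are
#' computed incrementally, futile forward+backward two-cycles are discarded,
#' and rays are classified by their homogenization coordinate.
#'
#' @param poly a `flux_polyhedron`.
#' @param max_reactions refuse enumeration above this many reactions unless
#'   `force = TRUE` (combinatorial explosion guard).
#' @param force override the size guard.
#' @param zero_tol zero threshold after per-ray max-norm scaling.
#' @return an `efv_set`: list with `vectors` (one EFV per row, columns =
#'   reaction ids; bounded rows are feasible points, unbounded rows max-norm-1
#'   directions), `bounded` (logical per row), `zero_tolerance` and the
#'   polyhedron's `fixed_fluxes`.
#' @export
enumerate_efvs <- function(poly, max_reactions = 400, force = FALSE,
                           zero_tol = .EFV_ZERO_TOL) {
  n <- length(poly$reaction_ids)
  if (n > max_reactions && !force) {
    stop("polyhedron has ", n, " reactions (limit ", max_reactions,
         "); use force = TRUE to enumerate anyway")
  }
  h <- homogenize(poly)
  rev_idx <- setdiff(seq_len(n), poly$irrev)
  ## split map T: (r, xi) = T z with z = (y_irrev/fwd, y_bwd, xi)
  d_split <- n + length(rev_idx) + 1L
  Tmap <- matrix(0, n + 1L, d_split)
  for (j in seq_len(n)) Tmap[j, j] <- 1
  if (length(rev_idx)) {
    Tmap[cbind(rev_idx, n + seq_along(rev_idx))] <- -1
  }
  Tmap[n + 1L, d_split] <- 1
  Eq <- h$Heq %*% Tmap
  G <- h$Hub %*% Tmap
  s <- nrow(G)
  M <- rbind(cbind(Eq, matrix(0, nrow(Eq), s)),
             cbind(G, diag(1, s)))
  rays <- .dd_rays(M, zero_tol)
  if (ncol(rays) == 0L) {
    return(.efv_set(matrix(0, 0, n, dimnames = list(NULL, poly$reaction_ids)),
                    logical(0), zero_tol, poly$fixed_fluxes))
  }
  ## map back to (r, xi); drop futile cycles / pure-slack rays
  rx <- Tmap %*% rays[seq_len(d_split), , drop = FALSE]
  keep <- apply(abs(rx), 2, max) > zero_tol
  rx <- rx[, keep, drop = FALSE]
  .efv_from_rx(rx, n, poly$reaction_ids, zero_tol, poly$fixed_fluxes)
}

## shared post-processing: columns of rx are (r, xi) rays
.efv_from_rx <- function(rx, n, reaction_ids, zero_tol, fixed_fluxes) {
  if (ncol(rx) == 0L) {
    return(.efv_set(matrix(0, 0, n, dimnames = list(NULL, reaction_ids)),
                    logical(0), zero_tol, fixed_fluxes))
  }
  xi <- rx[n + 1L, ]
  scale <- apply(abs(rx), 2, max)
  bounded <- xi > zero_tol * pmax(1, scale)
  vec <- matrix(0, ncol(rx), n, dimnames = list(NULL, reaction_ids))
  for (k in seq_len(ncol(rx))) {
    vec[k, ] <- if (bounded[k]) rx[seq_len(n), k] / xi[k]
                else rx[seq_len(n), k] / max(abs(rx[seq_len(n), k]))
  }
  ## deduplicate (distinct split rays can recombine to the same flux vector)
  key <- apply(round(vec / pmax(1, apply(abs(vec), 1, max)), 9), 1, paste,
               collapse = "|")
  key <- paste(key, bounded)
  first <- !duplicated(key)
  .efv_set(vec[first, , drop = FALSE], bounded[first], zero_tol, fixed_fluxes)
}

.efv_set <- function(vectors, bounded, zero_tolerance, fixed_fluxes = NULL) {
  structure(list(vectors = vectors, bounded = bounded,
                 zero_tolerance = zero_tolerance,
                 fixed_fluxes = fixed_fluxes),
            class = "efv_set")
}

#' @export
print.efv_set <- function(x, ...) {
  cat("EFV set: ", sum(x$bounded), " bounded, ", sum(!x$bounded),
      " unbounded, over ", ncol(x$vectors), " reactions\n", sep = "")
  invisible(x)
}

## double description for {z >= 0 : M z = 0}; returns generators as columns
.dd_rays <- function(M, zero_tol = .EFV_ZERO_TOL) {
  d <- ncol(M)
  R <- diag(1, d)
  ## Fukuda-style ordering: process dense rows last
  ord <- order(rowSums(M != 0))
  for (ri in ord) {
    m <- M[ri, ]
    if (all(m == 0)) next
    v <- as.numeric(m %*% R)
    vtol <- zero_tol * max(1, abs(m)) * apply(abs(R), 2, max)
    zero <- abs(v) <= vtol
    pos <- which(!zero & v > 0)
    neg <- which(!zero & v < 0)
    Zl <- abs(R) <= zero_tol * rep(pmax(1, apply(abs(R), 2, max)),
                                   each = nrow(R))
    newrays <- list()
    for (p in pos) {
      for (q in neg) {
        mask <- Zl[, p] & Zl[, q]
        ## adjacency: no third ray's zero set contains Z(p) & Z(q)
        cnt <- colSums(Zl[mask, , drop = FALSE])
        dom <- which(cnt == sum(mask))
        if (length(setdiff(dom, c(p, q)))) next
        r_new <- v[p] * R[, q] - v[q] * R[, p]
        r_new <- r_new / max(abs(r_new))
        r_new[abs(r_new) <= zero_tol] <- 0
        newrays[[length(newrays) + 1L]] <- r_new
      }
    }
    R <- cbind(R[, zero, drop = FALSE],
               if (length(newrays)) do.call(cbind, newrays))
    if (is.null(R) || ncol(R) == 0L) {
      return(matrix(0, d, 0))
    }
  }
  R
}

#' Brute-force EFV enumeration (exact oracle)
#'
#' Independent of the double-description path: enumerates vertices and
#' extreme rays of the polyhedron restricted to every sign orthant of the
#' reversible reactions, by exhaustive active-set combinations solved with
#' fraction-free exact integer arithmetic (Cramer / maximal minors).  Intended
#' for small instances only.
#'
#' @param poly a `flux_polyhedron`.
#' @param max_split refusal limit on reactions counted after reversible
#'   splitting.
#' @return an `efv_set` (same invariants as [enumerate_efvs()]).
#' @export
brute_force_vertices <- function(poly, max_split = 20L) {
  n <- length(poly$reaction_ids)
  rev_idx <- setdiff(seq_len(n), poly$irrev)
  if (n + length(rev_idx) > max_split) {
    stop("oracle limit exceeded: ", n + length(rev_idx),
         " reactions after splitting (max ", max_split, ")")
  }
  ## integer-scaled equality rows [Aeq | beq]
  EQ <- .int_rows(cbind(poly$Aeq, poly$beq))
  EQc <- EQ[, seq_len(n), drop = FALSE]
  ## inequality rows a r <= b (bounds, extra constraints)
  ineq <- list()
  for (j in seq_len(n)) {
    if (is.finite(poly$ub[j])) {
      row <- rep(0, n + 1); row[j] <- 1; row[n + 1] <- poly$ub[j]
      ineq[[length(ineq) + 1L]] <- row
    }
    if (is.finite(poly$lb[j])) {
      row <- rep(0, n + 1); row[j] <- -1; row[n + 1] <- -poly$lb[j]
      ineq[[length(ineq) + 1L]] <- row
    }
  }
  if (!is.null(poly$Aub)) {
    for (i in seq_len(nrow(poly$Aub))) {
      ineq[[length(ineq) + 1L]] <- c(poly$Aub[i, ], poly$bub[i])
    }
  }
  base_ineq <- if (length(ineq)) .int_rows(do.call(rbind, ineq)) else matrix(0, 0, n + 1)

  verts <- list(); vkeys <- character(0)
  rays <- list(); rkeys <- character(0)
  n_orth <- 2^length(rev_idx)
  for (mask in seq_len(n_orth) - 1L) {
    sgn <- rep(1, length(rev_idx))
    if (length(rev_idx)) {
      sgn <- ifelse(bitwAnd(mask, 2^(seq_along(rev_idx) - 1L)) > 0, -1, 1)
    }
    sign_rows <- matrix(0, 0, n + 1)
    for (k in seq_along(rev_idx)) {
      row <- rep(0, n + 1); row[rev_idx[k]] <- -sgn[k]
      sign_rows <- rbind(sign_rows, row)
    }
    IQ <- rbind(base_ineq, sign_rows)
    res <- .bf_orthant(EQ, EQc, IQ, n)
    for (v in res$verts) {
      key <- paste(round(v, 10), collapse = "|")
      if (!key %in% vkeys) { vkeys <- c(vkeys, key); verts[[length(verts) + 1L]] <- v }
    }
    for (v in res$rays) {
      key <- paste(round(v / max(abs(v)), 10), collapse = "|")
      if (!key %in% rkeys) { rkeys <- c(rkeys, key); rays[[length(rays) + 1L]] <- v / max(abs(v)) }
    }
  }
  nv <- length(verts); nr <- length(rays)
  vec <- matrix(0, nv + nr, n, dimnames = list(NULL, poly$reaction_ids))
  if (nv) vec[seq_len(nv), ] <- do.call(rbind, verts)
  if (nr) vec[nv + seq_len(nr), ] <- do.call(rbind, rays)
  .efv_set(vec, c(rep(TRUE, nv), rep(FALSE, nr)), .EFV_ZERO_TOL,
           poly$fixed_fluxes)
}

## vertices + extreme rays of {EQc r = EQ_rhs, IQc r <= IQ_rhs} (exact)
.bf_orthant <- function(EQ, EQc, IQ, n) {
  IQc <- IQ[, seq_len(n), drop = FALSE]
  IQb <- IQ[, n + 1L]
  keep <- .indep_rows_int(EQc)
  re <- length(keep)
  Ae <- EQc[keep, , drop = FALSE]
  be <- EQ[keep, n + 1L]
  m_iq <- nrow(IQ)
  feas_frac <- function(num, den) {
    ## exact feasibility of x = num/den against ALL rows
    sde <- sign(den)
    eq_ok <- all(abs(EQc %*% num - EQ[, n + 1L] * den) == 0)
    if (!eq_ok) return(FALSE)
    lhs <- as.numeric(IQc %*% num) * sde
    rhs <- IQb * abs(den)
    all(lhs <= rhs)
  }
  verts <- list()
  k <- n - re
  if (k >= 0 && m_iq >= k) {
    for (comb in .combinations(m_iq, k)) {
      A <- rbind(Ae, IQc[comb, , drop = FALSE])
      b <- c(be, IQb[comb])
      if (nrow(A) != n) next
      den <- .det_int(A)
      if (den == 0) next
      num <- vapply(seq_len(n), function(i) {
        Ai <- A; Ai[, i] <- b; .det_int(Ai)
      }, 0)
      if (feas_frac(num, den)) {
        verts[[length(verts) + 1L]] <- num / den
      }
    }
  }
  rays <- list()
  k <- n - re - 1L
  if (k >= 0 && m_iq >= k) {
    for (comb in .combinations(m_iq, k)) {
      B <- rbind(Ae, IQc[comb, , drop = FALSE])
      if (nrow(B) != n - 1L) next
      v <- .null1_int(B)
      if (is.null(v)) next
      for (dir in list(v, -v)) {
        hom_eq <- all(EQc %*% dir == 0)
        if (!hom_eq) next
        if (all(as.numeric(IQc %*% dir) <= 0)) {
          ## pointedness: skip full lines
          if (all(as.numeric(IQc %*% (-dir)) <= 0)) break
          rays[[length(rays) + 1L]] <- dir
        }
      }
    }
  }
  list(verts = verts, rays = rays)
}

.combinations <- function(m, k) {
  if (k == 0L) return(list(integer(0)))
  if (m < k) return(list())
  cmb <- utils::combn(m, k)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

#' Decompose a flux vector into elementary flux vectors
#'
#' Finds convex weights on the bounded EFVs and conic weights on the unbounded
#' ones reproducing `r` (the generator representation of the polyhedron).  A
#' small elastic program is solved; `r` counts as decomposable when the L1
#' residual is below `tol`.
#'
#' @param r numeric flux vector over the EFV set's reaction ids.
#' @param efvs an `efv_set`.
#' @param tol residual tolerance.
#' @return list with `feasible`, `gamma` (bounded weights, sum 1), `alpha`
#'   (unbounded weights) and `residual`.
#' @export
decompose_flux <- function(r, efvs, tol = 1e-8) {
  stopifnot(length(r) == ncol(efvs$vectors))
  B <- efvs$vectors[efvs$bounded, , drop = FALSE]
  U <- efvs$vectors[!efvs$bounded, , drop = FALSE]
  nb <- nrow(B); nu <- nrow(U); n <- length(r)
  if (nb == 0L) return(list(feasible = FALSE, gamma = numeric(0),
                            alpha = numeric(0), residual = Inf))
  ## variables: gamma (nb), alpha (nu), e+ (n), e- (n)
  Aeq <- rbind(
    cbind(t(B), if (nu) t(U) else NULL, diag(1, n), -diag(1, n)),
    c(rep(1, nb), rep(0, nu), rep(0, 2 * n)))
  beq <- c(r, 1)
  obj <- c(rep(0, nb + nu), rep(1, 2 * n))
  res <- solve_lp(obj, Aeq = Aeq, beq = beq, lb = 0, ub = Inf)
  if (res$status != "optimal") {
    return(list(feasible = FALSE, gamma = numeric(0), alpha = numeric(0),
                residual = Inf))
  }
  resid <- res$obj
  list(feasible = resid <= tol * max(1, max(abs(r))),
       gamma = res$x[seq_len(nb)],
       alpha = if (nu) res$x[nb + seq_len(nu)] else numeric(0),
       residual = resid)
}
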