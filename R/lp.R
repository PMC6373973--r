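## Dense bounded-variable two-phase simplex.
##
## All community/FVA/filter computations in this package reduce to small dense
## LPs (tens of variables).  Bland's rule is used throughout, which guarantees
## termination on the highly degenerate LPs that flux models produce.

#' Solve a linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `Aeq x = beq`,
#' `Aub x <= bub` and `lb <= x <= ub`.  Infinite bounds are allowed.
#'
#' @param obj numeric objective vector (length n).
#' @param Aeq,beq equality constraints (matrix with n columns, vector), or NULL.
#' @param Aub,bub inequality constraints (`Aub x <= bub`), or NULL.
#' @param lb,ub variable bounds; scalars are recycled.
#' @param maximize maximize instead of minimize.
#' @param tol feasibility/pivot tolerance.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `x` (solution, NA unless optimal) and `obj` (objective value).
#' @export
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                     lb = -Inf, ub = Inf, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), obj = NA_real_))
  }
  if (!is.null(Aeq)) Aeq <- matrix(as.numeric(Aeq), ncol = n)
  if (!is.null(Aub)) Aub <- matrix(as.numeric(Aub), ncol = n)
  m1 <- if (is.null(Aeq)) 0L else nrow(Aeq)
  m2 <- if (is.null(Aub)) 0L else nrow(Aub)
  ## slack variables for the inequality rows
  A <- rbind(
    if (m1) cbind(Aeq, matrix(0, m1, m2)),
    if (m2) cbind(Aub, diag(1, m2))
  )
  b <- c(if (m1) as.numeric(beq), if (m2) as.numeric(bub))
  cvec <- c(if (maximize) -obj else obj, rep(0, m2))
  res <- .simplex_bounded(cvec, A, b, c(lb, rep(0, m2)), c(ub, rep(Inf, m2)),
                          tol = tol)
  x <- if (res$status == "optimal") res$x[seq_len(n)] else rep(NA_real_, n)
  objval <- if (res$status == "optimal") sum(obj * x) else NA_real_
  list(status = res$status, x = x, obj = objval)
}

## core: min c'x  s.t.  A x = b, lb <= x <= ub  (A may have 0 rows)
.simplex_bounded <- function(cvec, A, b, lb, ub, tol = 1e-9) {
  n <- length(cvec)
  if (is.null(A)) {
    A <- matrix(0, 0, n)
    b <- numeric(0)
  }
  m <- nrow(A)
  if (m == 0L) {
    ## pure box problem
    x <- ifelse(cvec > 0, lb, ifelse(cvec < 0, ub, ifelse(is.finite(lb), lb, pmin(ub, 0))))
    x[!is.finite(x) & cvec == 0] <- 0
    if (any(!is.finite(x))) {
      return(list(status = "unbounded", x = NULL))
    }
    return(list(status = "optimal", x = x))
  }
  scale <- max(1, abs(b))
  ftol <- tol * scale

  ## initial nonbasic point: at a finite bound, or 0 for free variables
  start_val <- function(j) {
    if (is.finite(lb[j])) lb[j] else if (is.finite(ub[j])) ub[j] else 0
  }
  x0 <- vapply(seq_len(n), start_val, 0)
  resid <- b - as.numeric(A %*% x0)
  sigma <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(sigma, m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  art <- n + seq_len(m)

  status <- character(n + m)
  status[seq_len(n)] <- ifelse(is.finite(lb), "L", ifelse(is.finite(ub), "U", "F"))
  status[art] <- "B"
  basis <- art

  run <- function(cost, basis, status, ubf, maxit = 20000L) {
    nm <- ncol(Afull)
    for (it in seq_len(maxit)) {
      nb_val <- numeric(nm)
      nb_val[status == "L"] <- lbf[status == "L"]
      nb_val[status == "U"] <- ubf[status == "U"]
      ## free nonbasic sit at 0
      Bmat <- Afull[, basis, drop = FALSE]
      nonb <- which(status != "B")
      rhs <- b - if (length(nonb)) as.numeric(Afull[, nonb, drop = FALSE] %*% nb_val[nonb]) else 0
      xb <- tryCatch(solve(Bmat, rhs), error = function(e) NULL)
      if (is.null(xb)) stop("singular basis in simplex (numerical failure)")
      y <- solve(t(Bmat), cost[basis])
      d <- cost - as.numeric(y %*% Afull)
      enter <- 0L; dir <- 0
      for (j in seq_len(nm)) {       # Bland: first eligible index
        if (status[j] == "B") next
        if (status[j] == "L" && d[j] < -tol) { enter <- j; dir <- 1; break }
        if (status[j] == "U" && d[j] > tol)  { enter <- j; dir <- -1; break }
        if (status[j] == "F" && abs(d[j]) > tol) { enter <- j; dir <- if (d[j] > 0) -1 else 1; break }
      }
      if (enter == 0L) {
        x <- numeric(nm)
        x[status != "B"] <- nb_val[status != "B"]
        x[basis] <- xb
        return(list(status = "optimal", x = x, basis = basis, statusv = status))
      }
      w <- solve(Bmat, Afull[, enter])
      ## ratio test: how far can the entering variable move (step t >= 0)?
      t_own <- if (is.finite(ubf[enter]) && is.finite(lbf[enter])) ubf[enter] - lbf[enter] else Inf
      t_row <- rep(Inf, m)
      row_to <- character(m)
      for (i in seq_len(m)) {
        coef <- dir * w[i]           # basic i decreases at rate coef
        bi <- basis[i]
        if (coef > tol) {
          t_row[i] <- max(0, (xb[i] - lbf[bi]) / coef)
          row_to[i] <- "L"
        } else if (coef < -tol && is.finite(ubf[bi])) {
          t_row[i] <- max(0, (ubf[bi] - xb[i]) / (-coef))
          row_to[i] <- "U"
        }
      }
      t_blk <- if (m > 0) min(t_row) else Inf
      if (!is.finite(min(t_own, t_blk))) return(list(status = "unbounded"))
      if (t_own <= t_blk) {
        ## entering variable hits its opposite bound first: bound flip
        status[enter] <- if (status[enter] == "L") "U" else "L"
        next
      }
      cand <- which(t_row <= t_blk + ftol)
      leave <- cand[which.min(basis[cand])]   # Bland tie-break
      leave_to <- row_to[leave]
      out <- basis[leave]
      status[out] <- leave_to
      status[enter] <- "B"
      basis[leave] <- enter
    }
    stop("simplex iteration limit exceeded")
  }

  ## phase 1
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- run(cost1, basis, status, ubf)
  if (p1$status != "optimal") stop("phase-1 simplex failed unexpectedly")
  if (sum(p1$x[art]) > ftol * 10) {
    return(list(status = "infeasible", x = NULL))
  }
  ## phase 2: pin artificials to zero
  ubf[art] <- 0
  st <- p1$statusv
  st[art][st[art] == "U"] <- "L"   # all artificial bounds are now [0,0]
  cost2 <- c(cvec, rep(0, m))
  p2 <- run(cost2, p1$basis, st, ubf)
  if (p2$status == "unbounded") return(list(status = "unbounded", x = NULL))
  list(status = "optimal", x = p2$x[seq_len(n)])
}

## feasibility check helper used by the growth-rate search
.lp_feasible <- function(Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                         lb = -Inf, ub = Inf, tol = 1e-9) {
  nn <- if (!is.null(Aeq)) ncol(Aeq) else ncol(Aub)
  res <- solve_lp(rep(0, nn), Aeq, beq, Aub, bub, lb, ub, tol = tol)
  res$status == "optimal"
}
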