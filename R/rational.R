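## Exact arithmetic for the brute-force EFV oracle.
##
## All fixture coefficients are small rationals, so every row of a constraint
## system can be scaled to integers that fit exactly in a double.  Elimination
## is then done fraction-free (Bareiss), i.e. all intermediate quantities are
## exact integers; an overflow guard aborts rather than silently losing
## exactness.

.RAT_MAXDEN <- 10000L
.RAT_OVERFLOW <- 2^50

## smallest denominator d <= maxden with |x*d - round(x*d)| tiny
.denom_of <- function(x, maxden = .RAT_MAXDEN) {
  for (d in c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 10L, 12L, 20L, 25L, 50L, 100L,
              200L, 500L, 1000L, 2000L, 5000L, 10000L)) {
    if (abs(x * d - round(x * d)) < 1e-9 * max(1, abs(x * d))) return(d)
  }
  stop("coefficient ", x, " is not a small rational; exact oracle unavailable")
}

## scale each row of a numeric matrix to exact integers
.int_rows <- function(M) {
  if (nrow(M) == 0L) return(M)
  t(apply(M, 1, function(row) {
    dens <- vapply(row, .denom_of, 1L)
    d <- Reduce(function(a, b) a * b / .gcd2(a, b), unique(dens))
    v <- round(row * d)
    g <- Reduce(.gcd2, c(abs(v[v != 0]), 0))
    if (is.null(g) || length(g) == 0L || g == 0) v else v / g
  }))
}

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

## exact determinant of an integer matrix (Bareiss, column pivoting)
.det_int <- function(M) {
  n <- nrow(M)
  if (n == 0L) return(1)
  if (n != ncol(M)) stop("determinant needs a square matrix")
  A <- M
  sign <- 1
  prev <- 1
  for (k in seq_len(n - 1)) {
    if (A[k, k] == 0) {
      p <- which(A[k:n, k] != 0)
      if (length(p) == 0L) return(0)
      p <- p[1] + k - 1
      tmp <- A[k, ]; A[k, ] <- A[p, ]; A[p, ] <- tmp
      sign <- -sign
    }
    piv <- A[k, k]
    idx <- (k + 1):n
    A[idx, idx] <- (A[idx, idx, drop = FALSE] * piv -
                      outer(A[idx, k], A[k, idx])) / prev
    if (max(abs(A[idx, idx])) > .RAT_OVERFLOW) {
      stop("exact oracle overflow: coefficients too large")
    }
    A[idx, k] <- 0
    prev <- piv
  }
  sign * A[n, n]
}

## exact rank of an integer matrix
.rank_int <- function(M) {
  A <- M
  nr <- nrow(A); nc <- ncol(A)
  if (nr == 0L || nc == 0L) return(0L)
  r <- 0L
  prev <- 1
  for (col in seq_len(nc)) {
    if (r + 1L > nr) break
    p <- which(A[(r + 1L):nr, col] != 0)
    if (length(p) == 0L) next
    p <- p[1] + r
    if (p != r + 1L) { tmp <- A[r + 1L, ]; A[r + 1L, ] <- A[p, ]; A[p, ] <- tmp }
    r <- r + 1L
    piv <- A[r, col]
    if (r < nr) {
      idx <- (r + 1L):nr
      A[idx, ] <- (A[idx, , drop = FALSE] * piv - outer(A[idx, col], A[r, ])) / prev
      if (max(abs(A[idx, , drop = FALSE])) > .RAT_OVERFLOW) {
        stop("exact oracle overflow: coefficients too large")
      }
    }
    prev <- piv
  }
  r
}

## rows of M that form a basis of its row space (exact)
.indep_rows_int <- function(M) {
  keep <- integer(0)
  r <- 0L
  for (i in seq_len(nrow(M))) {
    cand <- M[c(keep, i), , drop = FALSE]
    if (.rank_int(cand) > r) { keep <- c(keep, i); r <- r + 1L }
  }
  keep
}

## exact solution of square integer system A x = b via Cramer's rule;
## returns NULL if singular, else the solution as a double vector (num/den
## evaluated; exact whenever num and den are exactly representable)
.solve_int <- function(A, b) {
  d <- .det_int(A)
  if (d == 0) return(NULL)
  n <- ncol(A)
  x <- numeric(n)
  for (i in seq_len(n)) {
    Ai <- A
    Ai[, i] <- b
    x[i] <- .det_int(Ai) / d
  }
  x
}

## exact 1-dimensional null vector of an (n-1) x n integer matrix of full row
## rank: signed maximal minors.  Returns NULL if rank < n-1 (all minors zero).
.null1_int <- function(B) {
  n <- ncol(B)
  stopifnot(nrow(B) == n - 1L)
  v <- numeric(n)
  for (i in seq_len(n)) {
    v[i] <- (-1)^(i + 1) * .det_int(B[, -i, drop = FALSE])
  }
  if (all(v == 0)) return(NULL)
  g <- Reduce(.gcd2, abs(v[v != 0]))
  v / g
}
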