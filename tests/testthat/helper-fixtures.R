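## Shared helpers for comparing EFV sets and sampling feasible points.

## canonical string keys for an EFV set (order-independent comparison);
## unbounded rays are compared after max-norm scaling
efv_keys <- function(e, digits = 6) {
  v <- e$vectors
  if (nrow(v) == 0) return(character(0))
  sc <- apply(abs(v), 1, max)
  sc[sc == 0] <- 1
  keys <- vapply(seq_len(nrow(v)), function(i) {
    row <- if (e$bounded[i]) v[i, ] else v[i, ] / sc[i]
    paste(round(row, digits), collapse = "|")
  }, "")
  sort(paste(keys, e$bounded))
}

## a random feasible point of a polyhedron: optimum of a random objective,
## occasionally averaged with a second one to leave the vertex set
random_feasible_point <- function(poly, seed) {
  set.seed(seed)
  n <- length(poly$reaction_ids)
  pt <- function() {
    res <- solve_lp(stats::rnorm(n), Aeq = poly$Aeq, beq = poly$beq,
                    Aub = poly$Aub, bub = poly$bub,
                    lb = poly$lb, ub = poly$ub)
    if (res$status != "optimal") return(NULL)
    res$x
  }
  a <- pt()
  if (is.null(a)) return(NULL)
  b <- pt()
  w <- stats::runif(1)
  if (is.null(b)) a else w * a + (1 - w) * b
}

## hand-assembled projected-EFV object (for filter/dedup unit tests)
make_projected <- function(oriented, mu_fix = 0.1, species_id = "X") {
  oriented <- as.matrix(oriented)
  structure(list(oriented = oriented,
                 signed = oriented,
                 exchange_ids = head(colnames(oriented), -1),
                 source_index = seq_len(nrow(oriented)),
                 full_vectors = oriented,
                 species_id = species_id, mu_fix = mu_fix),
            class = "projected_efvs")
}
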