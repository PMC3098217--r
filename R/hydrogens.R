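#' Reconstruct missing amide hydrogens
#'
#' Coarse-grained or backbone-only structures often lack amide hydrogens,
#' which the DSSP hydrogen-bond energy needs. For each residue i > 0 the H
#' is placed on the bisector convention: the unit vectors from C(i-1) to
#' N(i) and from CA(i) to N(i) are summed, normalized, and scaled to 1.00
#' Angstrom from N. Residue 0 of each chain gets no H (for GNNQQNY this is
#' the N-terminal glycine, excluded from bond counting anyway). Residues
#' that already carry an H are left untouched, so the operation is
#' idempotent.
#'
#' @param x an \code{assembly}.
#' @return The assembly with H filled in for residues 1..n-1 of every chain
#'   of length >= 2. Chains of length 1 are skipped with a warning.
#' @export
reconstruct_amide_hydrogens <- function(x) {
  stopifnot(inherits(x, "assembly"))
  short <- 0L
  x$chains <- lapply(x$chains, function(ch) {
    n <- n_residues(ch)
    if (n < 2L) { short <<- short + 1L; return(ch) }
    for (i in 2:n) {
      if (!is.na(ch$H[i, 1])) next
      u1 <- ch$N[i, ] - ch$C[i - 1L, ]
      u2 <- ch$N[i, ] - ch$CA[i, ]
      u1 <- u1 / sqrt(sum(u1^2))
      u2 <- u2 / sqrt(sum(u2^2))
      bis <- u1 + u2
      nb <- sqrt(sum(bis^2))
      if (nb < 1e-9) next  # degenerate collinear geometry; leave H absent
      ch$H[i, ] <- ch$N[i, ] + bis / nb
    }
    ch
  })
  if (short > 0L)
    warning(sprintf("%d chain(s) of length 1 skipped (no H placed)", short))
  x
}
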