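# DSSP electrostatic hydrogen-bond criterion.
#
# The bond energy between a donor N-H group and an acceptor C=O group is
#   E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)   [kcal/mol],
# distances in Angstrom, and a hydrogen bond is assigned when E falls below
# a cutoff (-0.5 kcal/mol, DSSP's published value).

#' DSSP hydrogen-bond energy of a donor/acceptor residue pair
#'
#' @param donor list with 3-vectors \code{N} and \code{H} (the N-H residue).
#' @param acceptor list with 3-vectors \code{C} and \code{O} (the C=O
#'   residue).
#' @return Energy in kcal/mol. If any of the four distances is at or below
#'   0.5 Angstrom (a clash), \code{Inf} is returned as a no-bond sentinel.
#' @export
dssp_energy <- function(donor, acceptor) {
  if (is.null(donor$H) || any(is.na(donor$H)))
    stop("donor has no amide H; run reconstruct_amide_hydrogens() first")
  d <- function(a, b) sqrt(sum((a - b)^2))
  r_on <- d(acceptor$O, donor$N)
  r_ch <- d(acceptor$C, donor$H)
  r_oh <- d(acceptor$O, donor$H)
  r_cn <- d(acceptor$C, donor$N)
  if (min(r_on, r_ch, r_oh, r_cn) <= 0.5) return(Inf)
  27.888 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

#' Detect backbone hydrogen bonds in an assembly
#'
#' Scans all donor (residue carrying an amide H) / acceptor pairs, skipping
#' self-pairs and same-chain pairs closer than 3 residues in sequence (the
#' DSSP convention, which keeps helical self-bonds out of beta statistics).
#' A 9 Angstrom O-N distance pre-screen is applied for speed only.
#'
#' @param x an \code{assembly} (with H present where bonds are expected; see
#'   [reconstruct_amide_hydrogens()]).
#' @param energy_cutoff bonds require E < this value (kcal/mol).
#' @return A data.frame of class \code{hbond_table} with columns
#'   \code{donor_chain}, \code{donor_res}, \code{acceptor_chain},
#'   \code{acceptor_res} (residue indices 0-based) and \code{energy},
#'   ordered by donor chain, donor index, acceptor chain, acceptor index.
#' @export
detect_hbonds <- function(x, energy_cutoff = -0.5) {
  stopifnot(inherits(x, "assembly"))
  f <- flatten_assembly(x)
  don <- which(!is.na(f$H[, 1]))
  empty <- data.frame(donor_chain = character(0), donor_res = integer(0),
                      acceptor_chain = character(0), acceptor_res = integer(0),
                      energy = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("hbond_table", "data.frame")
  if (length(don) == 0L) return(empty)
  nall <- length(f$res)
  # O(acceptor) - N(donor) distance pre-screen at 9 A
  d2 <- outer(rowSums(f$O^2), rowSums(f$N[don, , drop = FALSE]^2), "+") -
    2 * f$O %*% t(f$N[don, , drop = FALSE])
  cand <- which(d2 <= 81, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  acc_i <- cand[, 1]
  don_i <- don[cand[, 2]]
  same_res <- acc_i == don_i
  same_chain_close <- f$chain_ord[acc_i] == f$chain_ord[don_i] &
    abs(f$res[acc_i] - f$res[don_i]) < 3L
  keep <- !(same_res | same_chain_close)
  acc_i <- acc_i[keep]; don_i <- don_i[keep]
  if (length(acc_i) == 0L) return(empty)
  dist <- function(A, B) sqrt(rowSums((A - B)^2))
  r_on <- dist(f$O[acc_i, , drop = FALSE], f$N[don_i, , drop = FALSE])
  r_ch <- dist(f$C[acc_i, , drop = FALSE], f$H[don_i, , drop = FALSE])
  r_oh <- dist(f$O[acc_i, , drop = FALSE], f$H[don_i, , drop = FALSE])
  r_cn <- dist(f$C[acc_i, , drop = FALSE], f$N[don_i, , drop = FALSE])
  e <- 27.888 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  e[pmin(r_on, r_ch, r_oh, r_cn) <= 0.5] <- Inf
  hit <- e < energy_cutoff
  out <- data.frame(donor_chain = f$chain[don_i[hit]],
                    donor_res = f$res[don_i[hit]],
                    acceptor_chain = f$chain[acc_i[hit]],
                    acceptor_res = f$res[acc_i[hit]],
                    energy = e[hit], stringsAsFactors = FALSE)
  ord <- order(f$chain_ord[don_i[hit]], out$donor_res,
               f$chain_ord[acc_i[hit]], out$acceptor_res)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_table", "data.frame")
  out
}

#' Write a hydrogen-bond table as TSV
#'
#' @param hbonds an \code{hbond_table} from [detect_hbonds()].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_hbonds <- function(hbonds, path) {
  utils::write.table(hbonds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
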