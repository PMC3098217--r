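#' @keywords internal
"_PACKAGE"

# Boltzmann constant in kcal/mol/K, used throughout.
.kB <- 0.0019872

#' Boltzmann constant (kcal/mol/K)
#'
#' The value used by all thermodynamic routines in this package.
#'
#' @return A single number, 0.0019872 kcal/mol/K.
#' @export
kB_kcal <- function() .kB

#' Construct a backbone chain
#'
#' A chain holds the backbone atoms (N, CA, C, O and optionally the amide H)
#' of one peptide, one row per residue. Residues are indexed 0-based from the
#' N-terminus; in 7-residue GNNQQNY fixtures residue 0 is the N-terminal
#' glycine that is excluded from hydrogen-bond counting downstream.
#'
#' @param res_name character vector of 3-letter residue codes.
#' @param N,CA,C,O numeric n x 3 matrices of coordinates in Angstrom.
#' @param H optional n x 3 matrix; rows of NA mark residues without an amide
#'   hydrogen (residue 0 conventionally has none).
#' @param validate if TRUE, check coordinate finiteness and backbone bond
#'   lengths: |N-CA| in [1.2, 1.7], |CA-C| in [1.3, 1.8], |C-O| in [1.0, 1.5]
#'   Angstrom.
#' @return An object of class \code{backbone_chain}.
#' @export
backbone_chain <- function(res_name, N, CA, C, O, H = NULL, validate = TRUE) {
  n <- length(res_name)
  coerce <- function(m, what) {
    m <- as.matrix(m)
    if (!is.numeric(m) || ncol(m) != 3L || nrow(m) != n)
      stop(sprintf("'%s' must be a numeric %d x 3 matrix", what, n))
    dimnames(m) <- NULL
    m
  }
  N <- coerce(N, "N"); CA <- coerce(CA, "CA")
  C <- coerce(C, "C"); O <- coerce(O, "O")
  if (is.null(H)) H <- matrix(NA_real_, n, 3) else H <- coerce(H, "H")
  if (validate) {
    for (m in list(N, CA, C, O))
      if (any(!is.finite(m))) stop("backbone coordinates must be finite")
    present <- !is.na(H[, 1])
    if (any(!is.finite(H[present, , drop = FALSE])))
      stop("H coordinates must be finite where present")
    dlen <- function(a, b) sqrt(rowSums((a - b)^2))
    chk <- function(d, lo, hi, what) {
      bad <- which(d < lo | d > hi)
      if (length(bad))
        stop(sprintf("residue %d: |%s| = %.2f A outside [%.1f, %.1f]",
                     bad[1] - 1L, what, d[bad[1]], lo, hi))
    }
    chk(dlen(N, CA), 1.2, 1.7, "N-CA")
    chk(dlen(CA, C), 1.3, 1.8, "CA-C")
    chk(dlen(C, O), 1.0, 1.5, "C-O")
  }
  structure(list(res_name = as.character(res_name),
                 N = N, CA = CA, C = C, O = O, H = H),
            class = "backbone_chain")
}

#' Number of residues in a chain
#' @param chain a \code{backbone_chain}.
#' @return Integer residue count.
#' @export
n_residues <- function(chain) length(chain$res_name)

#' Construct a multi-chain assembly
#'
#' An assembly is an ordered, named list of peptide chains plus an optional
#' cubic box edge. One chain is one candidate beta-strand: the 7-residue
#' peptides studied here cannot form intra-chain sheets, so all sheet
#' topology lives in inter-chain hydrogen bonding.
#'
#' @param chains named list of \code{backbone_chain} objects (names are
#'   chain identifiers, e.g. "A", "B", ...).
#' @param box_edge optional cubic box edge length in Angstrom.
#' @return An object of class \code{assembly}.
#' @export
assembly <- function(chains, box_edge = NULL) {
  if (length(chains) < 1L) stop("assembly needs at least one chain")
  if (is.null(names(chains)) || any(!nzchar(names(chains))) ||
      anyDuplicated(names(chains)))
    stop("chains must have unique non-empty names")
  for (ch in chains) {
    if (!inherits(ch, "backbone_chain")) stop("all chains must be backbone_chain")
    if (n_residues(ch) < 1L) stop("chains must be non-empty")
  }
  if (!is.null(box_edge) && (!is.numeric(box_edge) || box_edge <= 0))
    stop("box_edge must be a positive number")
  structure(list(chains = chains, box_edge = box_edge), class = "assembly")
}

#' Number of chains in an assembly
#' @param x an \code{assembly}.
#' @return Integer chain count.
#' @export
n_chains <- function(x) length(x$chains)

#' @export
print.assembly <- function(x, ...) {
  nres <- vapply(x$chains, n_residues, integer(1))
  cat(sprintf("assembly: %d chain(s), %d residues total\n",
              n_chains(x), sum(nres)))
  cat("  chains:", paste(sprintf("%s(%d)", names(x$chains), nres),
                         collapse = " "), "\n")
  if (!is.null(x$box_edge))
    cat(sprintf("  box edge: %.1f A\n", x$box_edge))
  invisible(x)
}

#' Construct a trajectory frame
#'
#' Wraps an assembly with optional replica-exchange metadata.
#'
#' @param assembly an \code{assembly}.
#' @param time time in ps, or NULL.
#' @param temperature temperature in K (> 0), or NULL.
#' @param energy potential energy in kcal/mol, or NULL.
#' @param replica_id integer replica (walker) identifier, or NULL.
#' @return An object of class \code{remd_frame}.
#' @export
remd_frame <- function(assembly, time = NULL, temperature = NULL,
                       energy = NULL, replica_id = NULL) {
  stopifnot(inherits(assembly, "assembly"))
  if (!is.null(temperature) && temperature <= 0)
    stop("temperature must be positive")
  structure(list(assembly = assembly, time = time, temperature = temperature,
                 energy = energy, replica_id = replica_id),
            class = "remd_frame")
}

# Flatten an assembly into parallel per-residue vectors/matrices; used by the
# hydrogen-bond scan. Residue indices are 0-based within each chain.
flatten_assembly <- function(x) {
  ids <- names(x$chains)
  nres <- vapply(x$chains, n_residues, integer(1))
  chain <- rep(ids, nres)
  res <- unlist(lapply(nres, function(n) seq_len(n) - 1L), use.names = FALSE)
  stack <- function(field) do.call(rbind, lapply(x$chains, `[[`, field))
  list(chain = chain, res = res, chain_ord = rep(seq_along(ids), nres),
       N = stack("N"), CA = stack("CA"), C = stack("C"),
       O = stack("O"), H = stack("H"),
       res_name = unlist(lapply(x$chains, `[[`, "res_name"), use.names = FALSE))
}

#' Radius of gyration of an assembly
#'
#' Mass-unweighted radius of gyration over all backbone heavy atoms
#' (N, CA, C, O). Provided as a small convenience utility.
#'
#' @param x an \code{assembly}.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(x) {
  f <- flatten_assembly(x)
  xyz <- rbind(f$N, f$CA, f$C, f$O)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

# Apply a rigid-body transform (rotation matrix R then translation t) to all
# coordinates of an assembly. Used by generators and invariance tests.
transform_assembly <- function(x, R = diag(3), t = c(0, 0, 0)) {
  rot <- function(m) {
    out <- m
    ok <- !is.na(m[, 1])
    out[ok, ] <- m[ok, , drop = FALSE] %*% t(R) +
      matrix(t, sum(ok), 3, byrow = TRUE)
    out
  }
  x$chains <- lapply(x$chains, function(ch) {
    for (f in c("N", "CA", "C", "O", "H")) ch[[f]] <- rot(ch[[f]])
    ch
  })
  x
}
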