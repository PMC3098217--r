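# Synthetic fixtures: idealized beta-sheet assemblies with known topology,
# random-coil starting configurations at a prescribed concentration,
# temperature ladders, and a two-state replica-exchange energy simulator.
#
# Sheet geometry is flat (untwisted): strands run along x, the hydrogen-bond
# ladder direction is y (strand spacing 4.8 A), and sheets are stacked
# along z (10 A apart). The per-residue atom template is chosen so that
# (a) backbone bond lengths satisfy the validation ranges, (b) the emitted
# amide H coincides exactly with the bisector reconstruction convention,
# and (c) the DSSP energy of each intended inter-strand bond is ~ -2.0
# kcal/mol while every unintended donor/acceptor pair stays above the
# -0.5 kcal/mol cutoff.

.three_letter <- c(G = "GLY", N = "ASN", Q = "GLN", Y = "TYR", A = "ALA",
                   S = "SER", V = "VAL", L = "LEU", I = "ILE", F = "PHE",
                   K = "LYS", E = "GLU", D = "ASP", T = "THR", R = "ARG",
                   H = "HIS", W = "TRP", M = "MET", C = "CYS", P = "PRO")

chain_id_pool <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n > length(pool)) stop("too many chains for single-character PDB ids")
  pool[seq_len(n)]
}

#' Specify an idealized multi-sheet beta assembly
#'
#' @param sheet_sizes integer vector of strands per sheet, e.g.
#'   \code{c(8, 7, 5)}.
#' @param orientations per-sheet list of orientations
#'   (\code{"parallel"}/\code{"antiparallel"}) for each adjacent strand
#'   pair (length size - 1); a single string is recycled everywhere.
#' @param registers per-sheet list of integer register shifts per adjacent
#'   pair; a single integer is recycled. |shift| must be smaller than the
#'   sequence length.
#' @param sequence one-letter peptide sequence (default the yeast prion
#'   Sup35 fragment GNNQQNY).
#' @param strand_spacing inter-strand (hydrogen-bond ladder) spacing in A.
#' @param rise_per_residue translation per residue along the strand in A.
#' @param inter_sheet_offset stacking distance between sheets in A.
#' @return An object of class \code{sheet_spec}.
#' @export
sheet_spec <- function(sheet_sizes, orientations = "antiparallel",
                       registers = 0L, sequence = "GNNQQNY",
                       strand_spacing = 4.8, rise_per_residue = 3.4,
                       inter_sheet_offset = 10) {
  sheet_sizes <- as.integer(sheet_sizes)
  if (any(sheet_sizes < 1L)) stop("sheet sizes must be >= 1")
  L <- nchar(sequence)
  if (L < 2L) stop("sequence must have at least 2 residues")
  expand <- function(x, default_ok = TRUE) {
    if (!is.list(x)) x <- lapply(pmax(sheet_sizes - 1L, 0L),
                                 function(m) rep(x[1], m))
    if (length(x) != length(sheet_sizes))
      stop("need one orientations/registers entry per sheet")
    for (s in seq_along(x))
      if (length(x[[s]]) != max(sheet_sizes[s] - 1L, 0L))
        stop("orientations/registers length must be sheet size - 1")
    x
  }
  orientations <- expand(orientations)
  registers <- lapply(expand(registers), as.integer)
  for (o in unlist(orientations))
    match.arg(o, c("parallel", "antiparallel"))
  if (any(abs(unlist(registers)) >= L))
    stop("|register| must be smaller than the sequence length")
  structure(list(sheet_sizes = sheet_sizes, orientations = orientations,
                 registers = registers, sequence = sequence,
                 strand_spacing = strand_spacing,
                 rise_per_residue = rise_per_residue,
                 inter_sheet_offset = inter_sheet_offset),
            class = "sheet_spec")
}

# Ideal strand: base x positions p_m = origin + m * rise * dir; template
# offsets per residue relative to its base (direction-aware in x).
ideal_strand <- function(sequence, origin, dir, y, z, rise) {
  L <- nchar(sequence)
  aa <- strsplit(sequence, "")[[1]]
  res_name <- unname(.three_letter[aa])
  res_name[is.na(res_name)] <- "UNK"
  p <- origin + (seq_len(L) - 1L) * rise * dir
  N <- cbind(p, y, z)
  CA <- cbind(p + dir, y + 1, z)
  C <- cbind(p + (rise - 1) * dir, y + 1, z)
  O <- cbind(p + (rise - 2.2) * dir, y + 1.8, z)
  H <- cbind(p, y - 1, z)
  H[1, ] <- NA_real_  # residue 0: no amide H (N-terminal glycine)
  backbone_chain(res_name, N, CA, C, O, H)
}

#' Build an idealized beta-sheet assembly from a specification
#'
#' Lays each sheet's strands on ideal flat geometry, reversing antiparallel
#' neighbors in x and applying register shifts as x-offsets, and returns
#' both the assembly and the generator's bookkeeping (intended strand
#' pairs with orientations, registers and surviving hydrogen-bond counts,
#' the intended configuration type, and the intended bonded-residue
#' fraction), which oracle tests compare against the classifier output.
#'
#' @param spec a \code{sheet_spec}.
#' @return List with elements \code{assembly} and \code{bookkeeping}
#'   (\code{config_type}, \code{pairs} data.frame, \code{beta_content},
#'   \code{bonds} data.frame of intended detectable bonds).
#' @export
build_sheet_assembly <- function(spec) {
  stopifnot(inherits(spec, "sheet_spec"))
  L <- nchar(spec$sequence)
  rise <- spec$rise_per_residue
  ids <- chain_id_pool(sum(spec$sheet_sizes))
  chains <- list()
  pair_rows <- list()
  bond_rows <- list()
  ci <- 0L
  for (s in seq_along(spec$sheet_sizes)) {
    size <- spec$sheet_sizes[s]
    z <- (s - 1L) * spec$inter_sheet_offset
    origin <- 0; dir <- 1L
    for (k in seq_len(size)) {
      ci <- ci + 1L
      y <- (k - 1L) * spec$strand_spacing
      chains[[ids[ci]]] <- ideal_strand(spec$sequence, origin, dir, y, z, rise)
      if (k == size) next
      ori <- spec$orientations[[s]][k]
      sh <- spec$registers[[s]][k]
      a_id <- ids[ci]; b_id <- ids[ci + 1L]
      # intended bonds: donor residue j (>=1) on upper strand b, acceptor i
      # on lower strand a at the same x position
      jj <- seq_len(L) - 1L
      ii <- if (ori == "parallel") jj - sh else (L - 1L) + sh - jj
      ok <- jj >= 1L & ii >= 0L & ii <= (L - 1L)
      bond_rows[[length(bond_rows) + 1L]] <-
        data.frame(donor_chain = b_id, donor_res = jj[ok],
                   acceptor_chain = a_id, acceptor_res = ii[ok],
                   stringsAsFactors = FALSE)
      surv <- ok & ii >= 1L
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(a = a_id, b = b_id, n_hbonds = sum(surv),
                   orientation = ori, register = sh,
                   stringsAsFactors = FALSE)
      if (ori == "parallel") {
        origin <- origin - sh * rise * dir
      } else {
        origin <- origin + (L - 1L + sh) * rise * dir
        dir <- -dir
      }
    }
  }
  asm <- assembly(chains)
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs))
    pairs <- data.frame(a = character(0), b = character(0),
                        n_hbonds = integer(0), orientation = character(0),
                        register = integer(0))
  bonds <- do.call(rbind, bond_rows)
  if (is.null(bonds))
    bonds <- data.frame(donor_chain = character(0), donor_res = integer(0),
                        acceptor_chain = character(0),
                        acceptor_res = integer(0))
  surv <- bonds[bonds$donor_res > 0L & bonds$acceptor_res > 0L, , drop = FALSE]
  tags <- unique(c(paste(surv$donor_chain, surv$donor_res),
                   paste(surv$acceptor_chain, surv$acceptor_res)))
  list(assembly = asm,
       bookkeeping = list(
         config_type = paste(sort(spec$sheet_sizes, decreasing = TRUE),
                             collapse = " "),
         pairs = pairs,
         bonds = bonds,
         beta_content = length(tags) / (L * sum(spec$sheet_sizes))))
}

#' Cubic box edge from chain count and molar concentration
#'
#' edge = (n / (N_A c))^(1/3), converted to Angstrom.
#'
#' @param n_chains number of solute chains.
#' @param concentration molar concentration (mol/L).
#' @return Box edge in Angstrom.
#' @export
box_edge_from_concentration <- function(n_chains, concentration) {
  if (n_chains <= 0 || concentration <= 0)
    stop("n_chains and concentration must be positive")
  avogadro <- 6.02214076e23
  vol_m3 <- n_chains / (avogadro * concentration * 1000)
  vol_m3^(1 / 3) * 1e10
}

# --- internal backbone builder from dihedrals (NeRF placement) ------------

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# place atom D bonded to C with length len, angle B-C-D theta (deg) and
# torsion A-B-C-D chi (deg)
place_atom <- function(A, B, C, len, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-len * cos(th), len * sin(th) * cos(ch), len * sin(th) * sin(ch))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# build one backbone chain from phi/psi vectors (omega fixed trans)
build_coil_chain <- function(res_name, phi, psi) {
  n <- length(res_name)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231
  a_ncac <- 111.0; a_cacn <- 116.6; a_cnca <- 121.9; a_caco <- 120.5
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_nca, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], b_cac, a_ncac, phi[1])
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                           b_cn, a_cacn, psi[i - 1L])
      CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            b_nca, a_cnca, 180)
      C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                           b_cac, a_ncac, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], b_co, a_caco,
                         psi[i] + 180)
  }
  backbone_chain(res_name, N, CA, C, O)
}

# draw a dihedral pair outside the beta and alpha-helical bands
draw_coil_dihedrals <- function(n) {
  draw1 <- function() {
    v <- stats::runif(1, -150, 150)
    if (v < 0) v - 30 else v + 30  # uniform on (-180,-30) U (30,180)
  }
  phi <- numeric(n); psi <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      p1 <- draw1(); p2 <- draw1()
      in_beta <- p1 <= -90 && p2 >= 90
      in_alpha <- p1 > -100 && p1 < -30 && p2 > -80 && p2 < -5
      if (!in_beta && !in_alpha) break
    }
    phi[i] <- p1; psi[i] <- p2
  }
  list(phi = phi, psi = psi)
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build a random-coil starting configuration
#'
#' Generates \code{n_chains} peptide chains with backbone dihedrals drawn
#' outside the beta and helical bands (so the initial sheet content is
#' zero) and places them at random positions and orientations in a cubic
#' box such that all inter-chain centroid distances are at least
#' \code{min_sep} and every chain's nearest neighbor is within
#' \code{max_sep}.
#'
#' @param n_chains number of chains.
#' @param min_sep,max_sep centroid separation bounds in A.
#' @param box_edge cubic box edge in A; default derives from a 4.15 mM
#'   concentration via [box_edge_from_concentration()].
#' @param seed integer seed for reproducibility (required).
#' @param sequence one-letter peptide sequence.
#' @param max_tries placement retry budget before giving up.
#' @return An \code{assembly} with \code{box_edge} set.
#' @export
build_random_coils <- function(n_chains, min_sep = 12, max_sep = 50,
                               box_edge = NULL, seed = 1L,
                               sequence = "GNNQQNY", max_tries = 5000L) {
  if (is.null(box_edge))
    box_edge <- box_edge_from_concentration(n_chains, 4.15e-3)
  set.seed(seed)
  aa <- strsplit(sequence, "")[[1]]
  res_name <- unname(.three_letter[aa]); res_name[is.na(res_name)] <- "UNK"
  centers <- matrix(NA_real_, n_chains, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n_chains) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place chains under the separation constraints; ",
           "try a larger box")
    cand <- stats::runif(3, 0, box_edge)
    if (placed > 0L) {
      d <- sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                              2, cand)^2))
      if (any(d < min_sep)) next
      if (min(d) > max_sep) next  # keep every chain within reach of another
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  chains <- list()
  for (k in seq_len(n_chains)) {
    di <- draw_coil_dihedrals(length(aa))
    ch <- build_coil_chain(res_name, di$phi, di$psi)
    xyz <- rbind(ch$N, ch$CA, ch$C, ch$O)
    ctr <- colMeans(xyz)
    R <- random_rotation()
    move <- function(m) sweep(m, 2, ctr) %*% t(R) +
      matrix(centers[k, ], nrow(m), 3, byrow = TRUE)
    ch$N <- move(ch$N); ch$CA <- move(ch$CA)
    ch$C <- move(ch$C); ch$O <- move(ch$O)
    chains[[chain_id_pool(n_chains)[k]]] <- ch
  }
  assembly(chains, box_edge = box_edge)
}

#' Construct a replica-exchange temperature ladder
#'
#' \code{"log"} places \code{n} temperatures geometrically between
#' \code{t_min} and \code{t_max} (constant neighbor ratio, endpoints
#' exact). \code{"gaussian_quantile"} places them at equal quantiles of a
#' normal(center, width) truncated to [t_min, t_max], concentrating
#' replicas near the transition temperature.
#'
#' @param kind \code{"log"} or \code{"gaussian_quantile"}.
#' @param t_min,t_max ladder bounds in K, \code{t_min < t_max}.
#' @param n number of temperatures (>= 2).
#' @param center,width normal parameters in K (gaussian mode only).
#' @return Strictly increasing numeric vector of length \code{n}.
#' @export
make_temperature_ladder <- function(kind = c("log", "gaussian_quantile"),
                                    t_min, t_max, n,
                                    center = NULL, width = NULL) {
  kind <- match.arg(kind)
  if (!(t_min > 0 && t_min < t_max)) stop("need 0 < t_min < t_max")
  if (n < 2L) stop("need n >= 2 temperatures")
  if (kind == "log")
    return(exp(seq(log(t_min), log(t_max), length.out = n)))
  if (is.null(center) || is.null(width))
    stop("gaussian_quantile mode requires center and width")
  p <- seq(stats::pnorm(t_min, center, width),
           stats::pnorm(t_max, center, width), length.out = n)
  out <- stats::qnorm(p, center, width)
  out[1] <- t_min; out[n] <- t_max
  out
}

#' Parameters of the two-state replica-exchange energy model
#'
#' A minimal two-state (ordered aggregate vs disordered coil) model with a
#' single placed specific-heat peak: the ordered state is stabilized by
#' \code{delta_e}, the free-energy gap is linearized around the melting
#' temperature, dG(T) = delta_e (T/tm - 1) (so dG(tm) = 0), and energies
#' carry Gaussian fluctuations of width \code{sigma}.
#'
#' @param tm melting temperature in K; must lie inside the ladder range.
#' @param delta_e ordered-state stabilization in kcal/mol (> 0).
#' @param sigma Gaussian energy fluctuation in kcal/mol (> 0).
#' @param ladder replica temperature ladder (K, strictly increasing).
#' @param n_steps samples per temperature.
#' @param exchange_every attempt an exchange every this many steps.
#' @param seed integer RNG seed.
#' @return An object of class \code{two_state_params}.
#' @export
two_state_params <- function(tm, delta_e, sigma, ladder, n_steps,
                             exchange_every = 10L, seed = 1L) {
  if (any(diff(ladder) <= 0)) stop("ladder must be strictly increasing")
  if (tm < min(ladder) || tm > max(ladder))
    stop("tm must lie within the ladder range")
  if (delta_e <= 0 || sigma <= 0) stop("delta_e and sigma must be positive")
  structure(list(tm = tm, delta_e = delta_e, sigma = sigma,
                 ladder = as.numeric(ladder), n_steps = as.integer(n_steps),
                 exchange_every = as.integer(exchange_every),
                 seed = as.integer(seed)),
            class = "two_state_params")
}

#' Simulate a two-state replica-exchange energy trace
#'
#' At every step each temperature slot resamples its order state from the
#' two-state Gibbs distribution at its temperature and records an energy of
#' -delta_e (ordered) or 0 (disordered) plus Gaussian noise. Every
#' \code{exchange_every} steps one randomly chosen adjacent temperature
#' pair attempts a Metropolis swap (see [exchange_probability()]) of its
#' walkers, which is recorded in the exchange log. Fully reproducible
#' under the seed.
#'
#' @param params a \code{two_state_params}.
#' @return List with elements \code{trace} (an \code{remd_trace} whose
#'   samples are indexed by temperature slot), \code{exchange_log}
#'   (data.frame step/slot_i/slot_j/accepted, 0-based), \code{ordered}
#'   (list of 0/1 vectors per temperature) and \code{walker} (n_steps x
#'   n_slots matrix of 0-based walker ids per slot).
#' @export
simulate_two_state_remd <- function(params) {
  stopifnot(inherits(params, "two_state_params"))
  set.seed(params$seed)
  ladder <- params$ladder
  nT <- length(ladder)
  ns <- params$n_steps
  dg <- params$delta_e * (ladder / params$tm - 1)
  p_ord <- 1 / (1 + exp(dg / (.kB * ladder)))
  energies <- matrix(0, ns, nT)
  ordered <- matrix(0L, ns, nT)
  walker <- matrix(0L, ns, nT)
  slot_walker <- seq_len(nT) - 1L
  log_rows <- list()
  for (s in seq_len(ns)) {
    st <- as.integer(stats::runif(nT) < p_ord)
    e <- -params$delta_e * st + stats::rnorm(nT, 0, params$sigma)
    ordered[s, ] <- st
    energies[s, ] <- e
    if (nT > 1L && (s - 1L) %% params$exchange_every == 0L && s > 1L) {
      t1 <- sample.int(nT - 1L, 1L)
      p <- exchange_probability(e[t1], ladder[t1], e[t1 + 1L], ladder[t1 + 1L])
      acc <- stats::runif(1) < p
      if (acc) slot_walker[c(t1, t1 + 1L)] <- slot_walker[c(t1 + 1L, t1)]
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(step = s - 1L, slot_i = t1 - 1L, slot_j = t1,
                   accepted = as.integer(acc))
    }
    walker[s, ] <- slot_walker
  }
  exchange_log <- if (length(log_rows)) do.call(rbind, log_rows)
    else data.frame(step = integer(0), slot_i = integer(0),
                    slot_j = integer(0), accepted = integer(0))
  trace <- remd_trace(ladder, lapply(seq_len(nT), function(t) energies[, t]),
                      exchange_log = exchange_log)
  list(trace = trace, exchange_log = exchange_log,
       ordered = lapply(seq_len(nT), function(t) ordered[, t]),
       walker = walker)
}
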