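# Replica-exchange thermodynamics: Metropolis exchange probability,
# specific heat (direct and WHAM-reweighted), melting temperature, and
# Boltzmann free-energy differences between strand arrangements.
#
# Energies are in kcal/mol, temperatures in K, k_B = 0.0019872 kcal/mol/K.

#' Metropolis replica-exchange acceptance probability
#'
#' For replicas i and j with energies E_i, E_j at temperatures T_i, T_j,
#' p = min(1, exp[(1/kT_i - 1/kT_j) (E_i - E_j)]).
#'
#' @param E_i,E_j potential energies in kcal/mol.
#' @param T_i,T_j temperatures in K (> 0).
#' @return Acceptance probability in [0, 1].
#' @export
exchange_probability <- function(E_i, T_i, E_j, T_j) {
  if (any(c(T_i, T_j) <= 0)) stop("temperatures must be positive")
  expo <- (1 / (.kB * T_i) - 1 / (.kB * T_j)) * (E_i - E_j)
  min(1, exp(expo))
}

#' Specific heat from energy fluctuations at one temperature
#'
#' Cv = (<E^2> - <E>^2) / (k_B T^2), using the population variance.
#'
#' @param energies numeric vector of potential energies (kcal/mol) sampled
#'   at temperature \code{T}; at least 2 samples.
#' @param T temperature in K.
#' @return Specific heat in kcal/mol/K.
#' @export
specific_heat_direct <- function(energies, T) {
  if (length(energies) < 2L) stop("need at least 2 energy samples")
  if (T <= 0) stop("temperature must be positive")
  v <- mean(energies^2) - mean(energies)^2
  max(v, 0) / (.kB * T^2)
}

#' Construct a replica energy trace
#'
#' @param ladder numeric vector of temperatures in K, strictly increasing.
#' @param samples list of numeric vectors, one per ladder temperature, of
#'   potential energies in kcal/mol.
#' @param exchange_log optional data.frame (step, slot_i, slot_j, accepted).
#' @return An object of class \code{remd_trace}.
#' @export
remd_trace <- function(ladder, samples, exchange_log = NULL) {
  if (length(ladder) < 1L || any(diff(ladder) <= 0))
    stop("ladder must be strictly increasing")
  if (length(samples) != length(ladder))
    stop("one sample vector per ladder temperature required")
  if (any(vapply(samples, length, 0L) < 1L))
    stop("every temperature needs at least one sample")
  structure(list(ladder = as.numeric(ladder),
                 samples = lapply(samples, as.numeric),
                 exchange_log = exchange_log),
            class = "remd_trace")
}

#' @export
print.remd_trace <- function(x, ...) {
  cat(sprintf("remd_trace: %d temperatures (%.1f-%.1f K), %d samples total\n",
              length(x$ladder), min(x$ladder), max(x$ladder),
              sum(vapply(x$samples, length, 0L))))
  invisible(x)
}

#' Write / read an energy trace as TSV (step, temperature_index, energy)
#'
#' Temperature indices are 0-based; the ladder is recorded in a header
#' comment line.
#'
#' @param trace an \code{remd_trace}.
#' @param path file path.
#' @return \code{write_trace}: invisibly, \code{path}; \code{read_trace}:
#'   an \code{remd_trace}.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ladder\t",
                    paste(format(trace$ladder, digits = 10), collapse = "\t")),
             con)
  writeLines("step\ttemperature_index\tenergy", con)
  for (t in seq_along(trace$samples)) {
    e <- trace$samples[[t]]
    writeLines(sprintf("%d\t%d\t%.8g", seq_along(e) - 1L, t - 1L, e), con)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# ladder"))
    stop("trace file missing '# ladder' header: ", path)
  ladder <- as.numeric(strsplit(first, "\t")[[1]][-1])
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  samples <- lapply(seq_along(ladder) - 1L, function(t) {
    sub <- df[df$temperature_index == t, ]
    sub$energy[order(sub$step)]
  })
  remd_trace(ladder, samples)
}

# log(sum(exp(v))) without overflow
logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Binless temperature-WHAM self-consistency
#'
#' Solves the standard multiple-histogram equations in their binless
#' (sample-based) form by fixed-point iteration on the per-temperature
#' log-normalizers f_t:
#'   f_t = -log sum_n exp(-beta_t E_n - D_n),
#'   D_n = log sum_k N_k exp(f_k - beta_k E_n),
#' pooling all samples E_n over the ladder. The resulting weights let any
#' observable be reweighted to an arbitrary temperature inside the ladder.
#'
#' @param trace an \code{remd_trace}, or any list with elements
#'   \code{ladder} and \code{samples} (duplicated temperatures are allowed
#'   in the latter form).
#' @param tol convergence tolerance on the max change of the
#'   log-normalizers.
#' @param max_iter maximum number of fixed-point iterations; reaching it
#'   raises a warning and flags the result.
#' @return An object of class \code{wham_weights}: \code{ladder},
#'   \code{log_f} (normalizers, first fixed at 0), \code{energies} (pooled),
#'   \code{log_denom} (D_n), \code{n_k}, \code{residual}, \code{iterations},
#'   \code{converged}, \code{overlap_ok}.
#' @export
twham <- function(trace, tol = 1e-7, max_iter = 10000L) {
  ladder <- trace$ladder
  samples <- trace$samples
  nT <- length(ladder)
  n_k <- vapply(samples, length, 0L)
  E <- unlist(samples, use.names = FALSE)
  betas <- 1 / (.kB * ladder)
  # adjacent-temperature energy overlap check (ranges must intersect)
  overlap_ok <- TRUE
  if (nT > 1L) {
    for (t in seq_len(nT - 1L)) {
      if (min(samples[[t]]) > max(samples[[t + 1L]]) ||
          min(samples[[t + 1L]]) > max(samples[[t]])) overlap_ok <- FALSE
    }
    if (!overlap_ok)
      warning("no energy overlap between adjacent temperatures; ",
              "WHAM results will be of degraded accuracy")
  }
  M <- -outer(betas, E)                       # nT x N matrix of -beta_t E_n
  colmax <- function(A) Reduce(pmax, lapply(seq_len(nrow(A)), function(r) A[r, ]))
  log_f <- numeric(nT)
  residual <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    A <- M + (log(n_k) + log_f)               # recycled down columns
    m <- colmax(A)
    D <- m + log(colSums(exp(A - rep(m, each = nT))))
    B <- M - rep(D, each = nT)
    mb <- apply(B, 1L, max)
    new_f <- -(mb + log(rowSums(exp(B - mb))))
    new_f <- new_f - new_f[1L]
    residual <- max(abs(new_f - log_f))
    log_f <- new_f
    if (residual < tol || iter >= max_iter) break
  }
  if (residual >= tol)
    warning(sprintf("WHAM not converged after %d iterations (residual %.3g)",
                    iter, residual))
  # final D with converged f
  A <- M + (log(n_k) + log_f)
  m <- colmax(A)
  D <- m + log(colSums(exp(A - rep(m, each = nT))))
  structure(list(ladder = ladder, log_f = log_f, energies = E,
                 log_denom = D, n_k = n_k, residual = residual,
                 iterations = iter, converged = residual < tol,
                 overlap_ok = overlap_ok),
            class = "wham_weights")
}

#' Normalized WHAM sample weights at a target temperature
#'
#' @param weights a \code{wham_weights} object.
#' @param T target temperature in K, inside the ladder range.
#' @return Numeric vector of per-sample probabilities summing to 1.
#' @export
wham_sample_weights <- function(weights, T) {
  if (T < min(weights$ladder) || T > max(weights$ladder))
    stop("target temperature outside the ladder range (no extrapolation)")
  lw <- -weights$energies / (.kB * T) - weights$log_denom
  lw <- lw - logsumexp(lw)
  exp(lw)
}

#' WHAM-reweighted specific-heat curve and melting temperature
#'
#' Evaluates Cv(T) = (<E^2>_T - <E>_T^2) / (k_B T^2) on a temperature grid
#' using the reweighted ensemble averages, and reads off the melting
#' temperature as the grid argmax (ties resolve to the lowest temperature).
#' In the single-temperature case the weights are uniform and the curve
#' reduces to [specific_heat_direct()].
#'
#' @param weights a \code{wham_weights} from [twham()].
#' @param grid numeric vector of temperatures in K; must lie within the
#'   ladder range (no extrapolation).
#' @return An object of class \code{cv_curve}: \code{grid}, \code{cv}
#'   (kcal/mol/K), \code{tm} (K).
#' @export
cv_curve <- function(weights, grid) {
  if (min(grid) < min(weights$ladder) || max(grid) > max(weights$ladder))
    stop("grid outside [ladder min, ladder max] (no extrapolation)")
  E <- weights$energies
  cv <- vapply(grid, function(T) {
    w <- wham_sample_weights(weights, T)
    m1 <- sum(w * E)
    m2 <- sum(w * E^2)
    max(m2 - m1^2, 0) / (.kB * T^2)
  }, 0)
  structure(list(grid = as.numeric(grid), cv = cv,
                 tm = grid[which.max(cv)]),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("cv_curve: %d grid points (%.1f-%.1f K), Tm = %.1f K, peak Cv = %.4g kcal/mol/K\n",
              length(x$grid), min(x$grid), max(x$grid), x$tm, max(x$cv)))
  invisible(x)
}

#' Write a specific-heat curve as TSV (T, Cv)
#'
#' @param curve a \code{cv_curve}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_cv_curve <- function(curve, path) {
  utils::write.table(data.frame(T = curve$grid, Cv = curve$cv), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Free-energy difference between two populations
#'
#' The Boltzmann free-energy difference in favor of the first arrangement:
#' ddG = k_B T ln(p_num / p_den), positive when p_num > p_den. Used to
#' quantify, e.g., the preference for antiparallel over parallel strand
#' arrangements from their observed populations at one temperature.
#'
#' @param p_num,p_den populations (any common unit: percent or fraction);
#'   both must be positive unless a pseudo-count is supplied.
#' @param T temperature in K.
#' @param pseudo optional pseudo-count added to both populations (off by
#'   default); use when a population is zero by sampling.
#' @return Free-energy difference in kcal/mol.
#' @export
free_energy_difference <- function(p_num, p_den, T, pseudo = 0) {
  p_num <- p_num + pseudo
  p_den <- p_den + pseudo
  if (p_num <= 0 || p_den <= 0)
    stop("populations must be positive; for zero populations consider the ",
         "'pseudo' pseudo-count argument")
  if (T <= 0) stop("temperature must be positive")
  .kB * T * log(p_num / p_den)
}
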