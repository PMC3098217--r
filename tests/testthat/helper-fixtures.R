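# Shared fixture builders and independent oracles for the test suite.

# a bare residue for dssp_energy
res_at <- function(N, CA = N + c(1.4, 0, 0), C = CA + c(1.5, 0, 0),
                   O = C + c(0, 1.23, 0), H = NULL) {
  list(N = N, CA = CA, C = C, O = O, H = H)
}

# random sheet specification with at most max_chains chains
random_sheet_spec <- function(max_chains = 20L) {
  repeat {
    nsheets <- sample(1:3, 1)
    sizes <- sample(1:8, nsheets, replace = TRUE)
    if (sum(sizes) <= max_chains) break
  }
  ori <- lapply(pmax(sizes - 1L, 0L), function(m)
    sample(c("parallel", "antiparallel"), m, replace = TRUE))
  reg <- lapply(pmax(sizes - 1L, 0L), function(m)
    sample(-2:2, m, replace = TRUE))
  sheet_spec(sizes, ori, reg)
}

# independent oracle: connected components by brute-force transitive
# closure over the pair list
brute_force_components <- function(pairs, ids) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(adj) <- TRUE
  for (r in seq_len(nrow(pairs))) {
    adj[pairs$a[r], pairs$b[r]] <- TRUE
    adj[pairs$b[r], pairs$a[r]] <- TRUE
  }
  repeat {
    newadj <- (adj %*% adj) > 0
    if (identical(newadj, adj)) break
    adj <- newadj
  }
  groups <- unique(apply(adj, 1, function(row) paste(ids[row], collapse = " ")))
  sort(groups)
}

# independent O(n^2) medoid over the spec-defined feature
brute_force_medoid <- function(records, type) {
  feat <- function(r) {
    sizes <- sort(vapply(r$sheets, function(s) s$size, 0L), decreasing = TRUE)
    np <- nrow(r$pairs)
    fp <- if (np == 0) 0 else sum(r$pairs$orientation == "parallel") / np
    list(s = sizes, fp = fp, b = r$beta_content)
  }
  d <- function(x, y) {
    L <- max(length(x$s), length(y$s))
    pad <- function(v) c(v, rep(0, L - length(v)))
    sum(abs(pad(x$s) - pad(y$s))) + abs(x$fp - y$fp) + abs(x$b - y$b)
  }
  idx <- which(vapply(records, function(r) r$config_type, "") == type)
  fs <- lapply(records[idx], feat)
  best <- Inf; best_i <- NA
  for (a in seq_along(idx)) {
    m <- mean(vapply(seq_along(idx), function(b) d(fs[[a]], fs[[b]]), 0))
    if (m < best - 1e-12) { best <- m; best_i <- idx[a] }
  }
  best_i
}

# a small rotation matrix about an arbitrary axis
rot_xyz <- function(ax = 0.3, ay = -0.8, az = 1.2) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)), 3,
               byrow = TRUE)
  Rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1), 3,
               byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# thermodynamically consistent Gaussian-energy trace: at inverse
# temperature beta the energies are N(-sigma^2 * beta, sigma), which
# corresponds to a quadratic density of states with constant-variance
# fluctuations, so Cv(T) = sigma^2 / (kB T^2) exactly.
gaussian_energy_trace <- function(ladder, sigma, n) {
  kB <- kB_kcal()
  remd_trace(ladder, lapply(ladder, function(T)
    stats::rnorm(n, -sigma^2 / (kB * T), sigma)))
}

# two-level (Schottky) trace: states 0 / eps with degeneracy g on the
# excited level, sampled exactly from the Boltzmann distribution.
schottky_trace <- function(ladder, eps, g, n) {
  kB <- kB_kcal()
  remd_trace(ladder, lapply(ladder, function(T) {
    b <- 1 / (kB * T)
    p1 <- g * exp(-b * eps) / (1 + g * exp(-b * eps))
    eps * (stats::runif(n) < p1)
  }))
}

schottky_cv <- function(T, eps, g) {
  kB <- kB_kcal()
  b <- 1 / (kB * T)
  kB * (b * eps)^2 * g * exp(-b * eps) / (1 + g * exp(-b * eps))^2
}

default_ladder <- function()
  make_temperature_ladder("gaussian_quantile", 240, 340, 12,
                          center = 283, width = 25)

# strip S3 subclass + attachments for value-only data.frame comparison
plain_df <- function(d) {
  d <- as.data.frame(d)
  class(d) <- "data.frame"
  attr(d, "ij") <- NULL
  rownames(d) <- NULL
  d
}
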