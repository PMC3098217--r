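# Per-temperature ensemble statistics, convergence checking, replica
# demultiplexing, nucleation detection and representative selection.

# Pool pair/sheet statistics from a list of topology_records.
pool_topology_stats <- function(records) {
  ori <- unlist(lapply(records, function(r) r$pairs$orientation),
                use.names = FALSE)
  reg <- unlist(lapply(records, function(r) r$pairs$register),
                use.names = FALSE)
  reg <- reg[!is.na(reg)]
  chars <- unlist(lapply(records, function(r)
    vapply(r$sheets, `[[`, "", "character")), use.names = FALSE)
  chars <- chars[!is.na(chars)]
  beta <- vapply(records, `[[`, 0, "beta_content")
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(
    pct_parallel = pct(sum(ori == "parallel"), length(ori)),
    pct_antiparallel = pct(sum(ori == "antiparallel"), length(ori)),
    pct_undefined = pct(sum(ori == "undefined"), length(ori)),
    pct_fully_parallel = pct(sum(chars == "fully_parallel"), length(chars)),
    pct_fully_antiparallel = pct(sum(chars == "fully_antiparallel"),
                                 length(chars)),
    pct_mixed = pct(sum(chars == "mixed"), length(chars)),
    beta_pct = 100 * mean(beta),
    reg_in_register = pct(sum(reg == 0L), length(reg)),
    reg_shift_1 = pct(sum(abs(reg) == 1L), length(reg)),
    reg_shift_2plus = pct(sum(abs(reg) >= 2L), length(reg)))
}

#' Tabulate per-temperature ensemble statistics
#'
#' Builds the standard summary table of a replica-exchange run: at each
#' temperature, the populations of the observed configuration types, the
#' percentage of parallel / antiparallel / undefined adjacent strand pairs,
#' the sheet-character fractions (fully parallel / fully antiparallel /
#' mixed, over multi-strand sheets), the beta-content, and the register
#' fractions (in-register, out-of-register by 1, by 2 or more, over pairs
#' with a defined orientation). Pair- and sheet-level statistics are pooled
#' over all frames in the analysis window; type populations and
#' beta-content are per-frame averages.
#'
#' @param records list of \code{topology_record}s, one per frame.
#' @param temperature numeric vector of frame temperatures (K), parallel to
#'   \code{records}.
#' @param window NULL for the default window (the final half of the frames
#'   at each temperature), or an integer pair \code{c(first, last)} of
#'   1-based frame indices within each temperature's series.
#' @return An object of class \code{ensemble_table}: \code{temperatures},
#'   \code{types}, \code{populations} (types x temperatures matrix, percent,
#'   columns sum to 100), \code{stats} (data.frame, one row per
#'   temperature), \code{n_frames}.
#' @export
tabulate_ensemble <- function(records, temperature, window = NULL) {
  stopifnot(length(records) == length(temperature))
  temps <- sort(unique(temperature))
  groups <- lapply(temps, function(tt) records[temperature == tt])
  groups <- lapply(groups, function(g) {
    n <- length(g)
    idx <- if (is.null(window)) seq.int(floor(n / 2) + 1L, n)
           else seq.int(max(1L, window[1]), min(n, window[2]))
    if (length(idx) < 1L || idx[1] > n) stop("empty analysis window")
    g[idx]
  })
  types <- unique(unlist(lapply(groups, function(g)
    vapply(g, `[[`, "", "config_type"))))
  # order types by total population, then lexicographically
  counts <- sapply(types, function(ty) sum(unlist(lapply(groups, function(g)
    sum(vapply(g, `[[`, "", "config_type") == ty)))))
  types <- types[order(-counts, types)]
  pop <- sapply(groups, function(g) {
    obs <- vapply(g, `[[`, "", "config_type")
    100 * vapply(types, function(ty) mean(obs == ty), 0)
  })
  pop <- matrix(pop, nrow = length(types),
                dimnames = list(types, format(temps)))
  stats <- do.call(rbind, lapply(groups, function(g)
    as.data.frame(pool_topology_stats(g))))
  structure(list(temperatures = temps, types = types, populations = pop,
                 stats = stats,
                 n_frames = vapply(groups, length, 0L)),
            class = "ensemble_table")
}

#' @export
print.ensemble_table <- function(x, ...) {
  cat(sprintf("ensemble_table: %d temperature(s), %d configuration type(s)\n",
              length(x$temperatures), length(x$types)))
  print(round(x$populations, 1))
  invisible(x)
}

#' Write an ensemble table as TSV (row blocks) or JSON
#'
#' The TSV layout mirrors the conventional presentation: one column per
#' temperature; a block of configuration-type population rows, then the
#' orientation, sheet-character, beta-content and register rows.
#'
#' @param table an \code{ensemble_table}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_ensemble_table <- function(table, path) {
  pop <- table$populations
  stat_rows <- t(as.matrix(table$stats))
  rownames(stat_rows) <- c("% parallel", "% antiparallel", "% undefined",
                           "% fully parallel sheets",
                           "% fully antiparallel sheets", "% mixed sheets",
                           "beta-sheet content (%)", "% in-register",
                           "% shift by 1", "% shift by >=2")
  block <- rbind(pop, stat_rows)
  df <- data.frame(statistic = c(paste("type", rownames(pop)),
                                 rownames(stat_rows)),
                   round(block, 2), check.names = FALSE)
  names(df)[-1] <- format(table$temperatures)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_table
#' @export
ensemble_to_json <- function(table, path) {
  obj <- list(temperatures = table$temperatures, types = table$types,
              populations = apply(table$populations, 2, as.list),
              stats = table$stats, n_frames = table$n_frames)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}

#' Specific-heat convergence check over two time windows
#'
#' Computes a WHAM-reweighted Cv curve over two sampling windows of the
#' same trace and declares convergence when the melting-temperature
#' estimates agree within \code{tol_T} and the curves agree pointwise
#' within a relative tolerance \code{tol_c}. Relative deviation is measured
#' against the mean curve and evaluated only where the mean Cv exceeds 10%
#' of its peak, so that noise in the flat tails is not mistaken for
#' divergence.
#'
#' @param trace an \code{remd_trace}.
#' @param window_a,window_b integer pairs \code{c(first, last)} of 1-based
#'   sample indices per temperature; each window must keep at least 10
#'   samples at every temperature.
#' @param tol_T allowed melting-temperature shift in K.
#' @param tol_c allowed maximum relative Cv deviation (fraction).
#' @param grid_step Cv grid spacing in K.
#' @return List of class \code{cv_convergence}: \code{peak_shift} (K),
#'   \code{max_rel_dev}, \code{converged}, \code{curve_a}, \code{curve_b}.
#' @export
specific_heat_convergence <- function(trace, window_a, window_b,
                                      tol_T = 3, tol_c = 0.10,
                                      grid_step = 0.5) {
  slice <- function(w) {
    sub <- lapply(trace$samples, function(e) {
      idx <- seq.int(max(1L, w[1]), min(length(e), w[2]))
      e[idx]
    })
    if (any(vapply(sub, length, 0L) < 10L))
      stop("window leaves fewer than 10 samples at some temperature")
    remd_trace(trace$ladder, sub)
  }
  grid <- seq(min(trace$ladder), max(trace$ladder), by = grid_step)
  curve_a <- cv_curve(twham(slice(window_a)), grid)
  curve_b <- cv_curve(twham(slice(window_b)), grid)
  peak_shift <- abs(curve_a$tm - curve_b$tm)
  mid <- 0.5 * (curve_a$cv + curve_b$cv)
  mask <- mid >= 0.1 * max(mid)
  max_rel_dev <- max(abs(curve_a$cv - curve_b$cv)[mask] / mid[mask])
  structure(list(peak_shift = peak_shift, max_rel_dev = max_rel_dev,
                 converged = peak_shift <= tol_T && max_rel_dev <= tol_c,
                 curve_a = curve_a, curve_b = curve_b),
            class = "cv_convergence")
}

#' @export
print.cv_convergence <- function(x, ...) {
  cat(sprintf("cv_convergence: peak shift %.2f K, max relative deviation %.1f%% -> %s\n",
              x$peak_shift, 100 * x$max_rel_dev,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Demultiplex replica-exchange walkers through temperature space
#'
#' Replays an exchange log as permutation tracking: walkers start in their
#' own temperature slots; every accepted swap exchanges the walkers in the
#' two slots from that step on. Following a walker through the temperature
#' ladder reconstitutes its continuous trajectory, the raw material for
#' aggregation-pathway analysis.
#'
#' @param exchange_log data.frame with columns \code{step}, \code{slot_i},
#'   \code{slot_j}, \code{accepted} (0/1); steps and slots 0-based.
#' @param n_replicas number of temperature slots / walkers.
#' @param n_steps number of steps to unroll.
#' @return Integer matrix of \code{n_steps} rows (step s = row s + 1) and
#'   \code{n_replicas} columns (walker w = column w + 1) holding the
#'   0-based temperature slot of each walker at each step.
#' @export
demux_replicas <- function(exchange_log, n_replicas, n_steps) {
  path <- matrix(0L, n_steps, n_replicas)
  slot_of_walker <- seq_len(n_replicas) - 1L
  ev <- exchange_log[exchange_log$accepted != 0, , drop = FALSE]
  if (nrow(ev)) {
    ev <- ev[order(ev$step), , drop = FALSE]
    touched <- c(ev$slot_i, ev$slot_j)
    if (any(touched < 0 | touched >= n_replicas))
      stop("exchange log references invalid slots")
    for (s in unique(ev$step)) {
      sl <- c(ev$slot_i[ev$step == s], ev$slot_j[ev$step == s])
      if (anyDuplicated(sl))
        stop("inconsistent exchange log: slot swapped twice at step ", s)
    }
  }
  k <- 1L
  for (s in seq_len(n_steps) - 1L) {
    while (k <= nrow(ev) && ev$step[k] <= s) {
      if (ev$step[k] == s) {
        wi <- which(slot_of_walker == ev$slot_i[k])
        wj <- which(slot_of_walker == ev$slot_j[k])
        slot_of_walker[c(wi, wj)] <- slot_of_walker[c(wj, wi)]
      }
      k <- k + 1L
    }
    path[s + 1L, ] <- slot_of_walker
  }
  path
}

#' Invert walker paths back to slot occupancy
#'
#' The inverse of [demux_replicas()]: for each step, which walker occupies
#' each temperature slot. Applying it to the demuxed paths and reading off
#' walkers per slot reconstitutes the temperature-sorted frame assignment.
#'
#' @param paths matrix from [demux_replicas()].
#' @return Integer matrix of the same shape: entry [s, t] is the 0-based
#'   walker occupying slot t - 1 at step s - 1.
#' @export
remux_replicas <- function(paths) {
  out <- paths
  for (s in seq_len(nrow(paths)))
    out[s, paths[s, ] + 1L] <- seq_len(ncol(paths)) - 1L
  out
}

#' Write / read an exchange log as TSV
#'
#' Columns: step, slot_i, slot_j, accepted (0/1).
#'
#' @param exchange_log the log data.frame.
#' @param path file path.
#' @return \code{write_exchange_log}: invisibly, \code{path};
#'   \code{read_exchange_log}: the log data.frame.
#' @export
write_exchange_log <- function(exchange_log, path) {
  utils::write.table(exchange_log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_exchange_log
#' @export
read_exchange_log <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Detect nucleation events along walker trajectories
#'
#' Aggregation of short amyloid peptides is seeded by small ordered units
#' (dimer/trimer/tetramer sheets). For each walker series of classified
#' frames, reports the first frame at which any sheet reaches the seed
#' threshold, together with the size of that seed sheet.
#'
#' @param walker_series list (one element per walker) of lists of
#'   \code{topology_record}s, or of integer vectors of per-frame maximum
#'   sheet size.
#' @param seed_threshold minimum sheet size (strands) counting as a seed.
#' @return data.frame with columns \code{walker_id} (0-based),
#'   \code{frame_index} (0-based) and \code{seed_size}; walkers that never
#'   nucleate are absent.
#' @export
detect_nucleation <- function(walker_series, seed_threshold = 2L) {
  rows <- lapply(seq_along(walker_series), function(w) {
    series <- walker_series[[w]]
    maxsize <- vapply(series, function(fr) {
      if (inherits(fr, "topology_record"))
        as.integer(max(vapply(fr$sheets, function(s) as.numeric(s$size), 0)))
      else as.integer(max(fr))
    }, 0L)
    hit <- which(maxsize >= seed_threshold)[1]
    if (is.na(hit)) return(NULL)
    data.frame(walker_id = w - 1L, frame_index = hit - 1L,
               seed_size = maxsize[hit])
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(walker_id = integer(0), frame_index = integer(0),
                      seed_size = integer(0)))
  do.call(rbind, rows)
}

# feature vector of a topology record, for medoid distances
topology_feature <- function(record) {
  sizes <- sort(vapply(record$sheets, `[[`, 0L, "size"), decreasing = TRUE)
  np <- nrow(record$pairs)
  frac_par <- if (np == 0L) 0 else sum(record$pairs$orientation == "parallel") / np
  list(sizes = sizes, frac_par = frac_par, beta = record$beta_content)
}

topology_feature_dist <- function(fa, fb) {
  L <- max(length(fa$sizes), length(fb$sizes))
  pad <- function(v) c(v, rep(0L, L - length(v)))
  sum(abs(pad(fa$sizes) - pad(fb$sizes))) +
    abs(fa$frac_par - fb$frac_par) + abs(fa$beta - fb$beta)
}

#' Select representative frames by frequency of occurrence
#'
#' For each of the top-k configuration types by population, picks the
#' medoid frame of that type: the frame minimizing the mean feature
#' distance to the other frames of the type, where the feature is the
#' sheet-size multiset, the fraction of parallel pairs and the
#' beta-content. Ties resolve to the earliest frame.
#'
#' @param records list of \code{topology_record}s (classified frames).
#' @param k number of configuration types to represent; if larger than the
#'   number of observed types, all types are returned.
#' @param mode selection mode; only \code{"frequency"} is supported.
#' @return data.frame with columns \code{config_type},
#'   \code{population_pct} and \code{frame_index} (1-based index into
#'   \code{records}).
#' @export
select_representatives <- function(records, k = 1L, mode = "frequency") {
  mode <- match.arg(mode, "frequency")
  types <- vapply(records, `[[`, "", "config_type")
  tab <- sort(table(types), decreasing = TRUE)
  top <- names(tab)[seq_len(min(k, length(tab)))]
  feats <- lapply(records, topology_feature)
  rows <- lapply(top, function(ty) {
    idx <- which(types == ty)
    dmat <- outer(idx, idx, Vectorize(function(aa, bb)
      topology_feature_dist(feats[[aa]], feats[[bb]])))
    med <- idx[which.min(rowMeans(dmat))]
    data.frame(config_type = ty,
               population_pct = 100 * length(idx) / length(records),
               frame_index = med, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
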