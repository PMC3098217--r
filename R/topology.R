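# Strand-attachment topology: configuration types, orientation, register,
# sheet character and beta-content.
#
# Chains are clustered into beta-sheets by inter-chain backbone hydrogen
# bonding: a single surviving hydrogen bond attaches two strands (short
# 7-residue peptides justify the one-bond cutoff), except that bonds
# involving the N-terminal glycine (residue 0) are discarded first. The
# configuration type is the multiset of sheet sizes written as descending
# integers, e.g. "8 7 5" = three sheets of 8, 7 and 5 strands.

# round to integer, with exact .5 ties rounded toward zero
round_half_to_zero <- function(x) sign(x) * ceiling(abs(x) - 0.5)

#' Build the strand-pair table from detected hydrogen bonds
#'
#' Keeps inter-chain bonds only, removes every bond whose donor or acceptor
#' is residue 0 of its chain (the N-terminal glycine), and aggregates the
#' survivors per unordered chain pair. Orientation and register are
#' computed from the bonded residue index pairs of each chain pair.
#'
#' @param x the \code{assembly} the bonds were detected on.
#' @param hbonds an \code{hbond_table} from [detect_hbonds()] on \code{x}.
#' @return A data.frame of class \code{strand_pairs} with columns \code{a},
#'   \code{b} (chain ids, a before b in assembly order), \code{n_hbonds},
#'   \code{orientation} (\code{"parallel"}, \code{"antiparallel"} or
#'   \code{"undefined"}) and \code{register} (integer shift, NA when the
#'   orientation is undefined). The bonded index pairs of each chain pair
#'   are attached as the \code{"ij"} attribute (list of 2-column matrices,
#'   i on chain a, j on chain b).
#' @export
strand_pair_graph <- function(x, hbonds) {
  stopifnot(inherits(x, "assembly"))
  ids <- names(x$chains)
  ord <- stats::setNames(seq_along(ids), ids)
  hb <- hbonds[hbonds$donor_chain != hbonds$acceptor_chain &
                 hbonds$donor_res > 0L & hbonds$acceptor_res > 0L, ,
               drop = FALSE]
  empty <- data.frame(a = character(0), b = character(0),
                      n_hbonds = integer(0), orientation = character(0),
                      register = integer(0), stringsAsFactors = FALSE)
  if (nrow(hb) == 0L) {
    attr(empty, "ij") <- list()
    class(empty) <- c("strand_pairs", "data.frame")
    return(empty)
  }
  swap <- ord[hb$donor_chain] > ord[hb$acceptor_chain]
  a <- ifelse(swap, hb$acceptor_chain, hb$donor_chain)
  b <- ifelse(swap, hb$donor_chain, hb$acceptor_chain)
  i <- ifelse(swap, hb$acceptor_res, hb$donor_res)   # residue on chain a
  j <- ifelse(swap, hb$donor_res, hb$acceptor_res)   # residue on chain b
  key <- paste(a, b, sep = "\r")
  keys <- unique(key[order(ord[a], ord[b])])
  rows <- lapply(keys, function(k) {
    sel <- key == k
    ij <- cbind(i = i[sel], j = j[sel])
    ab <- strsplit(k, "\r", fixed = TRUE)[[1]]
    ori <- pair_orientation(ij)
    reg <- if (ori == "undefined") NA_integer_ else
      pair_register(ori, ij, n_residues(x$chains[[ab[2]]]))
    list(a = ab[1], b = ab[2], n = sum(sel), ori = ori, reg = reg, ij = ij)
  })
  out <- data.frame(a = vapply(rows, `[[`, "", "a"),
                    b = vapply(rows, `[[`, "", "b"),
                    n_hbonds = vapply(rows, `[[`, 0L, "n"),
                    orientation = vapply(rows, `[[`, "", "ori"),
                    register = vapply(rows, `[[`, NA_integer_, "reg"),
                    stringsAsFactors = FALSE)
  attr(out, "ij") <- lapply(rows, `[[`, "ij")
  class(out) <- c("strand_pairs", "data.frame")
  out
}

#' Orientation of a bonded strand pair
#'
#' A pair attached through a single distinct bonded residue pair has an
#' undefined orientation. Otherwise the sign of the least-squares slope of
#' the partner indices j against i decides: positive slope = parallel,
#' negative = antiparallel, zero (tie) = undefined.
#'
#' @param ij 2-column matrix of bonded residue index pairs (i on strand a,
#'   j on strand b).
#' @return One of \code{"parallel"}, \code{"antiparallel"},
#'   \code{"undefined"}.
#' @export
pair_orientation <- function(ij) {
  ij <- unique(ij[, 1:2, drop = FALSE])
  if (nrow(ij) < 2L) return("undefined")
  i <- ij[, 1]; j <- ij[, 2]
  sxx <- sum((i - mean(i))^2)
  sxy <- sum((i - mean(i)) * (j - mean(j)))
  if (sxx == 0 || sxy == 0) return("undefined")
  if (sxy > 0) "parallel" else "antiparallel"
}

#' Register shift of an oriented strand pair
#'
#' For a parallel pair the shift is the rounded median of j - i over the
#' bonded residue pairs; for an antiparallel pair, of i + j - (L - 1) where
#' L is the strand length. Shift 0 means in-register; |shift| = k means
#' out-of-register by k residues. Median ties round toward zero, a
#' deliberate conservative bias toward "in-register".
#'
#' @param orientation \code{"parallel"} or \code{"antiparallel"}.
#' @param ij 2-column matrix of bonded residue index pairs.
#' @param strand_length number of residues L of strand b.
#' @return Integer shift.
#' @export
pair_register <- function(orientation, ij, strand_length) {
  orientation <- match.arg(orientation, c("parallel", "antiparallel"))
  v <- if (orientation == "parallel") ij[, 2] - ij[, 1]
       else ij[, 1] + ij[, 2] - (strand_length - 1)
  as.integer(round_half_to_zero(stats::median(v)))
}

#' Group strands into beta-sheets
#'
#' Sheets are the connected components of the strand-attachment graph;
#' chains without any attachment are singleton sheets (free chains). A
#' multi-strand sheet is \code{"fully_parallel"} when every adjacent pair is
#' parallel, \code{"fully_antiparallel"} when every pair is antiparallel,
#' and \code{"mixed"} otherwise (pairs of undefined orientation force
#' mixed). Singletons have character NA.
#'
#' @param pairs a \code{strand_pairs} table.
#' @param chain_ids character vector of all chain ids, in assembly order.
#' @return List of sheets, each \code{list(strands, size, character)},
#'   ordered by decreasing size (ties by first strand's assembly order).
#' @export
build_sheets <- function(pairs, chain_ids) {
  g <- igraph::graph_from_data_frame(
    pairs[, c("a", "b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = chain_ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  sheets <- lapply(seq_len(comp$no), function(k) {
    strands <- chain_ids[comp$membership[chain_ids] == k]
    size <- length(strands)
    chr <- NA_character_
    if (size > 1L) {
      ori <- pairs$orientation[pairs$a %in% strands]
      chr <- if (all(ori == "parallel")) "fully_parallel"
             else if (all(ori == "antiparallel")) "fully_antiparallel"
             else "mixed"
    }
    list(strands = strands, size = size, character = chr)
  })
  first_ord <- vapply(sheets, function(s) match(s$strands[1], chain_ids), 0L)
  sizes <- vapply(sheets, `[[`, 0L, "size")
  sheets[order(-sizes, first_ord)]
}

#' Classify the beta-sheet topology of an assembly
#'
#' Runs the full pipeline: hydrogen-bond detection, glycine-excluded
#' strand-pair aggregation, and sheet decomposition. The beta-content is
#' the fraction of all residues (glycines included in the denominator)
#' participating in at least one surviving inter-strand hydrogen bond as
#' donor or acceptor.
#'
#' @param x an \code{assembly}. Amide hydrogens are reconstructed
#'   automatically where absent.
#' @param energy_cutoff hydrogen-bond energy cutoff in kcal/mol.
#' @return An object of class \code{topology_record}:
#'   \code{config_type} (string, sheet sizes sorted descending), \code{sheets}
#'   (from [build_sheets()]), \code{pairs} (a \code{strand_pairs} table),
#'   \code{beta_content} (fraction in [0, 1]), \code{n_chains},
#'   \code{n_residues}.
#' @export
classify <- function(x, energy_cutoff = -0.5) {
  stopifnot(inherits(x, "assembly"))
  f <- flatten_assembly(x)
  if (all(is.na(f$H[, 1])) && any(vapply(x$chains, n_residues, 0L) > 1L))
    x <- suppressWarnings(reconstruct_amide_hydrogens(x))
  hb <- detect_hbonds(x, energy_cutoff)
  pairs <- strand_pair_graph(x, hb)
  sheets <- build_sheets(pairs, names(x$chains))
  sizes <- sort(vapply(sheets, `[[`, 0L, "size"), decreasing = TRUE)
  # residues in >= 1 surviving inter-strand bond (for beta-content)
  surv <- hb[hb$donor_chain != hb$acceptor_chain &
               hb$donor_res > 0L & hb$acceptor_res > 0L, , drop = FALSE]
  tags <- unique(c(paste(surv$donor_chain, surv$donor_res),
                   paste(surv$acceptor_chain, surv$acceptor_res)))
  total <- sum(vapply(x$chains, n_residues, 0L))
  structure(list(config_type = paste(sizes, collapse = " "),
                 sheets = sheets, pairs = pairs,
                 beta_content = length(tags) / total,
                 n_chains = n_chains(x), n_residues = total),
            class = "topology_record")
}

#' @export
print.topology_record <- function(x, ...) {
  cat(sprintf("topology: configuration type \"%s\" (%d chains)\n",
              x$config_type, x$n_chains))
  cat(sprintf("  %d strand pair(s), beta-content %.1f%%\n",
              nrow(x$pairs), 100 * x$beta_content))
  invisible(x)
}

#' Export a topology record as JSON
#'
#' @param record a \code{topology_record}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
topology_to_json <- function(record, path) {
  obj <- list(
    config_type = record$config_type,
    beta_content = record$beta_content,
    n_chains = record$n_chains,
    sheets = lapply(record$sheets, function(s)
      list(strands = as.list(s$strands), size = s$size,
           character = s$character)),
    pairs = record$pairs[, c("a", "b", "n_hbonds", "orientation",
                             "register")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}

#' Write the per-pair strand table as TSV
#'
#' @param pairs a \code{strand_pairs} table.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_strand_pairs <- function(pairs, path) {
  df <- as.data.frame(pairs)
  names(df) <- c("chain_a", "chain_b", "n_hbonds", "orientation", "register")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
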