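# Multi-model PDB reading and writing.
#
# Dialect: MODEL/ENDMDL delimit frames (a file with no MODEL records is one
# frame); TER or a change of chain identifier delimits chains; per-frame
# metadata travels on "REMARK 250 KEY=VALUE" lines (TIME, TEMPERATURE,
# ENERGY, REPLICA) and is written back in the same form. Only backbone atoms
# N, CA, C, O and the amide H are read; everything else is ignored. Residues
# missing any of N/CA/C/O are dropped with a warning.

#' Read peptide assemblies from a (multi-model) PDB file
#'
#' @param path path to a PDB file.
#' @param format currently only \code{"pdb_multimodel"}.
#' @return A list of \code{remd_frame} objects, in file order.
#' @seealso [write_assembly()], [reconstruct_amide_hydrogens()]
#' @export
read_assemblies <- function(path, format = "pdb_multimodel") {
  format <- match.arg(format, "pdb_multimodel")
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("cannot read PDB file: ",
                                             path, " (", conditionMessage(e), ")"))
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) == 0L) {
    blocks <- list(lines)
  } else {
    ends <- which(trimws(rec) == "ENDMDL")
    blocks <- lapply(seq_along(model_starts), function(k) {
      lo <- model_starts[k]
      hi <- ends[ends > lo][1]
      if (is.na(hi)) hi <- length(lines) + 1L
      lines[seq(lo + 1L, hi - 1L)]
    })
    # header remarks (before first MODEL) apply to every frame
    header <- lines[seq_len(model_starts[1] - 1L)]
    blocks <- lapply(blocks, function(b) c(header, b))
  }
  frames <- list()
  n_dropped_total <- 0L
  for (b in blocks) {
    parsed <- parse_pdb_block(b)
    n_dropped_total <- n_dropped_total + parsed$n_dropped
    if (is.null(parsed$assembly)) next  # frame with zero complete residues
    frames[[length(frames) + 1L]] <-
      remd_frame(parsed$assembly, time = parsed$meta$time,
                 temperature = parsed$meta$temperature,
                 energy = parsed$meta$energy,
                 replica_id = parsed$meta$replica_id)
  }
  if (n_dropped_total > 0L)
    warning(sprintf("dropped %d residue(s) missing one of N/CA/C/O",
                    n_dropped_total))
  if (length(frames) == 0L) {
    first_atom <- lines[rec %in% c("ATOM  ", "HETATM")][1]
    stop("no complete residues found in ", path,
         if (!is.na(first_atom)) paste0("; first atom record: ",
                                        substr(first_atom, 1, 30)))
  }
  frames
}

# Parse one model's worth of PDB lines into an assembly + metadata.
parse_pdb_block <- function(lines) {
  rec <- substr(lines, 1, 6)
  meta <- list(time = NULL, temperature = NULL, energy = NULL,
               replica_id = NULL)
  for (l in lines[rec == "REMARK"]) {
    if (substr(l, 8, 10) != "250") next
    kv <- regmatches(l, regexec("([A-Z_]+)=([-0-9.eE+]+)", l))[[1]]
    if (length(kv) == 3L) {
      val <- as.numeric(kv[3])
      switch(kv[2],
             TIME = meta$time <- val,
             TEMPERATURE = meta$temperature <- val,
             ENERGY = meta$energy <- val,
             REPLICA = meta$replica_id <- as.integer(val))
    }
  }
  is_atom <- rec == "ATOM  "
  is_ter <- trimws(rec) == "TER"
  keep <- is_atom | is_ter
  if (!any(is_atom)) return(list(assembly = NULL, n_dropped = 0L, meta = meta))
  sub <- lines[keep]
  ter <- trimws(substr(sub, 1, 6)) == "TER"
  atom_name <- trimws(substr(sub, 13, 16))
  res_name <- trimws(substr(sub, 18, 20))
  chain_id <- substr(sub, 22, 22)
  res_seq <- suppressWarnings(as.integer(substr(sub, 23, 26)))
  x <- as.numeric(substr(sub, 31, 38))
  y <- as.numeric(substr(sub, 39, 46))
  z <- as.numeric(substr(sub, 47, 54))
  # segment chains: a TER line or a change of chain id starts a new chain
  seg <- integer(length(sub))
  cur <- 1L
  prev_chain <- NA_character_
  for (k in seq_along(sub)) {
    if (ter[k]) { cur <- cur + 1L; prev_chain <- NA_character_; next }
    if (!is.na(prev_chain) && chain_id[k] != prev_chain) cur <- cur + 1L
    seg[k] <- cur
    prev_chain <- chain_id[k]
  }
  atom_rows <- which(!ter)
  segs <- unique(seg[atom_rows])
  chains <- list()
  chain_names <- character(0)
  n_dropped <- 0L
  for (s in segs) {
    rows <- atom_rows[seg[atom_rows] == s]
    id <- chain_id[rows[1]]
    if (!nzchar(trimws(id))) id <- as.character(length(chains) + 1L)
    while (id %in% chain_names) id <- paste0(id, "'")
    resv <- res_seq[rows]
    ures <- unique(resv)
    fields <- list(N = "N", CA = "CA", C = "C", O = "O", H = "H")
    coords <- lapply(fields, function(f) matrix(NA_real_, length(ures), 3))
    rname <- character(length(ures))
    for (ri in seq_along(ures)) {
      rr <- rows[resv == ures[ri]]
      rname[ri] <- res_name[rr[1]]
      for (f in names(fields)) {
        hit <- rr[atom_name[rr] == f][1]
        if (!is.na(hit)) coords[[f]][ri, ] <- c(x[hit], y[hit], z[hit])
      }
    }
    complete <- !is.na(coords$N[, 1]) & !is.na(coords$CA[, 1]) &
      !is.na(coords$C[, 1]) & !is.na(coords$O[, 1])
    n_dropped <- n_dropped + sum(!complete)
    if (!any(complete)) next
    chains[[length(chains) + 1L]] <- backbone_chain(
      res_name = rname[complete],
      N = coords$N[complete, , drop = FALSE],
      CA = coords$CA[complete, , drop = FALSE],
      C = coords$C[complete, , drop = FALSE],
      O = coords$O[complete, , drop = FALSE],
      H = coords$H[complete, , drop = FALSE],
      validate = FALSE)
    chain_names <- c(chain_names, id)
  }
  if (length(chains) == 0L)
    return(list(assembly = NULL, n_dropped = n_dropped, meta = meta))
  names(chains) <- chain_names
  list(assembly = assembly(chains), n_dropped = n_dropped, meta = meta)
}

#' Write an assembly, frame or frame list to a PDB file
#'
#' A single assembly or frame is written as a plain PDB (ATOM/TER/END); a
#' list of frames is written with one MODEL/ENDMDL block per frame. Frame
#' metadata is serialized as \code{REMARK 250 KEY=VALUE} lines.
#'
#' @param x an \code{assembly}, an \code{remd_frame}, or a list of frames.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_assembly <- function(x, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  if (inherits(x, "assembly")) x <- list(remd_frame(x))
  if (inherits(x, "remd_frame")) x <- list(x)
  multi <- length(x) > 1L
  serial <- 0L
  emit <- function(...) writeLines(sprintf(...), con)
  for (fi in seq_along(x)) {
    fr <- x[[fi]]
    stopifnot(inherits(fr, "remd_frame"))
    if (multi) emit("MODEL     %4d", fi)
    for (key in c("time", "temperature", "energy", "replica_id")) {
      v <- fr[[key]]
      if (!is.null(v))
        emit("REMARK 250 %s=%s",
             switch(key, time = "TIME", temperature = "TEMPERATURE",
                    energy = "ENERGY", replica_id = "REPLICA"),
             format(v, digits = 10))
    }
    asm <- fr$assembly
    for (ci in seq_along(asm$chains)) {
      ch <- asm$chains[[ci]]
      cid <- substr(names(asm$chains)[ci], 1, 1)
      for (ri in seq_len(n_residues(ch))) {
        for (an in c("N", "H", "CA", "C", "O")) {
          xyz <- ch[[an]][ri, ]
          if (any(is.na(xyz))) next
          serial <- serial + 1L
          emit("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
               serial, paste0(" ", an), ch$res_name[ri], cid, ri,
               xyz[1], xyz[2], xyz[3], 1.00, 0.00, substr(an, 1, 1))
        }
      }
      serial <- serial + 1L
      emit("TER   %5d      %3s %1s%4d",
           serial, ch$res_name[n_residues(ch)], cid, n_residues(ch))
    }
    if (multi) emit("ENDMDL")
  }
  writeLines("END", con)
  invisible(path)
}
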