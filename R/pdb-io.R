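#' Read a PDB file
#'
#' ATOM/HETATM records are parsed with \pkg{bio3d}; CONECT records are scanned
#' in addition to populate the bond graph, and MODEL blocks yield one
#' structure per model. Coordinates are in angstrom throughout.
#'
#' Alternate locations: by default only the highest-occupancy conformer of
#' each (chain, residue, atom) is kept, so downstream geometry sees one
#' position per atom; `keep_altloc = TRUE` retains all conformers.
#'
#' @param path path to a PDB file.
#' @param keep_altloc keep all alternate-location conformers (default FALSE).
#' @return A [structure3d], or a list of them when the file holds several
#'   MODEL blocks.
#' @export
read_pdb <- function(path, keep_altloc = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  bad <- grep("^(ATOM|HETATM)", lines)
  bad <- bad[nchar(lines[bad]) < 54]
  if (length(bad))
    stop(sprintf("malformed ATOM/HETATM record (missing coordinates) at line %d", bad[1]))
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  atoms <- data.frame(serial = a$eleno, name = a$elety,
                      element = ifelse(is.na(a$elesy), "", a$elesy),
                      res_name = a$resid, res_id = a$resno,
                      chain = ifelse(is.na(a$chain), "", a$chain),
                      insert = ifelse(is.na(a$insert), "", a$insert),
                      altloc = ifelse(is.na(a$alt), "", a$alt),
                      x = a$x, y = a$y, z = a$z,
                      occupancy = ifelse(is.na(a$o), 1, a$o),
                      b_factor = ifelse(is.na(a$b), 0, a$b),
                      het = a$type == "HETATM",
                      stringsAsFactors = FALSE)
  keep <- seq_len(nrow(atoms))
  if (!keep_altloc && any(nzchar(atoms$altloc))) {
    key <- paste(atoms$chain, atoms$res_id, atoms$insert, atoms$name)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
      if (length(i) == 1) return(i)
      i[which.max(atoms$occupancy[i])]
    }), use.names = FALSE)
    keep <- sort(keep)
    atoms <- atoms[keep, , drop = FALSE]
    atoms$altloc <- ""
    rownames(atoms) <- NULL
  }
  # CONECT: serial-number pairs -> indices into the kept atom table
  bonds <- parse_conect(lines, atoms$serial)
  title <- sub("^TITLE\\s+", "", grep("^TITLE", lines, value = TRUE)[1])
  if (is.na(title)) title <- ""
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod) || nmod <= 1) {
    return(structure3d(atoms, bonds, title))
  }
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
    s <- structure3d(atoms, bonds, title)
    set_coords(s, xyz)
  })
}

parse_conect <- function(lines, serials) {
  con <- grep("^CONECT", lines, value = TRUE)
  if (!length(con)) return(NULL)
  pairs <- do.call(rbind, lapply(con, function(l) {
    f <- suppressWarnings(as.integer(strsplit(trimws(substring(l, 7)), "\\s+")[[1]]))
    f <- f[!is.na(f)]
    if (length(f) < 2) return(NULL)
    cbind(f[1], f[-1])
  }))
  if (is.null(pairs)) return(NULL)
  i <- match(pairs[, 1], serials); j <- match(pairs[, 2], serials)
  ok <- !is.na(i) & !is.na(j)
  if (!any(ok)) return(NULL)
  cbind(i[ok], j[ok])
}

#' Write a structure to a PDB file
#'
#' Fixed-column ATOM/HETATM records; CONECT records are emitted for every
#' bond in the structure's bond graph (so nonstandard connectivity such as an
#' LTQ crosslink survives a round trip).
#'
#' @param s a [structure3d] or a list of them (written as MODEL blocks).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  if (inherits(s, "structure3d")) s <- list(s)
  if (any(nchar(s[[1]]$atoms$name) > 4)) stop("atom names longer than 4 characters")
  lines <- character(0)
  if (nzchar(s[[1]]$title)) lines <- c(lines, sprintf("TITLE     %s", s[[1]]$title))
  multi <- length(s) > 1
  for (m in seq_along(s)) {
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    lines <- c(lines, format_atom_records(s[[m]]))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  b <- s[[1]]$bonds
  if (nrow(b)) {
    ser <- s[[1]]$atoms$serial
    lines <- c(lines, sprintf("CONECT%5d%5d", ser[b[, 1]], ser[b[, 2]]))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

format_atom_records <- function(s) {
  a <- s$atoms
  if (any(abs(c(a$x, a$y, a$z)) >= 10000)) stop("coordinate exceeds PDB field width")
  # PDB atom-name column rule: names of <4 chars start in column 14 unless the
  # element symbol is two letters
  nm <- vapply(seq_len(nrow(a)), function(i) {
    n <- a$name[i]
    if (nchar(n) >= 4 || nchar(a$element[i]) == 2) sprintf("%-4s", n)
    else sprintf(" %-3s", n)
  }, character(1))
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(a$het, "HETATM", "ATOM"), a$serial %% 100000, nm,
          substr(paste0(a$altloc, " "), 1, 1), a$res_name,
          substr(paste0(a$chain, " "), 1, 1), a$res_id %% 10000,
          substr(paste0(a$insert, " "), 1, 1),
          a$x, a$y, a$z, a$occupancy, a$b_factor, toupper(a$element))
}

#' Read a trajectory
#'
#' @param topology a [structure3d] defining the atom layout of every frame.
#' @param path trajectory file: a multi-model PDB or an XYZ frame stack
#'   (per frame: atom count line, comment line optionally carrying
#'   `t= <ps>`, then one `element x y z` line per atom).
#' @param format `"multi-model-pdb"` or `"xyz"`.
#' @param frame_spacing_ps picoseconds per frame; if NULL, taken from the XYZ
#'   comment times when present, else 40.
#' @return A [trajectory3d].
#' @export
read_traj <- function(topology, path, format = c("multi-model-pdb", "xyz"),
                      frame_spacing_ps = NULL) {
  format <- match.arg(format)
  n <- nrow(topology$atoms)
  if (format == "multi-model-pdb") {
    models <- read_pdb(path)
    if (inherits(models, "structure3d")) models <- list(models)
    frames <- lapply(models, coords)
  } else {
    parsed <- read_xyz_frames(path)
    frames <- parsed$frames
    if (is.null(frame_spacing_ps) && length(parsed$times) >= 2)
      frame_spacing_ps <- diff(parsed$times)[1]
  }
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]) != n)
      stop(sprintf("frame %d has %d atoms but topology has %d",
                   i, nrow(frames[[i]]), n))
  }
  if (is.null(frame_spacing_ps)) frame_spacing_ps <- 40
  trajectory3d(topology, frames, frame_spacing_ps)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(0); i <- 1; k <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    k <- k + 1
    if (is.na(nat)) stop(sprintf("XYZ frame %d: bad atom-count line %d", k, i))
    comment <- lines[i + 1]
    tm <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
    if (length(tm)) times <- c(times, as.numeric(sub("t=\\s*", "", tm)))
    block <- lines[(i + 2):(i + 1 + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    if (any(lengths(toks) < 4))
      stop(sprintf("XYZ frame %d: malformed atom line", k))
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) stop(sprintf("XYZ frame %d: non-numeric coordinate", k))
    frames[[k]] <- xyz
    i <- i + 2 + nat
  }
  if (!length(frames)) stop("no frames in XYZ file")
  list(frames = frames, times = times)
}

#' Write a trajectory
#'
#' @param traj a [trajectory3d].
#' @param path output path.
#' @param format `"xyz"` (default; comment line carries the frame time in ps)
#'   or `"multi-model-pdb"`.
#' @return `path`, invisibly.
#' @export
write_traj <- function(traj, path, format = c("xyz", "multi-model-pdb")) {
  format <- match.arg(format)
  if (format == "multi-model-pdb") {
    models <- lapply(traj$frames, function(f) set_coords(traj$topology, f))
    return(write_pdb(models, path))
  }
  el <- traj$topology$atoms$element
  el[!nzchar(el)] <- "X"
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    f <- traj$frames[[k]]
    writeLines(c(sprintf("%d", nrow(f)),
                 sprintf("frame %d t= %g", k, (k - 1) * traj$frame_spacing_ps),
                 sprintf("%-2s %12.6f %12.6f %12.6f", el, f[, 1], f[, 2], f[, 3])),
               con)
  }
  invisible(path)
}
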