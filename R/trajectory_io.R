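# Trajectory readers and the XYZ writer.
#
# XYZ dialect: standard XYZ with the box on the comment line as three
# whitespace-separated floats in Angstrom, optionally followed by
# "t=<time/ps>".  GRO files are in nm and converted to Angstrom on read;
# PDB boxes come from CRYST1.  A missing box is an error: analyses in a
# periodic box cannot fall back to a default.

#' Read a trajectory
#'
#' @param path Path to the coordinate file.
#' @param format One of `"auto"` (by file extension), `"xyz"`, `"gro"`,
#'   `"pdb"`.
#' @param topology A [topology()]; the per-frame atom count must match.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "gro", "pdb"),
                            topology) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("xyz", "gro", "pdb"))
      stop("cannot infer format from extension '", ext, "'")
    format <- ext
  }
  lines <- readLines(path)
  frames <- switch(format,
                   xyz = .read_xyz(lines, topology),
                   gro = .read_gro(lines, topology),
                   pdb = .read_pdb(lines, topology))
  trajectory(frames)
}

.check_count <- function(n, topology, frame_idx) {
  if (n != n_atoms(topology))
    stop("frame ", frame_idx, ": atom count ", n,
         " does not match topology (", n_atoms(topology), " atoms)")
}

.read_xyz <- function(lines, topology) {
  frames <- list()
  i <- 1L; fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed XYZ atom-count line ", i)
    .check_count(nat, topology, fidx)
    comment <- lines[i + 1L]
    toks <- strsplit(trimws(comment), "\\s+")[[1]]
    box <- suppressWarnings(as.numeric(toks[1:3]))
    if (length(toks) < 3 || anyNA(box))
      stop("frame ", fidx, ": XYZ comment line must carry the box as ",
           "three floats (Angstrom); none found")
    tm <- grep("^t=", toks, value = TRUE)
    time <- if (length(tm)) as.numeric(sub("^t=", "", tm[1])) else fidx
    body <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(body), "\\s+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- frame(xyz, box, time)
    i <- i + 2L + nat
    fidx <- fidx + 1L
  }
  if (!length(frames)) stop("no frames found in XYZ file")
  frames
}

.read_gro <- function(lines, topology) {
  frames <- list()
  i <- 1L; fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else fidx
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop("malformed GRO atom-count line ", i + 1L)
    .check_count(nat, topology, fidx)
    body <- lines[(i + 2L):(i + 1L + nat)]
    # fixed columns: positions in nm at 21-28, 29-36, 37-44
    x <- as.numeric(substr(body, 21, 28))
    y <- as.numeric(substr(body, 29, 36))
    z <- as.numeric(substr(body, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("frame ", fidx, ": malformed GRO coordinate records")
    boxline <- strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]]
    bv <- suppressWarnings(as.numeric(boxline))
    if (length(bv) < 3 || anyNA(bv[1:3]))
      stop("frame ", fidx, ": missing GRO box line")
    if (length(bv) > 3 && any(abs(bv[-(1:3)]) > 1e-9))
      stop("triclinic GRO boxes are not supported")
    frames[[length(frames) + 1L]] <-
      frame(cbind(x, y, z) * 10, bv[1:3] * 10, time)  # nm -> Angstrom
    i <- i + 3L + nat
    fidx <- fidx + 1L
  }
  if (!length(frames)) stop("no frames found in GRO file")
  frames
}

.read_pdb <- function(lines, topology) {
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cryst))
    stop("PDB file has no CRYST1 record; a periodic box is required")
  a <- as.numeric(substr(cryst[1], 7, 15))
  b <- as.numeric(substr(cryst[1], 16, 24))
  c_ <- as.numeric(substr(cryst[1], 25, 33))
  ang <- c(as.numeric(substr(cryst[1], 34, 40)),
           as.numeric(substr(cryst[1], 41, 47)),
           as.numeric(substr(cryst[1], 48, 54)))
  if (any(abs(ang - 90) > 1e-3))
    stop("triclinic PDB boxes are not supported (angles must be 90 degrees)")
  box <- c(a, b, c_)

  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  frames <- list()
  if (length(model_starts)) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records")
    for (k in seq_along(model_starts)) {
      sel <- which(is_atom & seq_along(lines) > model_starts[k] &
                     seq_along(lines) < ends[k])
      frames[[k]] <- .pdb_frame(lines[sel], box, k - 1, topology)
    }
  } else {
    frames[[1]] <- .pdb_frame(lines[is_atom], box, 0, topology)
  }
  if (!length(frames)) stop("no coordinates found in PDB file")
  frames
}

.pdb_frame <- function(atom_lines, box, fidx, topology) {
  .check_count(length(atom_lines), topology, fidx)
  x <- as.numeric(substr(atom_lines, 31, 38))
  y <- as.numeric(substr(atom_lines, 39, 46))
  z <- as.numeric(substr(atom_lines, 47, 54))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("frame ", fidx, ": malformed PDB coordinate records")
  frame(cbind(x, y, z), box, fidx)
}

#' Write a trajectory in the package's XYZ dialect
#'
#' The comment line of every frame carries the box edges (Angstrom) and the
#' frame time as `t=<ps>`, so files round-trip through [read_trajectory()].
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param topology A [topology()] supplying atom names.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, topology) {
  con <- file(path, "w")
  on.exit(close(con))
  names <- topology$atoms$name
  for (fr in traj$frames) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(sprintf("%.6f %.6f %.6f t=%.6f",
                       fr$box[1], fr$box[2], fr$box[3], fr$time), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", names,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}
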