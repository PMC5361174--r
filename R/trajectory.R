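#' Single trajectory frame
#'
#' @param coords Numeric matrix (n_atoms x 3) of coordinates in Angstrom.
#' @param box A `simulation_box` (or length-3 numeric).
#' @param time Frame time in ps.
#' @return A `frame` object.
#' @export
frame <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  storage.mode(coords) <- "double"
  structure(list(time = as.numeric(time), coords = coords, box = as_box(box)),
            class = "frame")
}

#' Time-ordered trajectory
#'
#' @param frames List of [frame()] objects with strictly increasing,
#'   uniformly spaced times (tolerance 1e-6 ps).
#' @param frame_spacing Frame spacing in ps; derived from the times when
#'   omitted (a single-frame trajectory defaults to 1 ps).
#' @return A `trajectory` object.
#' @export
trajectory <- function(frames, frame_spacing = NULL) {
  if (!length(frames)) stop("empty trajectory")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("frame times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6)
      stop("frame times must be uniformly spaced (tolerance 1e-6 ps)")
    sp <- mean(dt)
  } else sp <- 1
  if (!is.null(frame_spacing)) sp <- frame_spacing
  structure(list(frames = frames, frame_spacing = sp), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat("trajectory:", length(x$frames), "frames x", nrow(f1$coords),
      "atoms, spacing", x$frame_spacing, "ps, box",
      paste(signif(as.numeric(f1$box), 6), collapse = " x "), "A\n")
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Wrap a frame into the primary box
#'
#' Without a topology every atom is wrapped independently into
#' `[0, edge)` per axis.  With a topology, molecules are wrapped rigidly:
#' each atom is first rebuilt next to the molecule's first atom by the
#' minimum-image convention (so internal geometry is preserved), then the
#' whole molecule is shifted so its reference atom lies in the primary box.
#'
#' @param fr A [frame()].
#' @param topology Optional [topology()] for rigid per-molecule wrapping.
#' @return A wrapped `frame`.
#' @export
wrap_frame <- function(fr, topology = NULL) {
  box <- as.numeric(fr$box)
  x <- fr$coords
  if (is.null(topology)) {
    x <- x - sweep(floor(sweep(x, 2, box, "/")), 2, box, "*")
  } else {
    mols <- topology$molecules
    for (i in seq_len(nrow(mols))) {
      idx <- seq.int(mols$first[i], mols$last[i])
      ref <- x[idx[1], ]
      rel <- min_image_disp(x[idx, , drop = FALSE], ref, box)
      shift <- ref - box * floor(ref / box)
      x[idx, ] <- sweep(rel, 2, shift, "+")
    }
  }
  frame(x, fr$box, fr$time)
}

#' Center of mass of a molecule
#'
#' The molecule is first unwrapped by the minimum-image convention relative
#' to its first atom, then the mass-weighted mean position is taken and
#' wrapped back into the primary box.
#'
#' @param fr A [frame()].
#' @param topology A [topology()].
#' @param molecule_id Molecule id.
#' @return Numeric 3-vector (Angstrom), inside `[0, edge)` per axis.
#' @export
center_of_mass <- function(fr, topology, molecule_id) {
  idx <- mol_atoms(topology, molecule_id)
  m <- topology$atoms$mass[idx]
  if (sum(m) <= 0) stop("total mass of molecule ", molecule_id, " is zero")
  box <- as.numeric(fr$box)
  ref <- fr$coords[idx[1], ]
  rel <- min_image_disp(fr$coords[idx, , drop = FALSE], ref, box)
  com <- ref + colSums(rel * m) / sum(m)
  com - box * floor(com / box)
}

#' Centers of mass of all molecules
#'
#' @inheritParams center_of_mass
#' @return Matrix (n_molecules x 3) of wrapped centers of mass, rows in
#'   molecule order.
#' @export
molecule_coms <- function(fr, topology) {
  mols <- topology$molecules
  box <- as.numeric(fr$box)
  x <- fr$coords
  m <- topology$atoms$mass
  out <- matrix(0, nrow(mols), 3)
  for (i in seq_len(nrow(mols))) {
    idx <- seq.int(mols$first[i], mols$last[i])
    ref <- x[idx[1], ]
    rel <- min_image_disp(x[idx, , drop = FALSE], ref, box)
    w <- m[idx]
    com <- ref + colSums(rel * w) / sum(w)
    out[i, ] <- com - box * floor(com / box)
  }
  rownames(out) <- mols$molecule_id
  out
}
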