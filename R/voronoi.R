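# Periodic Voronoi tessellation, molecular cells, shell assignment and the
# time-averaged shell census.

#' Voronoi tessellation of a frame into molecular cells
#'
#' Atomic Voronoi cells are computed under periodic boundary conditions
#' (full 26-image ghost replication, orthorhombic box) and merged into
#' molecular cells: the molecular volume is the sum of the atomic cell
#' volumes and two molecules are neighbors when any of their atoms share a
#' Voronoi face.  Intra-molecular faces (including faces to a molecule's
#' own periodic image) are discarded.
#'
#' Degenerate site sets (exact lattices) that break the space partition are
#' retried with a deterministic jitter of 1e-8 Angstrom drawn from a fixed
#' seed; the magnitude is far below any physical length scale.
#'
#' @param fr A [frame()]; it is wrapped atom-wise internally.
#' @param topology A [topology()] with at least 2 molecules.
#' @param min_face_area Faces with area (Angstrom^2) at or below this
#'   threshold are dropped from the neighbor graph (volumes are not
#'   affected).  The tiny default suppresses numerically spurious contacts
#'   at degenerate tangencies, far below any physical face area.
#' @param sites `"atoms"` (default) uses every atom as a tessellation site;
#'   `"heavy"` drops hydrogens (elements H/D) for sensitivity checks.
#' @return A `voronoi_cells` object: per-molecule `volumes` (Angstrom^3),
#'   `neighbors` (adjacency list of molecule ids), `face_areas` (list of
#'   named numeric vectors, Angstrom^2), and the box volume.
#' @export
tessellate_frame <- function(fr, topology, min_face_area = 1e-6,
                             sites = c("atoms", "heavy")) {
  sites <- match.arg(sites)
  if (n_molecules(topology) < 2) stop("tessellation needs at least 2 molecules")
  fr <- wrap_frame(fr)
  keep <- seq_len(n_atoms(topology))
  if (sites == "heavy") {
    keep <- which(!topology$atoms$element %in% c("H", "D"))
    if (!all(topology$molecules$molecule_id %in%
             unique(topology$atoms$molecule_id[keep])))
      stop("heavy-atom tessellation would drop a hydrogen-only molecule")
  }
  coords <- fr$coords[keep, , drop = FALSE]
  mol <- topology$atoms$molecule_id[keep]
  vbox <- box_volume(fr$box)

  res <- NULL
  for (attempt in 0:3) {
    res <- voronoi_cells_cpp(coords, as.numeric(fr$box), mol,
                             jitter = if (attempt == 0) 0 else 1e-8 * attempt,
                             jitter_seed = 190537L + attempt)
    rel_err <- abs(sum(res$site_volumes) - vbox) / vbox
    if (rel_err < 1e-9 && all(res$mol_volumes > 0)) break
    if (attempt == 3)
      stop("degenerate site set: tessellation failed after 3 jitter retries ",
           "(partition error ", signif(rel_err, 3), ")")
  }

  nmol <- n_molecules(topology)
  # symmetrize directed face areas; drop areas at or below the threshold
  key <- paste(pmin(res$edge_i, res$edge_j), pmax(res$edge_i, res$edge_j))
  area2 <- tapply(res$edge_area, key, sum) / 2  # mean of the two directions
  pk <- strsplit(names(area2), " ")
  ei <- vapply(pk, function(p) as.integer(p[1]), integer(1))
  ej <- vapply(pk, function(p) as.integer(p[2]), integer(1))
  keep_e <- area2 > min_face_area
  ei <- ei[keep_e]; ej <- ej[keep_e]; area2 <- area2[keep_e]

  neighbors <- vector("list", nmol)
  face_areas <- vector("list", nmol)
  ids <- topology$molecules$molecule_id
  for (k in seq_along(ei)) {
    a <- ei[k]; b <- ej[k]; ar <- unname(area2[k])
    neighbors[[a]] <- c(neighbors[[a]], b)
    neighbors[[b]] <- c(neighbors[[b]], a)
    face_areas[[a]] <- c(face_areas[[a]], setNames(ar, b))
    face_areas[[b]] <- c(face_areas[[b]], setNames(ar, a))
  }
  # raw directed areas kept for symmetry checks
  structure(list(volumes = setNames(as.numeric(res$mol_volumes), ids),
                 neighbors = setNames(neighbors, ids),
                 face_areas = setNames(face_areas, ids),
                 edges = data.frame(i = ei, j = ej, area = as.numeric(area2)),
                 directed = data.frame(i = res$edge_i, j = res$edge_j,
                                       area = res$edge_area),
                 box_volume = vbox),
            class = "voronoi_cells")
}

#' @export
print.voronoi_cells <- function(x, ...) {
  cat("voronoi_cells:", length(x$volumes), "molecular cells, total volume",
      signif(sum(x$volumes), 8), "of box", signif(x$box_volume, 8), "A^3\n")
  invisible(x)
}

#' Assign molecules to solvation shells
#'
#' Shell index = breadth-first graph distance from the solute over the
#' molecular face-sharing neighbor graph: the solute is shell 0, its direct
#' Voronoi neighbors are the first solvation shell, neighbors of the first
#' shell are the second, and so on.
#'
#' @param cells A `voronoi_cells` object from [tessellate_frame()].
#' @param solute_id Molecule id of the solute.
#' @return Named integer vector: shell index per molecule (solute = 0).
#' @export
assign_shells <- function(cells, solute_id) {
  ids <- as.integer(names(cells$volumes))
  if (!solute_id %in% ids) stop("solute_id ", solute_id, " not in tessellation")
  shell <- setNames(rep(NA_integer_, length(ids)), ids)
  shell[as.character(solute_id)] <- 0L
  queue <- solute_id
  while (length(queue)) {
    nxt <- integer(0)
    for (m in queue) {
      for (nb in cells$neighbors[[as.character(m)]]) {
        nb_key <- as.character(nb)
        if (is.na(shell[nb_key])) {
          shell[nb_key] <- shell[as.character(m)] + 1L
          nxt <- c(nxt, nb)
        }
      }
    }
    queue <- nxt
  }
  if (anyNA(shell))
    stop("neighbor graph is disconnected: molecules ",
         paste(names(shell)[is.na(shell)], collapse = ", "),
         " unreachable from the solute")
  shell
}

#' Shell map of a whole trajectory
#'
#' Tessellates every frame and assigns shells, returning the per-frame
#' shell index and molecular cell volume of every molecule.  This is the
#' single tessellation pass shared by all downstream analyses.
#'
#' @param traj A [trajectory()].
#' @param topology A [topology()].
#' @inheritParams tessellate_frame
#' @return A `shell_map`: integer matrix `shells` (frames x molecules),
#'   numeric matrix `volumes` (frames x molecules, Angstrom^3), species
#'   vector, frame spacing and box volume.
#' @export
map_shells <- function(traj, topology, min_face_area = 1e-6,
                       sites = c("atoms", "heavy")) {
  sites <- match.arg(sites)
  nf <- n_frames(traj)
  nm <- n_molecules(topology)
  shells <- matrix(NA_integer_, nf, nm)
  vols <- matrix(NA_real_, nf, nm)
  colnames(shells) <- colnames(vols) <- topology$molecules$molecule_id
  vbox <- numeric(nf)
  for (f in seq_len(nf)) {
    cells <- tessellate_frame(traj$frames[[f]], topology,
                              min_face_area = min_face_area, sites = sites)
    shells[f, ] <- assign_shells(cells, topology$solute_id)
    vols[f, ] <- cells$volumes
    vbox[f] <- cells$box_volume
  }
  structure(list(shells = shells, volumes = vols,
                 species = species_of(topology),
                 solute_id = topology$solute_id,
                 frame_spacing = traj$frame_spacing,
                 box_volume = vbox),
            class = "shell_map")
}

#' @export
print.shell_map <- function(x, ...) {
  cat("shell_map:", nrow(x$shells), "frames x", ncol(x$shells),
      "molecules; mean first-shell size",
      signif(mean(rowSums(x$shells == 1L)), 4), "\n")
  invisible(x)
}

#' Time-averaged shell census
#'
#' Per-shell, per-species time averages of molecule counts and total
#' Voronoi cell volumes.  Shells beyond `max_shell` are pooled into a
#' `"bulk"` remainder bucket.
#'
#' @param x A `shell_map` from [map_shells()], or a [trajectory()] (in
#'   which case `topology` is required and the shell map is computed).
#' @param topology A [topology()] when `x` is a trajectory.
#' @param max_shell Largest shell index reported individually (>= 1).
#' @param ... Passed on to [map_shells()] when `x` is a trajectory.
#' @return A `shell_census`: data frame with columns `shell` (factor,
#'   `"0"`..`"max_shell"`, `"bulk"`), `species`, `cn` (time-averaged
#'   count), `volume` (time-averaged total cell volume of the shell,
#'   Angstrom^3, repeated across species).  Per-frame arrays are kept as
#'   attributes for estimator variants.
#' @export
shell_census <- function(x, topology = NULL, max_shell = 3, ...) {
  if (inherits(x, "trajectory")) {
    if (is.null(topology)) stop("topology required when passing a trajectory")
    x <- map_shells(x, topology, ...)
  }
  if (!inherits(x, "shell_map")) stop("x must be a shell_map or trajectory")
  max_shell <- as.integer(max_shell)
  if (max_shell < 1) stop("max_shell must be >= 1")

  sh <- x$shells
  capped <- pmin(sh, max_shell + 1L)      # max_shell+1 = bulk bucket
  shell_levels <- c(as.character(0:max_shell), "bulk")
  species_levels <- sort(unique(x$species))
  nf <- nrow(sh)

  counts <- array(0, c(nf, length(shell_levels), length(species_levels)),
                  dimnames = list(NULL, shell_levels, species_levels))
  volumes <- matrix(0, nf, length(shell_levels),
                    dimnames = list(NULL, shell_levels))
  spf <- factor(x$species, levels = species_levels)
  for (f in seq_len(nf)) {
    shf <- factor(capped[f, ], levels = 0:(max_shell + 1L),
                  labels = shell_levels)
    counts[f, , ] <- table(shf, spf)
    volumes[f, ] <- tapply(x$volumes[f, ], shf, sum, default = 0)
  }

  df <- expand.grid(shell = shell_levels, species = species_levels,
                    stringsAsFactors = FALSE)
  df$cn <- mapply(function(s, sp) mean(counts[, s, sp]),
                  df$shell, df$species)
  df$volume <- colMeans(volumes)[df$shell]
  structure(df, class = c("shell_census", "data.frame"),
            counts = counts, volumes = volumes,
            box_volume = mean(x$box_volume),
            frame_spacing = x$frame_spacing,
            species_totals = table(spf),
            solute_species = x$species[match(x$solute_id,
                                             colnames(x$shells))])
}

#' @export
print.shell_census <- function(x, ...) {
  cat("shell_census (", nrow(attr(x, "counts")), " frames):\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Export the neighbor graph of a tessellated frame
#'
#' @param cells A `voronoi_cells`.
#' @param path Output path; tab-separated columns `mol_i`, `mol_j`,
#'   `face_area`.
#' @param frame_index Frame index written into the first column.
#' @return `path`, invisibly.
#' @export
export_neighbor_graph <- function(cells, path, frame_index = 0) {
  df <- data.frame(frame = frame_index, mol_i = cells$edges$i,
                   mol_j = cells$edges$j, face_area = cells$edges$area)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
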