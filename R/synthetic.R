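# Synthetic configurations with analytically known ground truth.  Every
# generator returns a list(trajectory, topology, truth) whose truth entry
# records the imposed construction (densities, enrichment factor, exchange
# rate, lattice constants) so the analyses can be validated without any
# simulation data.  All randomness is driven by the `seed` argument;
# the same seed reproduces the same trajectory bit for bit.

.single_atom_topology <- function(species_per_mol, solute_mol = 1L,
                                  element = "Ar", mass = 18) {
  n <- length(species_per_mol)
  atoms <- data.frame(name = paste0("X", seq_len(n)), element = element,
                      mass = mass, charge = 0, epsilon = 0, sigma = 0,
                      molecule_id = seq_len(n), species = species_per_mol,
                      is_donor_h = FALSE, is_acceptor = FALSE,
                      stringsAsFactors = FALSE)
  topology(atoms, solute = solute_mol)
}

.species_assign <- function(n, fractions) {
  # deterministic counts (largest remainder), order fixed
  cnt <- floor(n * fractions)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(n * fractions - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  rep(names(fractions), cnt)
}

#' Ideal-gas solvent around a fixed solute
#'
#' Uniform i.i.d. single-atom solvent molecules re-drawn every frame
#' around a single-atom solute fixed at the box center: a homogeneous,
#' structureless reference system (g(r) = 1, all shell free energies 0).
#'
#' @param n_molecules Total molecules including the solute.
#' @param box_edge Cubic box edge in Angstrom.
#' @param species_fractions Named fractions of the solvent species
#'   (must sum to 1).
#' @param n_frames Number of frames.
#' @param frame_spacing Frame spacing in ps.
#' @param seed Integer seed; fully determines the output.
#' @return List with `trajectory`, `topology`, `truth` (species bulk
#'   densities in molecules/Angstrom^3).
#' @export
gen_ideal_gas <- function(n_molecules = 500, box_edge = 25,
                          species_fractions = c(A = 0.5, B = 0.5),
                          n_frames = 100, frame_spacing = 1, seed = 1) {
  if (n_molecules < 2) stop("need at least 2 molecules")
  if (abs(sum(species_fractions) - 1) > 1e-9)
    stop("species fractions must sum to 1")
  nsolv <- n_molecules - 1L
  species <- c("solute", .species_assign(nsolv, species_fractions))
  top <- .single_atom_topology(species)
  box <- simulation_box(box_edge)
  rng <- .new_rng(seed)
  frames <- lapply(seq_len(n_frames) - 1L, function(f) {
    xyz <- rbind(rep(box_edge / 2, 3),
                 matrix(rng(3 * nsolv) * box_edge, ncol = 3))
    frame(xyz, box, f * frame_spacing)
  })
  dens <- table(factor(species[-1],
                       levels = names(species_fractions))) / box_edge^3
  list(trajectory = trajectory(frames), topology = top,
       truth = list(c_bulk = setNames(as.numeric(dens), names(dens))))
}

#' Perfect lattice with the central site as solute
#'
#' Simple-cubic or face-centered-cubic lattice of single-atom molecules
#' filling the box periodically.  Exact Voronoi geometry is known: an SC
#' cell is a cube of volume a^3 with 6 face neighbors (18 second-shell
#' sites), an FCC cell is a rhombic dodecahedron with 12 face neighbors.
#'
#' @param kind `"sc"` or `"fcc"`.
#' @param n_cells Unit cells per box edge.
#' @param a Lattice constant in Angstrom.
#' @return List with single-frame `trajectory`, `topology`, `truth`
#'   (lattice constant, expected shell sizes).
#' @export
gen_lattice <- function(kind = c("sc", "fcc"), n_cells = 5, a = 4) {
  kind <- match.arg(kind)
  L <- n_cells * a
  base <- if (kind == "sc") matrix(0, 1, 3) else
    matrix(c(0, 0, 0, 0, .5, .5, .5, 0, .5, .5, .5, 0), ncol = 3,
           byrow = TRUE)
  cells <- as.matrix(expand.grid(0:(n_cells - 1), 0:(n_cells - 1),
                                 0:(n_cells - 1)))
  sites <- do.call(rbind, lapply(seq_len(nrow(base)), function(b)
    sweep(cells, 2, base[b, ], "+"))) * a
  # solute: site nearest the box center
  ctr <- rep(L / 2, 3)
  d <- min_image_dist_vec(sites, ctr, rep(L, 3))
  sol <- which.min(d)
  ord <- c(sol, setdiff(seq_len(nrow(sites)), sol))
  sites <- sites[ord, , drop = FALSE]
  species <- c("solute", rep("lattice", nrow(sites) - 1))
  top <- .single_atom_topology(species)
  truth <- list(a = a, kind = kind,
                shell1 = if (kind == "sc") 6L else 12L,
                shell2 = if (kind == "sc") 18L else NA_integer_,
                cell_volume = if (kind == "sc") a^3 else a^3 / 4)
  list(trajectory = trajectory(list(frame(sites, rep(L, 3), 0))),
       topology = top, truth = truth)
}

#' Surface-enriched binary solvent
#'
#' Species A is placed by rejection sampling with acceptance proportional
#' to f inside a sphere of radius `well_radius` around the fixed central
#' solute and 1 elsewhere, species B uniformly.  The construction fixes
#' the concentration ratio analytically: inside the well the A density is
#' f times its reservoir density, so the first-shell solvation free
#' energy must recover -RT ln f while species B stays at 0.
#'
#' @param box_edge Cubic box edge (Angstrom).
#' @param rho_a,rho_b Reservoir number densities (molecules/Angstrom^3)
#'   of the enriched species A and the unbiased species B.
#' @param f Enrichment factor (> 0; `f = 1` reduces to an ideal gas).
#' @param well_radius Radius of the enriched sphere (Angstrom); choose it
#'   to cover the first Voronoi shell.
#' @inheritParams gen_ideal_gas
#' @return List with `trajectory`, `topology`, `truth` (`f`,
#'   `well_radius`, reservoir densities `c_bulk`, expected first-shell
#'   free energies at temperature T via -RT ln f).
#' @export
gen_enriched_shell <- function(box_edge = 36, rho_a = 0.005, rho_b = 0.005,
                               f = 3, well_radius = 10, n_frames = 256,
                               frame_spacing = 1, seed = 1) {
  if (f <= 0) stop("enrichment factor must be positive")
  if (well_radius >= box_edge / 2) stop("well must fit in the half-box")
  V <- box_edge^3
  vw <- 4 * pi / 3 * well_radius^3
  n_a <- round(rho_a * (V + (f - 1) * vw))
  n_b <- round(rho_b * V)
  species <- c("solute", rep("A", n_a), rep("B", n_b))
  top <- .single_atom_topology(species)
  ctr <- rep(box_edge / 2, 3)
  rng <- .new_rng(seed)
  box <- simulation_box(box_edge)

  draw_a <- function() {
    # rejection: acceptance f/f = 1 inside the well, 1/f outside
    pts <- matrix(NA_real_, n_a, 3)
    got <- 0L
    while (got < n_a) {
      m <- max(64L, 2L * (n_a - got))
      p <- matrix(rng(3 * m) * box_edge, ncol = 3)
      r <- min_image_dist_vec(p, ctr, rep(box_edge, 3))
      u <- rng(m)
      keep <- which(ifelse(r < well_radius, TRUE, u < 1 / f))
      keep <- keep[seq_len(min(length(keep), n_a - got))]
      if (length(keep)) {
        pts[(got + 1):(got + length(keep)), ] <- p[keep, , drop = FALSE]
        got <- got + length(keep)
      }
    }
    pts
  }
  frames <- lapply(seq_len(n_frames) - 1L, function(fi) {
    xyz <- rbind(ctr, draw_a(),
                 matrix(rng(3 * n_b) * box_edge, ncol = 3))
    frame(xyz, box, fi * frame_spacing)
  })
  c_bulk <- c(A = n_a / (V + (f - 1) * vw), B = n_b / V)
  list(trajectory = trajectory(frames), topology = top,
       truth = list(f = f, well_radius = well_radius, c_bulk = c_bulk,
                    delta_A_shell1 = function(T) {
                      c(A = -.r_gas * T * log(f), B = 0)
                    }))
}

#' Two-state shell-exchange dynamics
#'
#' Independent two-state Markov chains switch each solvent molecule
#' between an inner spherical band around the fixed solute (by
#' construction the first Voronoi shell) and a distant reservoir;
#' positions are re-drawn uniformly within the current zone every frame.
#' The indicator autocorrelation has the closed form
#' p + (1 - p) exp(-k t) with stationary occupancy p and relaxation rate
#' k, so a bi-exponential fit must recover a mean residence time of 1/k.
#'
#' @param n_molecules Solvent molecules (plus one solute).
#' @param box_edge Cubic box edge (Angstrom).
#' @param p_inner Stationary occupancy of the inner zone.
#' @param rate Relaxation rate k in 1/ps.
#' @param r_inner Two radii (Angstrom): the inner zone is the spherical
#'   band between them.
#' @param r_outer_min Minimum radius of the reservoir zone (Angstrom);
#'   the gap between the zones keeps the Voronoi first shell equal to the
#'   inner zone membership up to rare line-of-sight leaks.
#' @inheritParams gen_ideal_gas
#' @return List with `trajectory`, `topology`, `truth` (`rate`, `p`,
#'   `mean_tau = 1/rate`, per-frame zone membership matrix).
#' @export
gen_exchange_dynamics <- function(n_molecules = 120, box_edge = 30,
                                  p_inner = 1 / 6, rate = 0.1,
                                  r_inner = c(3.5, 5.5), r_outer_min = 12,
                                  n_frames = 8000, frame_spacing = 0.2,
                                  seed = 1) {
  if (rate < 0) stop("rate must be >= 0")
  if (r_outer_min >= box_edge / 2) stop("reservoir must fit in the half-box")
  species <- c("solute", rep("W", n_molecules))
  top <- .single_atom_topology(species)
  ctr <- rep(box_edge / 2, 3)
  rng <- .new_rng(seed)
  box <- simulation_box(box_edge)

  dt <- frame_spacing
  decay <- exp(-rate * dt)
  p_out_in <- p_inner * (1 - decay)        # P(out -> in) per step
  p_in_out <- (1 - p_inner) * (1 - decay)  # P(in -> out) per step

  sample_inner <- function(n) {
    r3 <- r_inner[1]^3 + rng(n) * (r_inner[2]^3 - r_inner[1]^3)
    r <- r3^(1 / 3)
    z <- 2 * rng(n) - 1
    phi <- 2 * pi * rng(n)
    s <- sqrt(1 - z^2)
    sweep(cbind(r * s * cos(phi), r * s * sin(phi), r * z), 2, ctr, "+")
  }
  sample_outer <- function(n) {
    out <- matrix(NA_real_, n, 3)
    got <- 0L
    while (got < n) {
      m <- max(64L, 2L * (n - got))
      p <- matrix(rng(3 * m) * box_edge, ncol = 3)
      keep <- which(min_image_dist_vec(p, ctr, rep(box_edge, 3)) >
                      r_outer_min)
      keep <- keep[seq_len(min(length(keep), n - got))]
      if (length(keep)) {
        out[(got + 1):(got + length(keep)), ] <- p[keep, , drop = FALSE]
        got <- got + length(keep)
      }
    }
    out
  }

  state <- rng(n_molecules) < p_inner
  membership <- matrix(FALSE, n_frames, n_molecules)
  frames <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    if (fi > 1) {
      u <- rng(n_molecules)
      flip <- ifelse(state, u < p_in_out, u < p_out_in)
      state <- xor(state, flip)
    }
    membership[fi, ] <- state
    xyz <- matrix(NA_real_, n_molecules + 1, 3)
    xyz[1, ] <- ctr
    if (any(state)) xyz[1 + which(state), ] <- sample_inner(sum(state))
    if (any(!state)) xyz[1 + which(!state), ] <- sample_outer(sum(!state))
    frames[[fi]] <- frame(xyz, box, (fi - 1) * frame_spacing)
  }
  list(trajectory = trajectory(frames), topology = top,
       truth = list(rate = rate, p = p_inner,
                    mean_tau = if (rate > 0) 1 / rate else Inf,
                    membership = membership))
}

#' Planar solute in a structured solvent
#'
#' A rigid flat plate of atoms (grid spacing 1.4 Angstrom) as the solute,
#' coated by a contact layer of solvent at a fixed nearest-atom distance
#' band and surrounded by a distant uniform reservoir.  Because the plate
#' is strongly anisotropic, the spherical first-minimum coordination
#' number and the Voronoi first-shell coordination number must disagree,
#' and the first-shell contribution to g(r) extends beyond the first
#' spherical minimum.
#'
#' @param nx,ny Plate grid dimensions.
#' @param spacing Plate grid spacing (Angstrom).
#' @param n_layer Contact-layer molecules per frame.
#' @param layer_band Nearest-plate-atom distance band of the contact
#'   layer (Angstrom).
#' @param n_bulk Reservoir molecules per frame.
#' @param bulk_min Minimum nearest-plate-atom distance of the reservoir.
#' @inheritParams gen_ideal_gas
#' @return List with `trajectory`, `topology`, `truth`.
#' @export
gen_planar_solute <- function(nx = 4, ny = 4, spacing = 1.4, box_edge = 36,
                              n_layer = 24, layer_band = c(2.5, 3.5),
                              n_bulk = 150, bulk_min = 6.5, n_frames = 80,
                              frame_spacing = 1, seed = 1) {
  ctr <- rep(box_edge / 2, 3)
  gx <- (seq_len(nx) - (nx + 1) / 2) * spacing
  gy <- (seq_len(ny) - (ny + 1) / 2) * spacing
  plate <- as.matrix(expand.grid(x = gx, y = gy, z = 0))
  plate <- sweep(plate, 2, ctr, "+")
  n_plate <- nrow(plate)

  atoms <- data.frame(
    name = c(paste0("C", seq_len(n_plate)), paste0("X", seq_len(n_layer + n_bulk))),
    element = c(rep("C", n_plate), rep("Ar", n_layer + n_bulk)),
    mass = c(rep(12.011, n_plate), rep(18, n_layer + n_bulk)),
    charge = 0, epsilon = 0, sigma = 0,
    molecule_id = c(rep(1L, n_plate), 1L + seq_len(n_layer + n_bulk)),
    species = c(rep("solute", n_plate),
                rep("W", n_layer + n_bulk)),
    is_donor_h = FALSE, is_acceptor = FALSE, stringsAsFactors = FALSE)
  top <- topology(atoms, solute = 1L)

  rng <- .new_rng(seed)
  box <- simulation_box(box_edge)
  nearest_plate <- function(p) {
    d <- rep(Inf, nrow(p))
    for (a in seq_len(n_plate))
      d <- pmin(d, min_image_dist_vec(p, plate[a, ], rep(box_edge, 3)))
    d
  }
  sample_zone <- function(n, lo, hi) {
    out <- matrix(NA_real_, n, 3)
    got <- 0L
    while (got < n) {
      m <- max(128L, 4L * (n - got))
      p <- matrix(rng(3 * m) * box_edge, ncol = 3)
      d <- nearest_plate(p)
      keep <- which(d >= lo & d < hi)
      keep <- keep[seq_len(min(length(keep), n - got))]
      if (length(keep)) {
        out[(got + 1):(got + length(keep)), ] <- p[keep, , drop = FALSE]
        got <- got + length(keep)
      }
    }
    out
  }
  frames <- lapply(seq_len(n_frames) - 1L, function(fi) {
    xyz <- rbind(plate,
                 sample_zone(n_layer, layer_band[1], layer_band[2]),
                 sample_zone(n_bulk, bulk_min, Inf))
    frame(xyz, box, fi * frame_spacing)
  })
  list(trajectory = trajectory(frames), topology = top,
       truth = list(n_layer = n_layer, layer_band = layer_band,
                    bulk_min = bulk_min,
                    aspect_ratio = max(nx, ny) * spacing / spacing))
}

# Counter-free deterministic uniform stream: a closure over R's RNG with
# an isolated state, so generators never disturb (or depend on) the
# caller's RNG.
.new_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    x <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    x
  }
}
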