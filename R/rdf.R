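# Radial distribution functions around the solute (center-of-mass distance
# r or nearest-solute-atom distance s), their Voronoi-shell decomposition,
# cumulative/excess coordination numbers and Kirkwood-Buff integrals.

#' Construct a binned distribution curve
#'
#' Low-level constructor, mostly useful for building synthetic curves in
#' closed-form checks; the analysis entry points are [com_rdf()] and
#' [nearest_atom_rdf()].
#'
#' @param bin_edges Increasing numeric vector of bin edges (Angstrom),
#'   starting at 0 or above.
#' @param g Per-bin values of the distribution function.
#' @param rho Bulk number density of the binned species (molecules per
#'   Angstrom^3) used for normalization and integration.
#' @param counts Optional per-bin raw pair counts.
#' @param shell_g Optional matrix of per-shell components (bins x shells).
#' @param shell_counts Optional matrix of per-shell raw pair counts.
#' @param metric `"com_r"` or `"nearest_atom_s"`.
#' @param n_frames Number of frames averaged.
#' @param species Species label.
#' @return An `rdf_curve` object.
#' @export
rdf_curve <- function(bin_edges, g, rho, counts = NULL, shell_g = NULL,
                      shell_counts = NULL, metric = "com_r", n_frames = 1,
                      species = NA_character_) {
  bin_edges <- as.numeric(bin_edges)
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be increasing")
  if (length(g) != length(bin_edges) - 1)
    stop("g must have one value per bin")
  if (any(g < 0)) stop("g values must be non-negative")
  structure(list(bin_edges = bin_edges,
                 r = (head(bin_edges, -1) + tail(bin_edges, -1)) / 2,
                 g = as.numeric(g), counts = counts,
                 shell_g = shell_g, shell_counts = shell_counts,
                 metric = metric, rho = rho, n_frames = n_frames,
                 species = species),
            class = "rdf_curve")
}

#' @export
print.rdf_curve <- function(x, ...) {
  cat("rdf_curve (", x$metric, ", species ", x$species, "): ",
      length(x$g), " bins to ", max(x$bin_edges), " A, rho = ",
      signif(x$rho, 5), " A^-3, ", x$n_frames, " frames\n", sep = "")
  invisible(x)
}

.rdf_r_max <- function(r_max, box) {
  if (is.null(r_max)) r_max <- 0.49 * min(box)
  if (r_max > 0.5 * min(box))
    stop("r_max = ", r_max, " exceeds half the smallest box edge (",
         0.5 * min(box), " A); the minimum-image convention is only valid ",
         "below that distance")
  r_max
}

# shared histogram engine for both distance metrics
.solute_rdf <- function(traj, topology, species, bin_width, r_max,
                        shell_map, shells, metric) {
  box <- as.numeric(traj$frames[[1]]$box)
  r_max <- .rdf_r_max(r_max, box)
  nb <- floor(r_max / bin_width)
  if (nb < 1) stop("r_max smaller than one bin")
  edges <- seq(0, by = bin_width, length.out = nb + 1)

  mols <- topology$molecules
  sel <- which(mols$species == species & mols$molecule_id != topology$solute_id)
  if (!length(sel)) stop("no solvent molecules of species '", species, "'")
  solute_atoms <- mol_atoms(topology, topology$solute_id)

  decompose <- !is.null(shell_map)
  if (decompose) {
    if (nrow(shell_map$shells) != n_frames(traj))
      stop("shell_map covers ", nrow(shell_map$shells),
           " frames but the trajectory has ", n_frames(traj))
    comp_names <- c(as.character(shells), "rest")
    shell_counts <- matrix(0L, nb, length(comp_names),
                           dimnames = list(NULL, comp_names))
  } else shell_counts <- NULL

  counts <- integer(nb)
  for (f in seq_len(n_frames(traj))) {
    fr <- traj$frames[[f]]
    if (max(abs(as.numeric(fr$box) - box)) > 1e-9)
      stop("box must be constant along the trajectory")
    coms <- molecule_coms(fr, topology)
    target <- coms[sel, , drop = FALSE]
    if (metric == "com_r") {
      solute_com <- coms[match(topology$solute_id, mols$molecule_id), ]
      d <- min_image_dist_vec(target, solute_com, box)
    } else {
      d <- rep(Inf, nrow(target))
      for (a in solute_atoms)
        d <- pmin(d, min_image_dist_vec(target, fr$coords[a, ], box))
    }
    bin <- findInterval(d, edges, rightmost.closed = FALSE)
    ok <- bin >= 1 & bin <= nb
    counts <- counts + tabulate(bin[ok], nb)
    if (decompose) {
      sh <- shell_map$shells[f, match(mols$molecule_id[sel],
                                      colnames(shell_map$shells))]
      comp <- ifelse(sh %in% shells, as.character(sh), "rest")
      for (cn in comp_names) {
        m <- ok & comp == cn
        if (any(m))
          shell_counts[, cn] <- shell_counts[, cn] + tabulate(bin[m], nb)
      }
    }
  }

  vbin <- 4 * pi / 3 * diff(edges^3)     # exact spherical bin volumes
  rho <- length(sel) / prod(box)
  norm <- n_frames(traj) * rho * vbin
  rdf_curve(edges, counts / norm, rho, counts = counts,
            shell_g = if (decompose) sweep(shell_counts, 1, norm, "/"),
            shell_counts = shell_counts, metric = metric,
            n_frames = n_frames(traj), species = species)
}

#' Center-of-mass radial distribution function around the solute
#'
#' Histogram of minimum-image distances between the solute center of mass
#' and the centers of mass of all molecules of one solvent species,
#' normalized per frame by the exact spherical bin volume times the
#' whole-box species density rho_j = N_j / V_box.
#'
#' @param traj A [trajectory()] with a constant box.
#' @param topology A [topology()].
#' @param species Solvent species label.
#' @param bin_width Bin width in Angstrom.
#' @param r_max Histogram range; defaults to 0.49 x smallest box edge and
#'   must stay within half the smallest edge (minimum-image validity).
#' @param shell_map Optional `shell_map` from [map_shells()]; when given,
#'   every pair contribution is additionally routed to the solvent
#'   molecule's current Voronoi shell.
#' @param shells Shell indices resolved individually in the decomposition;
#'   all others are pooled into a `"rest"` component.
#' @return An `rdf_curve`.
#' @export
com_rdf <- function(traj, topology, species, bin_width = 0.1, r_max = NULL,
                    shell_map = NULL, shells = 1:3) {
  .solute_rdf(traj, topology, species, bin_width, r_max, shell_map, shells,
              metric = "com_r")
}

#' Nearest-solute-atom distribution function
#'
#' As [com_rdf()], but the abscissa is the distance s from the solvent
#' molecule's center of mass to the nearest solute atom.  The curve is
#' normalized by the same spherical bin volume 4 pi s^2 ds, which is biased
#' near an extended solute (part of that volume is excluded by the solute
#' itself); it is intended for resolving surface structure, not for
#' Kirkwood-Buff integration.
#'
#' @inheritParams com_rdf
#' @return An `rdf_curve` with metric `"nearest_atom_s"`.
#' @export
nearest_atom_rdf <- function(traj, topology, species, bin_width = 0.1,
                             r_max = NULL, shell_map = NULL, shells = 1:3) {
  .solute_rdf(traj, topology, species, bin_width, r_max, shell_map, shells,
              metric = "nearest_atom_s")
}

#' Voronoi-shell decomposition of a solute-solvent distribution function
#'
#' Convenience wrapper: computes [com_rdf()] (or [nearest_atom_rdf()])
#' with every pair contribution routed to the solvent molecule's current
#' Voronoi shell.  The per-bin components sum to the total exactly.
#'
#' @inheritParams com_rdf
#' @param metric `"com_r"` or `"nearest_atom_s"`.
#' @return An `rdf_curve` with `shell_g` components.
#' @export
shell_decompose_rdf <- function(traj, topology, species, shell_map,
                                shells = 1:3, bin_width = 0.1, r_max = NULL,
                                metric = c("com_r", "nearest_atom_s")) {
  metric <- match.arg(metric)
  .solute_rdf(traj, topology, species, bin_width, r_max, shell_map, shells,
              metric = metric)
}

# trapezoidal quadrature of f(r) over [0, R] on bin centers, f(0) = 0
.trapz_to <- function(r, f, R) {
  if (R > max(r) + (r[2] - r[1]) / 2 || R < 0)
    stop("R = ", R, " outside the binned range")
  keep <- r < R
  fr <- c(0, f[keep], approx(r, f, R, rule = 2)$y)
  rr <- c(0, r[keep], R)
  sum(diff(rr) * (head(fr, -1) + tail(fr, -1)) / 2)
}

# running cumulative trapezoid from 0 at every bin center
.trapz_running <- function(r, f) {
  rr <- c(0, r); ff <- c(0, f)
  cumsum(c(0, diff(rr) * (head(ff, -1) + tail(ff, -1)) / 2))[-1]
}

#' Cumulative coordination number
#'
#' CN(R) = rho_j int_0^R g(r) 4 pi r^2 dr by trapezoidal quadrature on the
#' bin centers.
#'
#' @param rdf An `rdf_curve`.
#' @param R Upper integration limit (Angstrom), within the binned range.
#' @return Coordination number (molecules).
#' @export
cumulative_cn <- function(rdf, R) {
  f <- 4 * pi * rdf$rho * rdf$r^2 * rdf$g
  .trapz_to(rdf$r, f, R)
}

#' First minimum of a distribution function
#'
#' Locates the first strict local minimum after the first local maximum of
#' the moving-average-smoothed curve.  When several candidate minima have
#' depths within 5 percent of the chosen one, the result is flagged as
#' ambiguous -- picking a shell radius this way is not always well defined,
#' and a manual override of R is supported everywhere it is consumed.
#'
#' @param rdf An `rdf_curve`.
#' @param smoothing_window Width (bins, odd) of the centered moving
#'   average applied before the scan.
#' @return List with elements `R` (Angstrom), `index`, `value` (smoothed g
#'   at the minimum), `ambiguous` (flag) and `candidates` (all local
#'   minima positions after the first maximum).
#' @export
first_minimum <- function(rdf, smoothing_window = 5) {
  w <- as.integer(smoothing_window)
  if (w < 1 || w %% 2 == 0) stop("smoothing_window must be odd and >= 1")
  g <- rdf$g
  s <- if (w == 1) g else
    as.numeric(stats::filter(g, rep(1 / w, w), sides = 2))
  idx <- which(!is.na(s))
  s <- s[idx]
  n <- length(s)
  if (n < 3) stop("curve too short")
  interior <- 2:(n - 1)
  maxima <- interior[s[interior] > s[interior - 1] & s[interior] > s[interior + 1]]
  if (!length(maxima)) stop("no minimum: curve has no local maximum")
  first_max <- maxima[1]
  minima <- interior[s[interior] < s[interior - 1] & s[interior] < s[interior + 1]]
  minima <- minima[minima > first_max]
  if (!length(minima)) stop("no minimum after the first maximum")
  chosen <- minima[1]
  ref <- if (s[chosen] > 0) s[chosen] else max(s)
  ambiguous <- any(abs(s[minima[-1]] - s[chosen]) <= 0.05 * ref)
  list(R = rdf$r[idx[chosen]], index = idx[chosen], value = s[chosen],
       ambiguous = ambiguous, candidates = rdf$r[idx[minima]])
}

#' Kirkwood-Buff integral
#'
#' Running integral dG(r) = int_0^r (g - 1) 4 pi x^2 dx.  Convergence of
#' the running curve should always be inspected: spherical Kirkwood-Buff
#' integrals converge notoriously slowly.
#'
#' @param rdf An `rdf_curve`.
#' @param r_upper Upper limit (Angstrom); defaults to the last bin center.
#' @return List with `delta_g` (Angstrom^3), `delta_g_cm3_mol`
#'   (cm^3/mol) and `running` (data frame `r`, `delta_g`).
#' @export
kb_integral <- function(rdf, r_upper = NULL) {
  if (is.null(r_upper)) r_upper <- max(rdf$r)
  f <- 4 * pi * rdf$r^2 * (rdf$g - 1)
  dg <- .trapz_to(rdf$r, f, r_upper)
  running <- data.frame(r = rdf$r, delta_g = .trapz_running(rdf$r, f))
  list(delta_g = dg,
       delta_g_cm3_mol = dg * 1e-24 * .n_avogadro / 1,
       running = running)
}

#' Kirkwood-Buff summary of a distribution function
#'
#' Bundles the running Kirkwood-Buff integral, the cumulative coordination
#' number curve, the shell radius R (first minimum unless overridden), the
#' coordination number at R and the excess coordination number
#' dCN = CN(R) - (4 pi / 3) R^3 rho_j.
#'
#' @param rdf An `rdf_curve`.
#' @param R Shell radius override (Angstrom); default: [first_minimum()].
#' @param smoothing_window Passed to [first_minimum()].
#' @return A `kb_result` list.
#' @export
kb_analysis <- function(rdf, R = NULL, smoothing_window = 5) {
  ambiguous <- FALSE
  if (is.null(R)) {
    fm <- first_minimum(rdf, smoothing_window)
    R <- fm$R
    ambiguous <- fm$ambiguous
  }
  fcn <- 4 * pi * rdf$rho * rdf$r^2 * rdf$g
  cn_curve <- data.frame(r = rdf$r, cn = .trapz_running(rdf$r, fcn))
  kb <- kb_integral(rdf)
  cn_at_R <- cumulative_cn(rdf, R)
  structure(list(R = R, R_ambiguous = ambiguous, cn_at_R = cn_at_R,
                 delta_cn = cn_at_R - 4 * pi / 3 * R^3 * rdf$rho,
                 rho = rdf$rho, cn_curve = cn_curve,
                 delta_g = kb$delta_g, running = kb$running),
            class = "kb_result")
}

#' Excess coordination number
#'
#' dCN = CN(R) - (4 pi / 3) R^3 rho_j: the coordination number at the
#' shell radius minus its ideal-bulk expectation.
#'
#' @param kb A `kb_result` from [kb_analysis()].
#' @return Excess coordination number (molecules).
#' @export
excess_cn <- function(kb) {
  if (is.null(kb$cn_at_R) || is.null(kb$R)) stop("kb_result lacks R / CN(R)")
  kb$cn_at_R - 4 * pi / 3 * kb$R^3 * kb$rho
}

#' @export
print.kb_result <- function(x, ...) {
  cat("kb_result: R =", signif(x$R, 5), "A",
      if (x$R_ambiguous) "(ambiguous minimum)", "\n")
  cat("  CN(R) =", signif(x$cn_at_R, 5),
      " dCN =", signif(x$delta_cn, 5),
      " dG(max) =", signif(x$delta_g, 5), "A^3\n")
  invisible(x)
}
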