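# Solute-solvent pair interaction energies: truncated minimum-image
# Coulomb and Lennard-Jones sums, and the per-first-shell-molecule
# interaction profile.
#
# The Coulomb sum is a direct pair sum with minimum-image truncation (the
# simulation-style cutoff, default 14 A) rather than an Ewald sum: lattice
# sums are not pairwise-decomposable per solvent molecule, and the
# per-molecule decomposition requires a direct pair sum.  This is an
# approximation for charged species and is documented as such.

# minimum-image distances between two atom blocks -> matrix (na x nb)
.pair_dist <- function(fr, ia, ib) {
  box <- as.numeric(fr$box)
  a <- fr$coords[ia, , drop = FALSE]
  b <- fr$coords[ib, , drop = FALSE]
  d2 <- matrix(0, length(ia), length(ib))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Coulomb interaction energy between two molecules
#'
#' Sum over inter-molecular atom pairs of k_e q_i q_j / r_ij with
#' minimum-image distances; pairs beyond the cutoff are skipped.
#' k_e = 1389.354 kJ Angstrom / (mol e^2).
#'
#' @param fr A [frame()].
#' @param topology A [topology()] with charges.
#' @param mol_a,mol_b Molecule ids (must differ).
#' @param cutoff Distance cutoff in Angstrom (`Inf` for none).
#' @return Energy in kJ/mol.
#' @export
pair_coulomb <- function(fr, topology, mol_a, mol_b, cutoff = 14) {
  if (mol_a == mol_b) stop("pair energies are inter-molecular only")
  ia <- mol_atoms(topology, mol_a); ib <- mol_atoms(topology, mol_b)
  q <- topology$atoms$charge
  if (anyNA(q[c(ia, ib)]))
    stop("missing charges on atoms ",
         paste(intersect(which(is.na(q)), c(ia, ib)), collapse = ", "))
  r <- .pair_dist(fr, ia, ib)
  e <- .ke_coulomb * outer(q[ia], q[ib]) / r
  sum(e[r < cutoff])
}

#' Lennard-Jones interaction energy between two molecules
#'
#' Sum over inter-molecular atom pairs of 4 eps_ij ((sig_ij/r)^12 -
#' (sig_ij/r)^6), truncated at the cutoff without shift.  Cross
#' parameters by Lorentz-Berthelot combination (arithmetic sigma,
#' geometric epsilon) or all-geometric combination.
#'
#' @inheritParams pair_coulomb
#' @param combining `"lorentz_berthelot"` (default) or `"geometric"`.
#' @return Energy in kJ/mol.
#' @export
pair_lj <- function(fr, topology, mol_a, mol_b, cutoff = 14,
                    combining = c("lorentz_berthelot", "geometric")) {
  combining <- match.arg(combining)
  if (mol_a == mol_b) stop("pair energies are inter-molecular only")
  ia <- mol_atoms(topology, mol_a); ib <- mol_atoms(topology, mol_b)
  eps <- topology$atoms$epsilon; sig <- topology$atoms$sigma
  if (anyNA(eps[c(ia, ib)]) || anyNA(sig[c(ia, ib)]))
    stop("missing Lennard-Jones parameters")
  r <- .pair_dist(fr, ia, ib)
  sij <- if (combining == "lorentz_berthelot")
    outer(sig[ia], sig[ib], "+") / 2 else sqrt(outer(sig[ia], sig[ib]))
  eij <- sqrt(outer(eps[ia], eps[ib]))
  sr6 <- (sij / r)^6
  e <- 4 * eij * (sr6^2 - sr6)
  sum(e[r < cutoff])
}

#' Per-molecule interaction profile of the first solvation shell
#'
#' For every frame and every molecule in the first Voronoi shell, the
#' solute-molecule Coulomb and Lennard-Jones energies are accumulated;
#' species means are the totals divided by the sample counts, i.e. the
#' average interaction of one solvent molecule of that species with the
#' solute while it resides in the first shell.
#'
#' @param traj A [trajectory()].
#' @param topology A [topology()].
#' @param shell_map A `shell_map` from [map_shells()].
#' @param cutoff Pair cutoff in Angstrom.
#' @param combining Lennard-Jones combining rule, see [pair_lj()].
#' @return An `interaction_profile` data frame: `species`,
#'   `mean_coulomb`, `sd_coulomb`, `mean_vdw`, `sd_vdw` (kJ/mol),
#'   `n_samples`.
#' @export
first_shell_energy_profile <- function(traj, topology, shell_map,
                                       cutoff = 14,
                                       combining = "lorentz_berthelot") {
  if (nrow(shell_map$shells) != n_frames(traj))
    stop("shell_map frame count does not match the trajectory")
  mols <- topology$molecules
  acc <- new.env()
  for (sp in unique(mols$species))
    assign(sp, list(c = numeric(0), v = numeric(0)), envir = acc)
  for (f in seq_len(n_frames(traj))) {
    fr <- traj$frames[[f]]
    members <- mols$molecule_id[shell_map$shells[f, ] == 1L]
    for (m in members) {
      sp <- mols$species[mols$molecule_id == m]
      ec <- pair_coulomb(fr, topology, topology$solute_id, m, cutoff)
      ev <- pair_lj(fr, topology, topology$solute_id, m, cutoff, combining)
      cur <- get(sp, envir = acc)
      cur$c <- c(cur$c, ec); cur$v <- c(cur$v, ev)
      assign(sp, cur, envir = acc)
    }
  }
  species <- setdiff(unique(mols$species),
                     mols$species[mols$molecule_id == topology$solute_id])
  rows <- lapply(species, function(sp) {
    cur <- get(sp, envir = acc)
    data.frame(species = sp,
               mean_coulomb = if (length(cur$c)) mean(cur$c) else NA_real_,
               sd_coulomb = if (length(cur$c) > 1) sd(cur$c) else NA_real_,
               mean_vdw = if (length(cur$v)) mean(cur$v) else NA_real_,
               sd_vdw = if (length(cur$v) > 1) sd(cur$v) else NA_real_,
               n_samples = length(cur$c),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (sum(out$n_samples) == 0)
    stop("first shell is empty across all frames")
  class(out) <- c("interaction_profile", "data.frame")
  out
}
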