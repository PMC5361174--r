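# Shell concentrations and per-shell solvation free energies from the
# Voronoi shell census.

#' Concentration of a species in a Voronoi shell
#'
#' c_j(shell) = CN_j(shell) / V(shell): the time-averaged molecule count
#' over the time-averaged total cell volume of the shell (ratio of means;
#' see [solvation_free_energy()] for the mean-of-ratios variant).
#'
#' @param census A `shell_census` from [shell_census()].
#' @param species Species label.
#' @param shell Shell index (integer, or `"bulk"` for the pooled
#'   remainder).
#' @return Named numeric vector: concentration in `A3` (molecules per
#'   Angstrom^3) and `molL` (mol/L).
#' @export
shell_concentration <- function(census, species, shell) {
  shell <- as.character(shell)
  row <- census[census$shell == shell & census$species == species, ]
  if (nrow(row) != 1)
    stop("no census entry for species '", species, "', shell ", shell)
  if (row$volume <= 0) stop("shell ", shell, " has zero volume")
  c_a3 <- row$cn / row$volume
  c(A3 = c_a3, molL = c_a3 * .ang3_to_molL)
}

#' Per-shell solvation free energies
#'
#' dA_j(shell) = -R T ln(c_j(shell) / c_j(bulk)) at temperature T, for
#' every species and shell of the census.  Negative values indicate
#' preferred solvation (enrichment at the solute), positive values
#' expulsion of the species from that shell (dewetting); dA approaches
#' zero in the most distant shells of a homogeneous solvent.  An empty
#' shell (c_shell = 0) is reported as +Inf.
#'
#' @param census A `shell_census`.
#' @param T Temperature in K.
#' @param c_bulk Bulk concentrations (molecules/Angstrom^3) as a named
#'   vector per species.  Default: the whole-box species density
#'   N_j / V_box from the census.  Pass the known reservoir density when
#'   the construction provides one (e.g. synthetic enrichment fixtures).
#' @param estimator `"ratio_of_means"` (default; time-averaged counts over
#'   time-averaged volumes, stabler for sparse species) or
#'   `"mean_of_ratios"` (per-frame concentration averaged over frames).
#' @return A `shell_thermo` data frame: `species`, `shell`, `cn`,
#'   `volume` (Angstrom^3), `c_shell_molL`, `c_bulk_molL`,
#'   `delta_A` (kJ/mol).
#' @export
solvation_free_energy <- function(census, T = 300, c_bulk = NULL,
                                  estimator = c("ratio_of_means",
                                                "mean_of_ratios")) {
  estimator <- match.arg(estimator)
  if (!is.numeric(T) || T <= 0) stop("temperature must be positive")
  species_tot <- attr(census, "species_totals")
  vbox <- attr(census, "box_volume")
  solute_sp <- attr(census, "solute_species")
  keep <- census$shell != "0" & !census$species %in% solute_sp
  if (is.null(c_bulk)) {
    c_bulk <- as.numeric(species_tot) / vbox
    names(c_bulk) <- names(species_tot)
  } else {
    miss <- setdiff(unique(census$species[keep]), names(c_bulk))
    if (length(miss))
      stop("c_bulk missing species: ", paste(miss, collapse = ", "))
    if (any(c_bulk <= 0)) stop("c_bulk must be positive")
  }

  out <- census[keep, c("species", "shell", "cn", "volume")]
  rownames(out) <- NULL
  if (estimator == "ratio_of_means") {
    c_shell <- out$cn / out$volume
  } else {
    counts <- attr(census, "counts")
    volumes <- attr(census, "volumes")
    c_shell <- mapply(function(s, sp) {
      v <- volumes[, s]
      ok <- v > 0
      if (!any(ok)) return(NA_real_)
      mean(counts[ok, s, sp] / v[ok])
    }, out$shell, out$species)
  }
  cb <- c_bulk[out$species]
  out$c_shell_molL <- c_shell * .ang3_to_molL
  out$c_bulk_molL <- cb * .ang3_to_molL
  out$delta_A <- ifelse(c_shell > 0, -.r_gas * T * log(c_shell / cb), Inf)
  out$T <- T
  class(out) <- c("shell_thermo", "data.frame")
  out
}

#' @export
print.shell_thermo <- function(x, ...) {
  cat("shell_thermo at T =", x$T[1], "K (dA in kJ/mol):\n")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
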