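#' Molecular topology
#'
#' A topology groups atoms into molecules, labels molecules with species
#' names, designates the single solute molecule and carries the per-atom
#' force-field attributes (mass, partial charge, Lennard-Jones epsilon and
#' sigma) plus hydrogen-bond donor/acceptor flags.
#'
#' @param atoms A data frame with one row per atom, in trajectory order.
#'   Required columns: `molecule_id` (integer, contiguous blocks) and
#'   `species` (label, constant within a molecule).  Optional columns with
#'   defaults: `name`, `element` (default from `name`), `mass` (default:
#'   standard element mass), `charge` (0), `epsilon` (0, kJ/mol),
#'   `sigma` (0, Angstrom), `is_donor_h` (FALSE), `is_acceptor` (FALSE).
#' @param bonds Two-column integer matrix of covalently bonded atom index
#'   pairs (1-based atom ids); needed for donor-hydrogen geometry.
#' @param solute Molecule id of the single solute molecule.
#' @return A `topology` object.
#' @export
topology <- function(atoms, bonds = NULL, solute) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (n == 0) stop("topology needs at least one atom")
  if (is.null(atoms$molecule_id)) stop("atoms need a molecule_id column")
  if (is.null(atoms$species)) stop("atoms need a species column")
  if (is.null(atoms$name)) atoms$name <- paste0("X", seq_len(n))
  if (is.null(atoms$element)) atoms$element <- gsub("[0-9]+$", "", atoms$name)
  if (is.null(atoms$mass)) atoms$mass <- .element_mass(atoms$element)
  atoms$mass[is.na(atoms$mass)] <- .element_mass(atoms$element[is.na(atoms$mass)])
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$epsilon)) atoms$epsilon <- 0
  if (is.null(atoms$sigma)) atoms$sigma <- 0
  if (is.null(atoms$is_donor_h)) atoms$is_donor_h <- FALSE
  if (is.null(atoms$is_acceptor)) atoms$is_acceptor <- FALSE
  atoms$atom_id <- seq_len(n)
  atoms$molecule_id <- as.integer(atoms$molecule_id)

  if (any(atoms$mass < 0)) stop("negative atomic mass")
  if (any(atoms$epsilon < 0) || any(atoms$sigma < 0))
    stop("negative Lennard-Jones parameters")

  # molecules must be contiguous atom blocks
  rle_mol <- rle(atoms$molecule_id)
  if (anyDuplicated(rle_mol$values))
    stop("atoms of a molecule must be contiguous")
  mol_ids <- rle_mol$values
  last <- cumsum(rle_mol$lengths)
  first <- c(1L, head(last, -1) + 1L)
  mol_species <- atoms$species[first]
  if (!all(atoms$species == rep(mol_species, rle_mol$lengths)))
    stop("species label must be constant within a molecule")

  molecules <- data.frame(molecule_id = mol_ids, species = mol_species,
                          first = first, last = last,
                          stringsAsFactors = FALSE)

  solute <- as.integer(solute)
  if (length(solute) != 1 || !(solute %in% mol_ids))
    stop("solute must name exactly one molecule present in the topology")

  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1) || any(bonds > n))
      stop("bond list references invalid atom ids")
  }

  # donor flag only on hydrogens that have a recorded covalent partner
  don <- which(atoms$is_donor_h)
  if (length(don)) {
    if (!all(atoms$element[don] %in% c("H", "D")))
      stop("is_donor_h set on non-hydrogen atoms: ",
           paste(don[!atoms$element[don] %in% c("H", "D")], collapse = ", "))
    bonded <- if (is.null(bonds)) integer(0) else unique(c(bonds))
    if (!all(don %in% bonded))
      stop("donor hydrogens without a recorded covalent bond: atoms ",
           paste(setdiff(don, bonded), collapse = ", "))
  }

  structure(list(atoms = atoms, molecules = molecules, bonds = bonds,
                 solute_id = solute),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,", nrow(x$molecules), "molecules\n")
  tab <- table(x$molecules$species)
  cat("  species:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  solute: molecule", x$solute_id, "(",
      x$molecules$species[x$molecules$molecule_id == x$solute_id], ")\n")
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)
n_molecules <- function(top) nrow(top$molecules)

# atom indices (rows) of a molecule
mol_atoms <- function(top, molecule_id) {
  m <- top$molecules[top$molecules$molecule_id == molecule_id, ]
  if (nrow(m) != 1) stop("unknown molecule_id ", molecule_id)
  seq.int(m$first, m$last)
}

species_of <- function(top) top$molecules$species

#' Read a topology from a YAML configuration file
#'
#' The config lists species templates in trajectory order.  Each species
#' block gives the per-molecule atoms (name/element/mass/charge/
#' epsilon/sigma/donor/acceptor), intra-molecular bonds (1-based within the
#' molecule), and the number of molecules of that species.  The `solute`
#' key names the species holding the single solute molecule.
#'
#' @param path Path to the YAML file.
#' @return A `topology`.
#' @export
read_topology <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species)) stop("topology config needs a 'species' list")
  if (is.null(cfg$solute)) stop("topology config needs a 'solute' key")
  atoms <- list(); bonds <- list()
  mol_id <- 0L; at_off <- 0L
  solute_mol <- NA_integer_
  for (sp in cfg$species) {
    count <- if (is.null(sp$count)) 1L else as.integer(sp$count)
    adf <- do.call(rbind, lapply(sp$atoms, function(a) {
      data.frame(name = a$name %||% "X",
                 element = a$element %||% gsub("[0-9]+$", "", a$name %||% "X"),
                 mass = a$mass %||% NA_real_,
                 charge = a$charge %||% 0,
                 epsilon = a$epsilon %||% 0,
                 sigma = a$sigma %||% 0,
                 is_donor_h = isTRUE(a$donor),
                 is_acceptor = isTRUE(a$acceptor),
                 stringsAsFactors = FALSE)
    }))
    na <- nrow(adf)
    bl <- if (is.null(sp$bonds)) NULL else matrix(as.integer(unlist(sp$bonds)),
                                                  ncol = 2, byrow = TRUE)
    for (k in seq_len(count)) {
      mol_id <- mol_id + 1L
      a <- adf
      a$molecule_id <- mol_id
      a$species <- sp$name
      atoms[[length(atoms) + 1L]] <- a
      if (!is.null(bl)) bonds[[length(bonds) + 1L]] <- bl + at_off
      if (identical(sp$name, cfg$solute) && is.na(solute_mol))
        solute_mol <- mol_id
      at_off <- at_off + na
    }
  }
  if (is.na(solute_mol)) stop("solute species '", cfg$solute, "' not found")
  topology(do.call(rbind, atoms),
           bonds = if (length(bonds)) do.call(rbind, bonds) else NULL,
           solute = solute_mol)
}

#' Write a topology to a YAML configuration file
#'
#' Inverse of [read_topology()]; consecutive identical molecules are
#' collapsed into species blocks with a count.
#'
#' @param top A `topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  mols <- top$molecules
  specs <- list()
  i <- 1
  while (i <= nrow(mols)) {
    sp <- mols$species[i]
    j <- i
    while (j < nrow(mols) && mols$species[j + 1] == sp) j <- j + 1
    rows <- seq.int(mols$first[i], mols$last[i])
    a <- top$atoms[rows, ]
    atoms <- lapply(seq_len(nrow(a)), function(k) {
      list(name = a$name[k], element = a$element[k], mass = a$mass[k],
           charge = a$charge[k], epsilon = a$epsilon[k], sigma = a$sigma[k],
           donor = a$is_donor_h[k], acceptor = a$is_acceptor[k])
    })
    blk <- list(name = sp, count = j - i + 1L, atoms = atoms)
    if (!is.null(top$bonds)) {
      sel <- top$bonds[, 1] >= mols$first[i] & top$bonds[, 1] <= mols$last[i]
      if (any(sel)) {
        bl <- top$bonds[sel, , drop = FALSE] - mols$first[i] + 1L
        blk$bonds <- lapply(seq_len(nrow(bl)), function(k) as.integer(bl[k, ]))
      }
    }
    specs[[length(specs) + 1L]] <- blk
    i <- j + 1
  }
  solute_sp <- mols$species[mols$molecule_id == top$solute_id]
  yaml::write_yaml(list(solute = solute_sp, species = specs), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
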