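# Geometric hydrogen-bond detection: an H...A contact is a hydrogen bond
# iff the minimum-image H-acceptor distance is strictly below d_max AND
# the D-H...A angle at the hydrogen is strictly above angle_min (so a
# perfectly linear bond is 180 degrees).

#' Geometric hydrogen-bond criterion
#'
#' @param d_max Maximum H...acceptor distance in Angstrom (strict
#'   inequality; default 2.4).
#' @param angle_min Minimum donor-H...acceptor angle at the hydrogen in
#'   degrees (strict inequality; default 135).
#' @return An `hbond_criterion`.
#' @export
hbond_criterion <- function(d_max = 2.4, angle_min = 135) {
  if (d_max <= 0) stop("d_max must be positive")
  if (angle_min <= 0 || angle_min >= 180)
    stop("angle_min must be in (0, 180) degrees")
  structure(list(d_max = d_max, angle_min = angle_min),
            class = "hbond_criterion")
}

# covalent heavy-atom partner of each donor hydrogen
.donor_partners <- function(topology) {
  don <- which(topology$atoms$is_donor_h)
  if (!length(don)) return(integer(0))
  if (is.null(topology$bonds))
    stop("donor hydrogens present but the topology has no bond list")
  partner <- setNames(rep(NA_integer_, length(don)), don)
  for (i in seq_along(don)) {
    h <- don[i]
    hit <- c(topology$bonds[topology$bonds[, 1] == h, 2],
             topology$bonds[topology$bonds[, 2] == h, 1])
    if (!length(hit))
      stop("donor hydrogen atom ", h, " has no bonded heavy atom")
    partner[i] <- hit[1]
  }
  partner
}

#' Detect solute-solvent hydrogen bonds in a frame
#'
#' Evaluates the geometric criterion for both directions (solute as donor
#' towards solvent acceptors, and solvent donors towards solute
#' acceptors), restricted to the solute and one solvent species (or all
#' species).
#'
#' @param fr A [frame()].
#' @param topology A [topology()] with donor/acceptor flags and bonds.
#' @param criterion An [hbond_criterion()].
#' @param species Solvent species label, or `NULL` for all species.
#' @return Data frame with one row per bond: `h_atom`, `donor_atom`,
#'   `acceptor_atom`, `distance` (Angstrom), `angle` (degrees),
#'   `direction` (`"solute_donor"` / `"solute_acceptor"`), `species` (of
#'   the partner molecule).
#' @export
detect_hbonds <- function(fr, topology, criterion = hbond_criterion(),
                          species = NULL) {
  at <- topology$atoms
  box <- as.numeric(fr$box)
  partner <- .donor_partners(topology)
  solute_atoms <- mol_atoms(topology, topology$solute_id)
  in_species <- if (is.null(species)) {
    at$molecule_id != topology$solute_id
  } else {
    at$species == species & at$molecule_id != topology$solute_id
  }

  check <- function(hs, as_) {
    if (!length(hs) || !length(as_)) return(NULL)
    out <- list()
    for (h in hs) {
      d <- partner[[as.character(h)]]
      av <- min_image_disp(fr$coords[as_, , drop = FALSE], fr$coords[h, ], box)
      dist <- sqrt(rowSums(av * av))
      near <- which(dist < criterion$d_max)
      if (!length(near)) next
      dv <- min_image_disp(fr$coords[d, , drop = FALSE], fr$coords[h, ], box)
      dv <- dv / sqrt(sum(dv * dv))
      cosang <- (av[near, , drop = FALSE] %*% t(dv)) / dist[near]
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      hit <- which(ang > criterion$angle_min)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          h_atom = h, donor_atom = d, acceptor_atom = as_[near[hit]],
          distance = dist[near[hit]], angle = ang[hit])
    }
    if (length(out)) do.call(rbind, out) else NULL
  }

  don_h <- which(at$is_donor_h)
  acc <- which(at$is_acceptor)

  sd <- check(intersect(don_h, solute_atoms), intersect(acc, which(in_species)))
  sa <- check(intersect(don_h, which(in_species)),
              intersect(acc, solute_atoms))
  res <- list()
  if (!is.null(sd)) { sd$direction <- "solute_donor"; res$sd <- sd }
  if (!is.null(sa)) { sa$direction <- "solute_acceptor"; res$sa <- sa }
  if (!length(res))
    return(data.frame(h_atom = integer(0), donor_atom = integer(0),
                      acceptor_atom = integer(0), distance = numeric(0),
                      angle = numeric(0), direction = character(0),
                      species = character(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  partner_mol <- ifelse(out$direction == "solute_donor",
                        at$molecule_id[out$acceptor_atom],
                        at$molecule_id[out$h_atom])
  out$species <- at$species[match(partner_mol, at$molecule_id)]
  out
}

#' Hydrogen-bond counts along a trajectory
#'
#' Per-frame counts of solute hydrogen bonds to every solvent species,
#' tallied separately as solute-as-donor and solute-as-acceptor plus
#' their sum, with trajectory means and standard deviations.
#'
#' @param traj A [trajectory()].
#' @param topology A [topology()].
#' @param criterion An [hbond_criterion()].
#' @return An `hbond_profile` list: `per_frame` data frame (`frame`,
#'   `species`, `donor`, `acceptor`, `total`) and `summary` data frame
#'   (`species`, `mean_donor`, `mean_acceptor`, `mean_total`, `sd_total`).
#' @export
hbond_profile <- function(traj, topology, criterion = hbond_criterion()) {
  species <- setdiff(unique(topology$molecules$species),
                     topology$molecules$species[
                       topology$molecules$molecule_id == topology$solute_id])
  nf <- n_frames(traj)
  rows <- list()
  for (f in seq_len(nf)) {
    bonds <- detect_hbonds(traj$frames[[f]], topology, criterion)
    for (sp in species) {
      b <- bonds[bonds$species == sp, ]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, species = sp,
        donor = sum(b$direction == "solute_donor"),
        acceptor = sum(b$direction == "solute_acceptor"),
        total = nrow(b), stringsAsFactors = FALSE)
    }
  }
  per_frame <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(species, function(sp) {
    b <- per_frame[per_frame$species == sp, ]
    data.frame(species = sp, mean_donor = mean(b$donor),
               mean_acceptor = mean(b$acceptor), mean_total = mean(b$total),
               sd_total = if (nrow(b) > 1) sd(b$total) else 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_frame = per_frame, summary = summary),
            class = "hbond_profile")
}

#' @export
print.hbond_profile <- function(x, ...) {
  cat("hbond_profile over", max(x$per_frame$frame), "frames:\n")
  print.data.frame(x$summary, digits = 4)
  invisible(x)
}
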