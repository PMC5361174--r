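# Independent brute-force oracles and small fixture builders shared by the
# test files.  Oracles deliberately avoid the package's own code paths.

# exhaustive minimum over the 27 periodic image translations
oracle_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- (b + c(i, j, k) * box) - a
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# brute-force Coulomb sum between two atom index sets (27-image minimum)
oracle_coulomb <- function(coords, q, ia, ib, box, cutoff = Inf) {
  e <- 0
  for (i in ia) for (j in ib) {
    r <- oracle_min_image(coords[i, ], coords[j, ], box)
    if (r < cutoff) e <- e + 1389.354 * q[i] * q[j] / r
  }
  e
}

oracle_lj <- function(coords, eps, sig, ia, ib, box, cutoff = Inf) {
  e <- 0
  for (i in ia) for (j in ib) {
    r <- oracle_min_image(coords[i, ], coords[j, ], box)
    if (r < cutoff) {
      sij <- (sig[i] + sig[j]) / 2
      eij <- sqrt(eps[i] * eps[j])
      e <- e + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    }
  }
  e
}

# brute-force solute-solvent distance histogram (per-molecule COM built
# with plain arithmetic; single-atom molecules only)
oracle_rdf_counts <- function(frames, solute_row, target_rows, box,
                              bin_width, n_bins, nearest_rows = NULL) {
  counts <- integer(n_bins)
  for (fr in frames) {
    for (t in target_rows) {
      if (is.null(nearest_rows)) {
        d <- oracle_min_image(fr[solute_row, ], fr[t, ], box)
      } else {
        d <- min(vapply(nearest_rows, function(a)
          oracle_min_image(fr[a, ], fr[t, ], box), numeric(1)))
      }
      b <- floor(d / bin_width) + 1
      if (b >= 1 && b <= n_bins) counts[b] <- counts[b] + 1L
    }
  }
  counts
}

# grid-based periodic Voronoi oracle: assign a cubic grid of probe points
# to the nearest site (minimum image) and read off volumes and
# face-adjacency.  Edge/vertex-only contacts produce O(n_grid) touching
# pairs while true faces produce O(n_grid^2), so a count threshold
# separates them.
oracle_grid_voronoi <- function(sites, box, n_grid = 64) {
  stopifnot(length(unique(box)) == 1)
  L <- box[1]
  g <- (seq_len(n_grid) - 0.5) * L / n_grid
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  n <- nrow(sites)
  owner <- integer(nrow(pts))
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    d <- pts - matrix(sites[i, ], nrow(pts), 3, byrow = TRUE)
    d <- d - L * round(d / L)
    di <- rowSums(d * d)
    take <- di < best
    owner[take] <- i
    best[take] <- di[take]
  }
  vol <- tabulate(owner, n) * (L / n_grid)^3
  arr <- array(owner, c(n_grid, n_grid, n_grid))
  contacts <- integer(n * n)
  shift_count <- function(a, b) {
    sel <- a != b
    i <- pmin(a[sel], b[sel]); j <- pmax(a[sel], b[sel])
    contacts <<- contacts + tabulate((i - 1L) * n + j, n * n)
  }
  wrap <- c(2:n_grid, 1)
  shift_count(arr, arr[wrap, , ])
  shift_count(arr, arr[, wrap, ])
  shift_count(arr, arr[, , wrap])
  contacts <- matrix(contacts, n, n, byrow = TRUE)
  # faces carry ~ (n_grid/n^(1/3))^2 contacts; edges only ~ n_grid
  thresh <- max(4L, as.integer(0.25 * n_grid^2 / n^(2 / 3)))
  adj <- contacts + t(contacts) > thresh
  list(volumes = vol, adjacency = adj)
}

oracle_bfs <- function(adj, start) {
  n <- nrow(adj)
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (m in frontier) {
      nb <- which(adj[m, ] & is.na(dist))
      dist[nb] <- dist[m] + 1L
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  dist
}

# brute-force hydrogen-bond finder: all (donor-H, acceptor) pairs checked
# with explicit 27-image geometry
oracle_hbonds <- function(coords, box, donors_h, partners, acceptors,
                          mol_id, d_max = 2.4, angle_min = 135) {
  hits <- list()
  for (k in seq_along(donors_h)) {
    h <- donors_h[k]; d <- partners[k]
    for (a in acceptors) {
      if (mol_id[a] == mol_id[h]) next
      # nearest image of a relative to h
      bestv <- NULL; bestr <- Inf
      for (i in -1:1) for (j in -1:1) for (l in -1:1) {
        v <- coords[a, ] + c(i, j, l) * box - coords[h, ]
        r <- sqrt(sum(v * v))
        if (r < bestr) { bestr <- r; bestv <- v }
      }
      if (bestr >= d_max) next
      bestdv <- NULL; bestdr <- Inf
      for (i in -1:1) for (j in -1:1) for (l in -1:1) {
        v <- coords[d, ] + c(i, j, l) * box - coords[h, ]
        r <- sqrt(sum(v * v))
        if (r < bestdr) { bestdr <- r; bestdv <- v }
      }
      ang <- acos(max(-1, min(1, sum(bestv * bestdv) / (bestr * bestdr)))) *
        180 / pi
      if (ang > angle_min)
        hits[[length(hits) + 1L]] <- c(h = h, a = a)
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("h", "a")))
}

# n water-like 3-site molecules plus a hydroxyl solute, for energetics and
# hydrogen-bond tests
make_polar_system <- function(n_water, box_edge, seed = 1) {
  water <- data.frame(
    name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
    mass = c(15.999, 1.008, 1.008),
    charge = c(-0.8476, 0.4238, 0.4238),
    epsilon = c(0.65, 0, 0), sigma = c(3.166, 0, 0),
    is_donor_h = c(FALSE, TRUE, TRUE), is_acceptor = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  solute <- data.frame(
    name = c("C1", "O1", "HO1"), element = c("C", "O", "H"),
    mass = c(12.011, 15.999, 1.008), charge = c(0.15, -0.6, 0.45),
    epsilon = c(0.3, 0.5, 0), sigma = c(3.6, 3.0, 0),
    is_donor_h = c(FALSE, FALSE, TRUE),
    is_acceptor = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  atoms <- rbind(cbind(solute, molecule_id = 1L, species = "solute"),
                 do.call(rbind, lapply(seq_len(n_water), function(i)
                   cbind(water, molecule_id = i + 1L, species = "W"))))
  bonds <- rbind(c(2L, 3L),                      # O1-HO1
                 do.call(rbind, lapply(seq_len(n_water), function(i) {
                   o <- 3L + (i - 1L) * 3L + 1L
                   rbind(c(o, o + 1L), c(o, o + 2L))
                 })))
  top <- topology(atoms, bonds = bonds, solute = 1L)
  set.seed(seed)
  place_mol <- function(center) {
    rbind(center,
          center + c(0.96, 0, 0) + rnorm(3, 0, 0.02),
          center + c(-0.24, 0.93, 0) + rnorm(3, 0, 0.02))
  }
  coords <- place_mol(rep(box_edge / 2, 3))
  for (i in seq_len(n_water))
    coords <- rbind(coords, place_mol(runif(3) * box_edge))
  list(topology = top, frame = frame(coords, box_edge))
}
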