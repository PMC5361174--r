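# Periodic Voronoi tessellation, molecular cells, shell assignment, census.

test_that("two opposed molecules split a cubic box into equal half cells", {
  L <- 10
  top <- voroshell:::.single_atom_topology(c("solute", "W"))
  fr <- frame(rbind(c(L / 4, L / 2, L / 2), c(3 * L / 4, L / 2, L / 2)), L)
  cells <- tessellate_frame(fr, top)
  expect_equal(unname(cells$volumes), c(500, 500), tolerance = 1e-12)
  expect_equal(cells$neighbors[["1"]], 2)
  expect_equal(cells$neighbors[["2"]], 1)
  # two shared faces through periodicity: 2 * L^2 of bisector area
  expect_equal(unname(cells$face_areas[["1"]]["2"]), 200, tolerance = 1e-9)
  expect_equal(unname(assign_shells(cells, 1)), c(0L, 1L))
})

test_that("random frames partition the box and the neighbor relation is symmetric", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 60
    box <- c(14, 16, 18)
    top <- voroshell:::.single_atom_topology(c("solute", rep("W", n - 1)))
    fr <- frame(sweep(matrix(runif(3 * n), ncol = 3), 2, box, "*"), box)
    cells <- tessellate_frame(fr, top)
    expect_lt(abs(sum(cells$volumes) - prod(box)) / prod(box), 1e-9)
    # symmetry of the raw directed face areas
    d <- cells$directed
    key <- paste(d$i, d$j)
    rev <- match(paste(d$j, d$i), key)
    expect_false(anyNA(rev))
    expect_lt(max(abs(d$area - d$area[rev])), 1e-6)
    # adjacency lists are mutual
    mutual <- vapply(names(cells$neighbors), function(m)
      all(vapply(cells$neighbors[[m]], function(nb)
        as.integer(m) %in% cells$neighbors[[as.character(nb)]],
        logical(1))), logical(1))
    expect_true(all(mutual))
  }
})

test_that("cell volumes agree with a Monte-Carlo nearest-site oracle", {
  set.seed(5)
  n <- 10; L <- 12
  sites <- matrix(runif(3 * n) * L, ncol = 3)
  top <- voroshell:::.single_atom_topology(c("solute", rep("W", n - 1)))
  cells <- tessellate_frame(frame(sites, L), top)
  npts <- 2e5
  pts <- matrix(runif(3 * npts) * L, ncol = 3)
  best <- rep(Inf, npts); owner <- integer(npts)
  for (i in seq_len(n)) {
    d <- pts - matrix(sites[i, ], npts, 3, byrow = TRUE)
    d <- d - L * round(d / L)
    di <- rowSums(d * d)
    take <- di < best
    owner[take] <- i; best[take] <- di[take]
  }
  phat <- tabulate(owner, n) / npts
  se <- sqrt(phat * (1 - phat) / npts)
  mc_vol <- phat * L^3
  expect_true(all(abs(mc_vol - cells$volumes) <= 3 * se * L^3 + 1e-9))
})

test_that("tessellation matches an independent Qhull construction exactly", {
  # scipy.spatial (Qhull) on the same ghost-replicated sites is a fully
  # independent geometric oracle for volumes and shell indices
  set.seed(42)
  n <- 80; L <- 15
  sites <- matrix(runif(3 * n) * L, ncol = 3)
  top <- voroshell:::.single_atom_topology(c("solute", rep("W", n - 1)))
  cells <- tessellate_frame(frame(sites, L), top)
  shells <- assign_shells(cells, 1)
  td <- withr::local_tempdir()
  write.table(sites, file.path(td, "sites.txt"), row.names = FALSE,
              col.names = FALSE)
  script <- sprintf('
import numpy as np, itertools, collections
from scipy.spatial import Voronoi, ConvexHull
x = np.loadtxt(%s); L = %f; n = len(x)
imgs = [np.array(s) * L for s in itertools.product([-1, 0, 1], repeat=3)
        if s != (0, 0, 0)]
allpts = np.vstack([x] + [x + s for s in imgs])
vor = Voronoi(allpts)
vols = [ConvexHull(vor.vertices[vor.regions[vor.point_region[i]]]).volume
        for i in range(n)]
adj = collections.defaultdict(set)
for p, q in vor.ridge_points:
    if p < n or q < n:
        adj[p %% n].add(q %% n); adj[q %% n].add(p %% n)
dist = {0: 0}; frontier = [0]
while frontier:
    nxt = []
    for m in frontier:
        for nb in adj[m]:
            if nb not in dist:
                dist[nb] = dist[m] + 1; nxt.append(nb)
    frontier = nxt
np.savetxt(%s, np.column_stack([vols, [dist[i] for i in range(n)]]))
', shQuote(file.path(td, "sites.txt")), L,
    shQuote(file.path(td, "out.txt")))
  writeLines(script, file.path(td, "oracle.py"))
  status <- system2("python", file.path(td, "oracle.py"),
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  ref <- as.matrix(read.table(file.path(td, "out.txt")))
  expect_equal(unname(cells$volumes), ref[, 1], tolerance = 1e-9)
  expect_identical(unname(shells), as.integer(ref[, 2]))
})

test_that("lattice shells match exact ground truth and the grid oracle", {
  sc <- gen_lattice("sc", n_cells = 5, a = 4)
  cells <- tessellate_frame(sc$trajectory$frames[[1]], sc$topology)
  shells <- assign_shells(cells, 1)
  expect_equal(sum(shells == 1), 6L)
  expect_equal(sum(shells == 2), 18L)
  expect_equal(unname(cells$volumes), rep(64, 125), tolerance = 1e-9)

  fcc <- gen_lattice("fcc", n_cells = 4, a = 5)
  cf <- tessellate_frame(fcc$trajectory$frames[[1]], fcc$topology)
  sf <- assign_shells(cf, 1)
  expect_equal(sum(sf == 1), 12L)
  # FCC cells carry degenerate vertices; volumes exact to clipping tolerance
  expect_equal(unname(cf$volumes), rep(5^3 / 4, 256), tolerance = 1e-7)

  # independent half-space (grid) oracle on the SC lattice
  sites <- sc$trajectory$frames[[1]]$coords
  or <- oracle_grid_voronoi(sites, as.numeric(sc$trajectory$frames[[1]]$box),
                            n_grid = 60)
  expect_equal(sum(or$adjacency[1, ]), 6)
  odist <- oracle_bfs(or$adjacency, 1)
  expect_identical(unname(shells), odist)
})

test_that("shell indices are BFS distances on the exported neighbor graph", {
  skip_if_not_installed("igraph")
  set.seed(12)
  n <- 40; L <- 13
  top <- voroshell:::.single_atom_topology(c("solute", rep("W", n - 1)))
  cells <- tessellate_frame(frame(matrix(runif(3 * n) * L, ncol = 3), L), top)
  shells <- assign_shells(cells, 1)
  g <- igraph::graph_from_data_frame(cells$edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = 1:n))
  ref <- as.integer(igraph::distances(g, v = "1")[1, as.character(1:n)])
  expect_identical(unname(shells), ref)
})

test_that("rigid translation leaves volumes, adjacency and shells unchanged", {
  set.seed(77)
  n <- 50; L <- 12
  top <- voroshell:::.single_atom_topology(c("solute", rep("W", n - 1)))
  x <- matrix(runif(3 * n) * L, ncol = 3)
  c1 <- tessellate_frame(frame(x, L), top)
  shift <- c(3.217, -5.882, 9.004)
  c2 <- tessellate_frame(frame(sweep(x, 2, shift, "+"), L), top)
  expect_equal(c1$volumes, c2$volumes, tolerance = 1e-9)
  expect_identical(lapply(c1$neighbors, sort), lapply(c2$neighbors, sort))
  expect_identical(assign_shells(c1, 1), assign_shells(c2, 1))
})

test_that("coincident sites trigger the deterministic jitter retry", {
  top <- voroshell:::.single_atom_topology(c("solute", "W", "W"))
  fr <- frame(rbind(c(2, 2, 2), c(7, 7, 7), c(7, 7, 7)), 10)
  cells <- tessellate_frame(fr, top)
  expect_lt(abs(sum(cells$volumes) - 1000) / 1000, 1e-9)
  expect_true(all(cells$volumes > 0))
})

test_that("shell census time-averages counts and volumes consistently", {
  # a static frame repeated is identical to the single-frame census
  set.seed(21)
  n <- 40; L <- 12
  top <- voroshell:::.single_atom_topology(
    c("solute", rep(c("A", "B"), c(31, 8))))
  x <- matrix(runif(3 * n) * L, ncol = 3)
  fr <- frame(x, L)
  traj1 <- trajectory(list(fr))
  traj10 <- trajectory(lapply(0:9, function(t) frame(x, L, time = t)))
  c1 <- shell_census(traj1, top, max_shell = 2)
  c10 <- shell_census(traj10, top, max_shell = 2)
  expect_equal(c1$cn, c10$cn)
  expect_equal(c1$volume, c10$volume, tolerance = 1e-12)
  # volumes partition the box
  expect_equal(sum(c1$volume[c1$species == "A"]), L^3, tolerance = 1e-6)
  expect_error(shell_census(traj1, top, max_shell = 0), "max_shell")
})

test_that("ideal-gas shell composition follows the species fractions", {
  gen <- gen_ideal_gas(n_molecules = 250, box_edge = 20,
                       species_fractions = c(A = 0.8, B = 0.2),
                       n_frames = 30, seed = 14)
  cen <- shell_census(gen$trajectory, gen$topology, max_shell = 2)
  n_a <- cen$cn[cen$shell == "1" & cen$species == "A"]
  n_b <- cen$cn[cen$shell == "1" & cen$species == "B"]
  # binomial: fraction of A among first-shell members
  ntot <- (n_a + n_b) * 30
  phat <- n_a / (n_a + n_b)
  se <- sqrt(0.8 * 0.2 / ntot)
  expect_lt(abs(phat - 0.8), 3 * se + 0.02)
})

test_that("heavy-atom-only tessellation drops hydrogen sites", {
  sys <- make_polar_system(6, 14)
  cells_all <- tessellate_frame(sys$frame, sys$topology)
  cells_heavy <- tessellate_frame(sys$frame, sys$topology, sites = "heavy")
  expect_equal(sum(cells_heavy$volumes), 14^3, tolerance = 1e-6)
  expect_equal(length(cells_heavy$volumes), 7)
  expect_false(identical(cells_all$volumes, cells_heavy$volumes))
})

test_that("neighbor graph exports as a frame-tagged edge list", {
  set.seed(3)
  top <- voroshell:::.single_atom_topology(c("solute", rep("W", 9)))
  cells <- tessellate_frame(frame(matrix(runif(30) * 10, ncol = 3), 10), top)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_neighbor_graph(cells, path, frame_index = 4)
  df <- read.delim(path)
  expect_named(df, c("frame", "mol_i", "mol_j", "face_area"))
  expect_true(all(df$frame == 4))
  expect_equal(nrow(df), nrow(cells$edges))
})
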