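# Trajectory/topology data model, file formats, periodic geometry.

test_that("XYZ writer/reader round-trips coordinates, box and times", {
  gen <- gen_ideal_gas(n_molecules = 5, box_edge = 12, n_frames = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(gen$trajectory, path, gen$topology)
  back <- read_trajectory(path, "xyz", gen$topology)
  expect_equal(length(back$frames), 3)
  for (f in 1:3) {
    expect_equal(back$frames[[f]]$coords, gen$trajectory$frames[[f]]$coords,
                 tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(back$frames[[f]]$time, gen$trajectory$frames[[f]]$time)
    expect_equal(as.numeric(back$frames[[f]]$box), rep(12, 3))
  }
})

test_that("GRO boxes are nanometers and convert to Angstrom", {
  top <- voroshell:::.single_atom_topology(c("solute", "W"))
  lines <- c("test t= 0.0", "2",
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "SOL", "X", 1,
                     1.0, 2.0, 3.0),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 2, "W", "X", 2,
                     4.0, 5.0, 0.5),
             "   6.0015   6.0015   6.0015")
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(lines, path)
  traj <- read_trajectory(path, "gro", top)
  expect_equal(as.numeric(traj$frames[[1]]$box), rep(60.015, 3))
  expect_equal(traj$frames[[1]]$coords[1, ], c(10, 20, 30),
               ignore_attr = TRUE)
})

test_that("PDB frames read CRYST1 boxes and reject triclinic cells", {
  top <- voroshell:::.single_atom_topology(c("solute", "W"))
  pdb <- c(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1",
                   20, 20, 20, 90, 90, 90),
           sprintf("ATOM  %5d  X   MOL A%4d    %8.3f%8.3f%8.3f", 1, 1,
                   1.5, 2.5, 3.5),
           sprintf("ATOM  %5d  X   MOL A%4d    %8.3f%8.3f%8.3f", 2, 2,
                   6.0, 7.0, 8.0))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  traj <- read_trajectory(path, "pdb", top)
  expect_equal(traj$frames[[1]]$coords[2, ], c(6, 7, 8), ignore_attr = TRUE)
  pdb[1] <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1",
                    20, 20, 20, 90, 95, 90)
  writeLines(pdb, path)
  expect_error(read_trajectory(path, "pdb", top), "triclinic")
})

test_that("structural errors name the offending frame and refuse missing boxes", {
  top <- voroshell:::.single_atom_topology(c("solute", "W", "W"))
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("4", "10 10 10", "X 1 1 1", "X 2 2 2", "X 3 3 3", "X 4 4 4"),
             path)
  expect_error(read_trajectory(path, "xyz", top), "frame 0")
  writeLines(c("3", "no box here at all", "X 1 1 1", "X 2 2 2", "X 3 3 3"),
             path)
  expect_error(read_trajectory(path, "xyz", top), "box")
})

test_that("wrapping maps into the half-open box and preserves molecules", {
  b <- simulation_box(10)
  fr <- frame(rbind(c(-1, 0, 0), c(10, 5, 5)), b)
  w <- wrap_frame(fr)
  expect_equal(w$coords[1, ], c(9, 0, 0), ignore_attr = TRUE)
  expect_equal(w$coords[2, ], c(0, 5, 5), ignore_attr = TRUE)
  # diatomic straddling the boundary: rigid wrap keeps the bond length
  atoms <- data.frame(name = c("A", "B"), element = "C", mass = 12,
                      molecule_id = 1L, species = "solute")
  atoms <- rbind(atoms, data.frame(name = "C", element = "C", mass = 12,
                                   molecule_id = 2L, species = "W"))
  top <- topology(atoms, solute = 1L)
  fr2 <- frame(rbind(c(9.7, 5, 5), c(10.4, 5, 5), c(3, 3, 3)), b)
  w2 <- wrap_frame(fr2, top)
  bond <- sqrt(sum((w2$coords[1, ] - w2$coords[2, ])^2))
  expect_equal(bond, 0.7, tolerance = 1e-12)
  expect_true(all(w2$coords[1, ] >= 0 & w2$coords[1, ] < 10))
})

test_that("center of mass handles weights and split molecules", {
  atoms <- data.frame(name = c("A", "B"), element = "C",
                      mass = c(1, 1), molecule_id = 1L, species = "solute")
  atoms <- rbind(atoms, data.frame(name = "C", element = "C", mass = 12,
                                   molecule_id = 2L, species = "W"))
  top <- topology(atoms, solute = 1L)
  fr <- frame(rbind(c(0, 0, 0), c(2, 0, 0), c(5, 5, 5)), 10)
  expect_equal(center_of_mass(fr, top, 1), c(1, 0, 0))
  # masses 1 and 3 at x = 0 and 4
  top2 <- topology(within(top$atoms, mass <- c(1, 3, 12)), solute = 1L)
  fr2 <- frame(rbind(c(0, 0, 0), c(4, 0, 0), c(5, 5, 5)), 10)
  expect_equal(center_of_mass(fr2, top2, 1), c(3, 0, 0))
  # split across the boundary: COM wraps to 0, never 5
  fr3 <- frame(rbind(c(9.5, 0, 0), c(0.5, 0, 0), c(5, 5, 5)), 10)
  expect_equal(center_of_mass(fr3, top, 1), c(0, 0, 0))
})

test_that("minimum-image distance matches the 27-image oracle", {
  b <- simulation_box(10)
  expect_equal(minimum_image_distance(c(1, 0, 0), c(9, 0, 0), b), 2)
  expect_equal(minimum_image_distance(c(3, 4, 5), c(3, 4, 5), b), 0)
  set.seed(8)
  box <- c(8, 11, 14)
  for (i in 1:50) {
    a <- runif(3) * box
    p <- runif(3) * box
    expect_equal(minimum_image_distance(a, p, simulation_box(box)),
                 oracle_min_image(a, p, box), tolerance = 1e-12)
  }
  # symmetry and half-diagonal bound
  for (i in 1:20) {
    a <- runif(3) * box; p <- runif(3) * box
    d1 <- minimum_image_distance(a, p, simulation_box(box))
    expect_equal(d1, minimum_image_distance(p, a, simulation_box(box)))
    expect_lte(d1, sqrt(sum((box / 2)^2)) + 1e-12)
  }
})

test_that("topology validation enforces its invariants", {
  atoms <- data.frame(name = c("O", "H"), element = c("O", "H"),
                      molecule_id = c(1L, 1L), species = "solute")
  # donor hydrogen needs a recorded bond
  a2 <- within(atoms, is_donor_h <- c(FALSE, TRUE))
  expect_error(topology(a2, solute = 1L), "bond")
  expect_s3_class(topology(a2, bonds = rbind(c(1L, 2L)), solute = 1L),
                  "topology")
  # donor flag on a non-hydrogen
  a3 <- within(atoms, is_donor_h <- c(TRUE, FALSE))
  expect_error(topology(a3, bonds = rbind(c(1L, 2L)), solute = 1L),
               "non-hydrogen")
  # non-contiguous molecule blocks
  a4 <- data.frame(name = c("A", "B", "C"), element = "C",
                   molecule_id = c(1L, 2L, 1L),
                   species = c("solute", "W", "solute"))
  expect_error(topology(a4, solute = 1L), "contiguous")
  # solute must exist
  expect_error(topology(atoms, solute = 9L), "solute")
  # zero total mass is rejected at COM time
  a5 <- within(atoms, mass <- c(0, 0))
  top5 <- topology(a5, solute = 1L)
  expect_error(center_of_mass(frame(rbind(c(1, 1, 1), c(2, 2, 2)), 10),
                              top5, 1), "mass")
})

test_that("topology YAML config round-trips", {
  sys <- make_polar_system(3, 15)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_topology(sys$topology, path)
  back <- read_topology(path)
  expect_equal(back$atoms$charge, sys$topology$atoms$charge)
  expect_equal(back$atoms$species, sys$topology$atoms$species)
  expect_equal(back$atoms$is_donor_h, sys$topology$atoms$is_donor_h)
  expect_equal(back$solute_id, sys$topology$solute_id)
  expect_equal(dim(back$bonds), dim(sys$topology$bonds))
})

test_that("trajectories require uniform strictly increasing times", {
  f <- function(t) frame(matrix(runif(6), 2), 10, time = t)
  expect_error(trajectory(list(f(0), f(0.5), f(0.7))), "uniform")
  expect_error(trajectory(list(f(0), f(0))), "increasing")
  expect_equal(trajectory(list(f(0), f(0.5), f(1)))$frame_spacing, 0.5)
})
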