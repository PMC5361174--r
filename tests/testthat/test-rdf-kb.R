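# Radial distribution functions, shell decomposition, coordination
# numbers and Kirkwood-Buff integrals.

test_that("histogram counts match a brute-force pair loop", {
  set.seed(9)
  n <- 25; box <- c(12, 12, 12)
  top <- voroshell:::.single_atom_topology(c("solute", rep("W", n - 1)))
  frames <- lapply(0:2, function(t)
    frame(matrix(runif(3 * n) * box[1], ncol = 3), box, time = t))
  traj <- trajectory(frames)
  curve <- com_rdf(traj, top, "W", bin_width = 0.25, r_max = 5.5)
  ref <- oracle_rdf_counts(lapply(frames, function(f) f$coords), 1, 2:n,
                           box, 0.25, length(curve$counts))
  expect_identical(curve$counts, ref)
  # nearest-atom variant with a 3-atom solute
  atoms <- data.frame(name = c("A", "B", "C"), element = "C", mass = 12,
                      molecule_id = 1L, species = "solute")
  atoms <- rbind(atoms, data.frame(name = paste0("X", 1:(n - 1)),
                                   element = "Ar", mass = 18,
                                   molecule_id = 1L + seq_len(n - 1),
                                   species = "W"))
  top3 <- topology(atoms, solute = 1L)
  frames3 <- lapply(0:2, function(t)
    frame(matrix(runif(3 * (n + 2)) * box[1], ncol = 3), box, time = t))
  traj3 <- trajectory(frames3)
  ncurve <- nearest_atom_rdf(traj3, top3, "W", bin_width = 0.25, r_max = 5.5)
  ref3 <- oracle_rdf_counts(lapply(frames3, function(f) f$coords), NULL,
                            4:(n + 2), box, 0.25, length(ncurve$counts),
                            nearest_rows = 1:3)
  expect_identical(ncurve$counts, ref3)
})

test_that("a single solvent molecule lands in exactly one bin", {
  top <- voroshell:::.single_atom_topology(c("solute", "W"))
  L <- 20
  fr <- frame(rbind(c(10, 10, 10), c(10 + 4.23, 10, 10)), L)
  curve <- com_rdf(trajectory(list(fr)), top, "W", bin_width = 0.1)
  expect_equal(sum(curve$counts), 1L)
  expect_equal(curve$r[which(curve$counts == 1)], 4.25)
})

test_that("nearest-atom distances reduce to COM distances for a point solute", {
  gen <- gen_ideal_gas(n_molecules = 40, box_edge = 15, n_frames = 2, seed = 4)
  a <- com_rdf(gen$trajectory, gen$topology, "A", bin_width = 0.2)
  b <- nearest_atom_rdf(gen$trajectory, gen$topology, "A", bin_width = 0.2)
  expect_identical(a$counts, b$counts)
})

test_that("a solvent ring at constant surface distance gives one nearest-atom bin", {
  # linear triatomic solute along x; solvent placed directly above each
  # atom at height s0 has nearest-atom distance exactly s0
  s0 <- 3.07
  atoms <- data.frame(name = c("A", "B", "C"), element = "C", mass = 12,
                      molecule_id = 1L, species = "solute")
  atoms <- rbind(atoms, data.frame(name = paste0("X", 1:3), element = "Ar",
                                   mass = 18, molecule_id = 2:4,
                                   species = "W"))
  top <- topology(atoms, solute = 1L)
  ctr <- c(12, 12, 12)
  solute <- rbind(ctr + c(-1.4, 0, 0), ctr, ctr + c(1.4, 0, 0))
  solv <- sweep(solute, 2, c(0, 0, s0), "+")
  fr <- frame(rbind(solute, solv), 24)
  curve <- nearest_atom_rdf(trajectory(list(fr)), top, "W", bin_width = 0.1)
  expect_equal(sum(curve$counts), 3L)
  expect_equal(sum(curve$counts > 0), 1L)
  expect_equal(curve$r[which(curve$counts > 0)], 3.05)
})

test_that("shell components partition the histogram exactly", {
  gen <- gen_ideal_gas(n_molecules = 120, box_edge = 16, n_frames = 5,
                       seed = 6)
  sm <- map_shells(gen$trajectory, gen$topology)
  curve <- com_rdf(gen$trajectory, gen$topology, "A", shell_map = sm)
  expect_identical(as.integer(rowSums(curve$shell_counts)), curve$counts)
  expect_equal(unname(rowSums(curve$shell_g)), curve$g, tolerance = 1e-12)
  # two-molecule system: all signal in shell 1
  top2 <- voroshell:::.single_atom_topology(c("solute", "W"))
  fr2 <- frame(rbind(c(8, 8, 8), c(11, 8, 8)), 16)
  tr2 <- trajectory(list(fr2))
  sm2 <- map_shells(tr2, top2)
  c2 <- com_rdf(tr2, top2, "W", shell_map = sm2)
  expect_equal(sum(c2$shell_counts[, "1"]), 1L)
  expect_equal(sum(c2$shell_counts[, c("2", "3", "rest")]), 0L)
  # frame mismatch is refused
  sm_short <- sm; sm_short$shells <- sm$shells[1:3, ]
  expect_error(com_rdf(gen$trajectory, gen$topology, "A",
                       shell_map = sm_short), "frames")
})

test_that("SC lattice shell components integrate to 6 and 18 molecules", {
  sc <- gen_lattice("sc", n_cells = 5, a = 4)
  sm <- map_shells(sc$trajectory, sc$topology)
  curve <- shell_decompose_rdf(sc$trajectory, sc$topology, "lattice", sm,
                               bin_width = 0.1)
  expect_equal(sum(curve$shell_counts[, "1"]), 6L)
  expect_equal(sum(curve$shell_counts[, "2"]), 18L)
})

test_that("cumulative coordination numbers reproduce closed forms", {
  edges <- seq(0, 10, by = 0.1)
  rho <- 0.02
  zero <- rdf_curve(edges, rep(0, 100), rho)
  expect_equal(cumulative_cn(zero, 8), 0)
  flat <- rdf_curve(edges, rep(1, 100), rho)
  R <- 6.05
  expect_equal(cumulative_cn(flat, R), 4 * pi / 3 * R^3 * rho,
               tolerance = 1e-3)
  # smooth Gaussian enhancement vs adaptive quadrature oracle
  gfun <- function(r) 1 + 2 * exp(-(r - 3)^2 / (2 * 0.8^2))
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  bump <- rdf_curve(edges, gfun(centers), rho)
  R2 <- 9.95
  ref <- stats::integrate(function(r) 4 * pi * rho * r^2 * gfun(r), 0, R2,
                          rel.tol = 1e-10)$value
  expect_equal(cumulative_cn(bump, R2), ref, tolerance = 1e-4)
})

test_that("first minimum detection, ambiguity flag and monotone error", {
  edges <- seq(0, 10, by = 0.1)
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  peaky <- function(r) 1 + 1.5 * exp(-(r - 3)^2 / 0.5) +
    0.8 * exp(-(r - 7)^2 / 0.5) - 0.9 * exp(-(r - 5)^2 / 0.5)
  curve <- rdf_curve(edges, peaky(centers), rho = 0.02)
  fm <- first_minimum(curve)
  expect_equal(fm$R, 5.05, tolerance = 0.1)
  expect_false(fm$ambiguous)
  mono <- rdf_curve(edges, seq(0.1, 2, length.out = 100), rho = 0.02)
  expect_error(first_minimum(mono), "no minimum")
  # two troughs of near-equal depth
  double <- function(r) 1 + 1.5 * exp(-(r - 2.5)^2 / 0.3) +
    1.4 * exp(-(r - 5.5)^2 / 0.3) + 1.5 * exp(-(r - 8.5)^2 / 0.3)
  dcurve <- rdf_curve(edges, double(centers), rho = 0.02)
  dm <- first_minimum(dcurve)
  expect_true(dm$ambiguous)
  expect_gte(length(dm$candidates), 2)
})

test_that("Kirkwood-Buff integrals match closed forms", {
  edges <- seq(0, 12, by = 0.1)
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  flat <- rdf_curve(edges, rep(1, length(centers)), rho = 0.01)
  expect_equal(kb_integral(flat)$delta_g, 0, tolerance = 1e-9)
  hs <- rdf_curve(edges, as.numeric(centers > 3), rho = 0.01)
  expect_equal(kb_integral(hs)$delta_g, -4 * pi / 3 * 27, tolerance = 1e-3)
  # unit conversion: Angstrom^3 -> cm^3/mol
  expect_equal(kb_integral(hs)$delta_g_cm3_mol,
               kb_integral(hs)$delta_g * 0.602214076, tolerance = 1e-6)
})

test_that("ideal-gas KB integral is statistically zero", {
  gen <- gen_ideal_gas(n_molecules = 300, box_edge = 20, n_frames = 60,
                       seed = 23)
  # block resampling over frame blocks gives the sampling scale
  blocks <- lapply(0:5, function(b) {
    tr <- trajectory(gen$trajectory$frames[(b * 10 + 1):(b * 10 + 10)])
    kb_integral(com_rdf(tr, gen$topology, "A", bin_width = 0.2),
                r_upper = 8)$delta_g
  })
  pooled <- kb_integral(com_rdf(gen$trajectory, gen$topology, "A",
                                bin_width = 0.2), r_upper = 8)$delta_g
  se <- sd(unlist(blocks)) / sqrt(6)
  expect_lt(abs(pooled), 3 * se + 1e-9)
})

test_that("excess coordination number follows its identity", {
  edges <- seq(0, 12, by = 0.1)
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  rho <- 0.015
  # depletion: hard-sphere hole means negative excess
  hs <- rdf_curve(edges, as.numeric(centers > 3), rho)
  kb <- kb_analysis(hs, R = 5)
  expect_lt(excess_cn(kb), 0)
  # identity dCN(R) = rho * dG(R) via the two code paths
  gfun <- 1 + 0.8 * sin(centers)^2 * exp(-centers / 4)
  wig <- rdf_curve(edges, gfun, rho)
  kb2 <- kb_analysis(wig, R = 7.05)
  # both code paths share the g(r) quadrature; the residual difference is
  # the trapezoid error of the exact-sphere term, O(h^2)
  expect_equal(excess_cn(kb2), rho * kb_integral(wig, r_upper = 7.05)$delta_g,
               tolerance = 2e-3)
  expect_equal(excess_cn(kb2), kb2$delta_cn, tolerance = 1e-12)
})

test_that("r_max beyond the minimum-image range is rejected", {
  gen <- gen_ideal_gas(n_molecules = 20, box_edge = 10, n_frames = 1, seed = 1)
  expect_error(com_rdf(gen$trajectory, gen$topology, "A", r_max = 5.2),
               "minimum-image")
  expect_silent(com_rdf(gen$trajectory, gen$topology, "A", r_max = 4.9))
})

test_that("rdf_curve validates its contract", {
  expect_error(rdf_curve(c(0, 1, 2), c(-0.1, 1), rho = 0.1), "non-negative")
  expect_error(rdf_curve(c(0, 1, 0.5), c(1, 1), rho = 0.1), "increasing")
  expect_error(rdf_curve(c(0, 1, 2), c(1, 1, 1), rho = 0.1), "per bin")
})
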