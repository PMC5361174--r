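# voroshell

Parameter-free solvation-shell analysis of molecular-simulation
trajectories by periodic Voronoi tessellation.

## The problem

Solvation structure around a solute is conventionally measured with the
radial distribution function g(r) between centers of mass, integrated
into Kirkwood–Buff integrals

    ΔG_ij = ∫₀ᴿ [g_ij(r) − 1] 4πr² dr

and cumulative coordination numbers CN_j = ρ_j ∫₀ᴿ g_ij(r) 4πr² dr,
with the shell radius R taken from the first minimum of g(r).  For
anisotropic solutes — flat ring systems, elongated molecules — a single
spherical cutoff mixes first-, second- and third-shell molecules, and R
itself is ambiguous whenever g(r) has several shallow minima.

`voroshell` instead decomposes the entire periodic cell into Voronoi
polyhedra (atomic sites merged into molecular cells).  Two molecules are
neighbors when their cells share a face; the first solvation shell is the
set of direct neighbors of the solute, and shell k is the breadth-first
graph distance k from the solute.  No cutoff, no fitted radius.  On top
of the shell map the package computes shell-decomposed g(r), running
Kirkwood–Buff integrals and excess coordination numbers, per-shell
concentrations and solvation free energies ΔA_j(shell) =
−RT ln[c_j(shell)/c_j(bulk)], residence-time autocorrelation functions
with bi-exponential mean residence times, per-first-shell-molecule
Coulomb/Lennard-Jones interaction energies, and geometric hydrogen-bond
counts (H···A < 2.4 Å, donor–H···A angle > 135°, strict).

It is aimed at people analyzing single-solute MD trajectories in mixed
solvents (water/co-solvent, aqueous ionic liquids) who need
shell-resolved structure, thermodynamics and kinetics that remain
meaningful for anisotropic solutes.

Inputs: XYZ (box on the comment line), GRO or PDB coordinates plus a YAML
topology (species, masses, charges, Lennard-Jones parameters,
donor/acceptor flags, bonds, solute).  Units: Å, ps, kJ/mol, K.  A
synthetic-configuration module (ideal gas, SC/FCC lattices,
surface-enriched solvents, two-state exchange dynamics, planar solutes)
provides fixtures with analytic ground truth for every analysis stage.

## Worked example

Residence kinetics of a solvent exchanging between the first shell and a
reservoir, on the built-in two-state exchange fixture whose true
relaxation time is 10 ps:

```r
library(voroshell)

gen <- gen_exchange_dynamics(seed = 7)   # 120 molecules, 8000 frames, k = 0.1/ps
sm  <- map_shells(gen$trajectory, gen$topology)   # one tessellation pass
cen <- shell_census(sm, max_shell = 2)
print(cen)
#> shell_census (8000 frames):
#>   shell species       cn      volume
#> 1     0  solute  1.00000    74.19128
#> 2     1  solute  0.00000  2988.80269
#> 3     2  solute  0.00000 14435.50470
#> 4  bulk  solute  0.00000  9501.50133
#> 5     0       W  0.00000    74.19128
#> 6     1       W 16.87288  2988.80269
#> 7     2       W 52.53025 14435.50470
#> 8  bulk       W 50.59687  9501.50133

ser <- residence_series(sm, "W")                  # first-shell indicator n(t)
ac  <- residence_autocorrelation(ser, max_lag = 100)
fit <- fit_biexponential(ac)
print(fit)
#> biexp_fit: a1=0.701 tau1=9.731 ps, a2=0.000 tau2=33.333 ps, c=0.137
#>   mean residence time = 9.731 ps (rms residual 5.72e-03)
```

Reading the numbers: the time-averaged first-shell coordination number is
16.9 molecules (and `C(0)` of the residence correlation equals it
identically); the shell volumes partition the 27000 Å³ box exactly.  The
correlation decays to a plateau c = 0.137 — the stationary probability
that a molecule that left the shell is found there again — and the fitted
mean residence time of 9.73 ps recovers the imposed 10 ps relaxation
within 3%.

The same shell map feeds the other analyses: `com_rdf(..., shell_map =
sm)` for shell-decomposed g(r), `solvation_free_energy(cen)` for
per-shell ΔA, `first_shell_energy_profile()` for per-molecule
interaction energies, `hbond_profile()` for hydrogen-bond counts.

A command-line front end covers the same pipeline:

```sh
exec/voroshell synth --kind ideal_gas --out fixtures --seed 1
exec/voroshell all --trajectory fixtures/trajectory.xyz \
    --topology fixtures/topology.yaml --out results
```

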