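# notchwnt

Simulation and analysis of Notch–Wnt signalling crosstalk in coupled
intestinal-crypt cells.

Each cell carries a twelve-species ODE system — seven Notch-side species
(Notch, Delta, NICD, the NICD:β-catenin complex, Hes1, Hath1, Ngn3) and
five Wnt-side species (β-catenin, Axin, free GSK3β, the destruction
complex, and complex-bound β-catenin) — with first-order decays, Hill
activation, hyperbolic repression and mass-action binding. Cells are
coupled by lateral inhibition on a contact graph: Notch production
responds to the mean Delta presented by a cell's neighbours. The Hes1
promoter is the crosstalk hub, mixing a Notch-mediated and a direct
β-catenin transcription route with weight `theta2`.

## Features

- **Model core** — `full_rhs()`, `hes1_production()`, `hill_act()` /
  `hill_inh()`, `psi_w()` / `psi_wa()`, validated parameter sets with
  YAML round-trip (`crypt_params()`, `read_params()`, `write_params()`).
- **Multicell** — arbitrary contact graphs with per-cell environments
  (`cell_graph()`, `coupled_rhs()`, CSV round trip).
- **Simulation** — stiff deterministic integration with timed mutation
  events (APC knockout, Wnt hyperstimulation), and a stochastic
  Euler–Maruyama extension with noise on Hes1 production
  (`build_scenario()`, `run_deterministic()`, `run_stochastic()`).
- **Dynamics analysis** — steady states with Jacobian stability labels,
  amplitude-filtered period measurement, decoupled β-catenin steady
  state, and `theta2 × W` regime sweeps (`find_steady_states()`,
  `measure_period()`, `bstar_decoupled()`, `sweep_regimes()`).
- **Network structure** — influence-annotated reaction networks,
  stoichiometry, conservativity and weak-reversibility checks, a
  text export/import dialect for external structural-analysis tools,
  and a numerical multistability probe (`build_network()`,
  `is_conservative()`, `export_crn_toolbox()`,
  `multistability_probe()`).
- **Calibration** — normalised sensitivity indices, sensitivity-ranked
  sequential 1-D grid fitting, MSE objective, and a synthetic-target
  generator for parameter-recovery tests (`sensitivity_report()`,
  `sequential_fit()`, `generate_synthetic_target()`).

## Worked example

```r
library(notchwnt)

p <- crypt_params()

# Two healthy coupled cells for 24 h
sc <- build_scenario("healthy_pair", p, hours = 24)
tr <- run_deterministic(sc, p)
plot(tr$times / 60, tr$conc[, "cell1", "H1"], type = "l",
     xlab = "time (h)", ylab = "Hes1 (nM)")
lines(tr$times / 60, tr$conc[, "cell2", "H1"], col = 2)

# Decoupled Notch pair: Hes1 oscillates with a ~2.1 h period
np <- build_scenario("notch_pair", p, hours = 14)
measure_period(run_deterministic(np, p), "H1", cell = "cell1")

# Wnt hyperstimulation raises mutant-cell beta-catenin ~2.2-fold
hy <- build_scenario("wnt_hyper_pair", p, W = 1, hours = 24)
trh <- run_deterministic(hy, p)
i <- which(trh$times == 24 * 60)
trh$conc[i, "cell2", "B"] / trh$conc[i, "cell1", "B"]

# Structural analysis of the Wnt-only subnetwork
nw <- build_network("wnt_only", wnt = "on")
is_conservative(nw)
cat(head(export_crn_toolbox(nw), 6), sep = "\n")
```

## Command line

An executable front end ships at `inst/cli/notchwnt`:

```sh
Rscript inst/cli/notchwnt simulate --scenario wnt_hyper_pair --hours 24 \
    --out traj.csv --manifest run.json
Rscript inst/cli/notchwnt sweep --theta2 0:1:11 --W 0,1,2 --out regimes.csv
Rscript inst/cli/notchwnt network --variant full --coupling step4_only \
    --wnt off --export toolbox.txt --probe --out verdict.json
Rscript inst/cli/notchwnt sensitivity --output bstar --out sens.csv
```

## Testing

The package uses testthat (3rd edition):

```r
testthat::test_dir("tests/testthat")
```

`scripts/acceptance.R` recomputes the headline quantities (oscillation
period, fold changes, switching fraction, probe verdicts, sensitivity
rankings) and writes them as flat JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
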