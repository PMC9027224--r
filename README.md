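# petdosim

Internal radiation dosimetry and pharmacokinetics for serial whole-body PET
tracer studies.

First-in-human PET tracer trials quantify three things from a handful of
whole-body scans (typically ~10 min, 1 h and 2 h post-injection), urine
collections and blood samples: the tracer's **biodistribution** (SUV in
organs and lesions), the **radiation dose** a patient absorbs per MBq
administered, and the tracer's **plasma kinetics**. `petdosim` implements
that analysis chain for nuclear-medicine physicists and trial teams, plus a
synthetic-cohort generator with analytic ground truth so every stage can be
validated without patient data.

## The model

* **SUV** — decay-corrected tissue concentration normalised to injected
  activity per body weight: `SUV = C [kBq/mL] · W [kg] / A0 [MBq]`
  (g/mL at unit density).
* **TIAC** (time-integrated activity coefficient, hours) — for each organ,
  concentration × phantom organ mass (scaled by patient/phantom weight)
  gives the decay-uncorrected fraction of injected activity; that sparse
  curve is integrated by the trapezoidal rule, a linear rise from zero over
  `[0, t1]`, and an analytic tail `A(tn)/λ` assuming only physical decay.
* **Bladder voiding model** — pooled cumulative urine activity is fitted to
  a one-phase exponential association `U(t) = F(1 − e^{−kt})`; bladder
  contents between voids are `e^{−λt}[U(t) − U(t_last void)]`, integrated
  over voiding cycles (default interval 1 h) to the bladder-contents TIAC.
  A remainder-of-body TIAC closes the decay balance
  (`Σ TIAC ≤ 1/λ = 1.6350 h` for a 68-min nuclide).
* **MIRD schema** — `D(target) = Σ_source ã(source) · S(target ← source)`,
  with the effective dose `ED = Σ_T w_T D_T` under ICRP-103 tissue weights,
  scalable to an administered activity.
* **Plasma PK** — per-patient mono-exponential fits `C(t) = C0 e^{−kt}`;
  the cohort half-life is the mean of per-patient half-lives.
* **Lesion statistics** — group mean ± SEM of SUVmax/SUVmean and
  tumor-to-organ ratios (per-patient ratios first, averaged second).

The packaged phantom and S-value table are clearly labelled **synthetic**
stand-ins (physically plausible beta-self-dose + photon-bath factors); swap
in your own CSV/JSON via `read_phantom()` / `read_smatrix()` for real work.

## Worked example

```r
library(petdosim)

co  <- gen_cohort(cohort_config(), seed = 42)       # 5 BC + 5 NEN patients
rep <- run_report(co$tac, co$patients, co$phantom, default_smatrix(),
                  urine = co$urine, plasma = co$plasma, lesions = co$lesions)
print(rep)
#> == study report ==
#> cohort TIACs (9 regions), bladder 0.1914 h, remainder 0.6929 h
#> urinary excretion: F = 0.547, biologic T1/2 = 33.0 min
#> effective dose: 0.01255 mSv/MBq (2.51 mSv at 200 MBq)
#> plasma half-life: mean 9.44 min (range 4.96-14.16, n = 7)
```

Reading: about 55 % of the injected activity is excreted renally with a
33-min biologic half-time; the voiding bladder holds 0.19 h of decays, so
the bladder wall tops the absorbed-dose table (0.167 mGy/MBq, ahead of
kidneys at 0.085), and a 200 MBq administration of this synthetic tracer
costs 2.5 mSv. The plasma fits recover the generator's half-lives
(drawn uniformly on 3.9–14.0 min).

The packaged clinical uptake table reproduces its published group means:

```r
s <- lesion_group_summary(example_lesions())
round_half_up(s$suv_max_mean[s$group == "NEN"], 2)
#> [1]  7.21  9.60 10.00
round_half_up(s$suv_max_mean[s$group == "BC"], 2)
#> [1] 5.09 6.32 6.55
```

A thin CLI over the same functions lives at `inst/scripts/petdosim.R`
(subcommands `simulate | stats | pk | dose | report`).

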