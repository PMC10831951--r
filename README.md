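# frapkit

Quantification toolkit for live-cell imaging of DNA-repair factors:
strip-FRAP chromatin-binding analysis, accumulation kinetics at local DNA
damage, and fluorescence-based protein-level / transcription scoring —
together with seeded simulators that generate every input with known ground
truth, so the whole pipeline can be verified by parameter recovery without a
microscope.

## The problem

Transcription-blocking DNA lesions stall elongating RNA polymerase II and
recruit transcription-coupled repair factors (such as CSB and UVSSA) to the
stalled complex. In cells expressing an endogenously tagged fluorescent
fusion of such a factor, three live-cell readouts report on the process:

* **Strip FRAP.** A narrow strip spanning the nucleus is photobleached and
  recovery of fluorescence is imaged at a fixed frame interval. Molecules
  bound to chromatin for longer than the acquisition window do not recover:
  damage converts a mobile protein into a partially *immobile* one.
* **Accumulation at local damage.** After focal UV-C irradiation, the
  fluorescence at the damage spot rises (association-rate-dominated
  recruitment), typically saturating around 1.4-fold over the pre-damage
  level.
* **Protein levels by flow cytometry.** The tagged protein's abundance is
  the mean reporter fluorescence of gated single cells; damage-induced
  degradation appears as a percentage drop relative to untreated cells.

## The core statistic

FRAP traces are background corrected (`roi − background`), normalized so the
mean pre-bleach intensity is exactly 1, ensemble averaged hierarchically
(cells within experiment, then experiments), and renormalized into the
**immobile fraction**

```
F_imm = 1 − (I_final,UV − I_0,UV) / (I_final,unc − I_0,UV)
```

where `I_0,UV` is the treated curve's intensity immediately after bleaching
and `I_final` is the mean intensity over a late steady window (8–12 s for
the CSB-style protocol, 5–8 s for the UVSSA-style protocol) of the treated
(`UV`) and unchallenged (`unc`) conditions. The statistic is deliberately
not clamped to [0, 1].

The simulator behind the recovery tests is a 1-D reaction–diffusion model:
free molecules diffuse with coefficient `D` and exchange with a chromatin-
bound state at rates `kon*`/`koff`; a damage-induced immobile fraction
`f_imm` neither diffuses nor exchanges within the acquisition window. A
closed-form reaction-dominant recovery model serves as an independent
analytic oracle and as the target of the optional kinetic fit.

## Worked example

```r
library(frapkit)

protocol  <- frap_protocol_preset("csb")     # 5 pre + 2 bleach + 30 recovery frames @ 0.4 s
treated   <- simulate_frap_ensemble(frap_sim_config(f_imm = 0.25, seed = 7), protocol, "UV4")
reference <- simulate_frap_ensemble(frap_sim_config(f_imm = 0,    seed = 8), protocol, "NT")

uv <- average_ensemble(normalize_prebleach(treated$traces,   protocol))
nt <- average_ensemble(normalize_prebleach(reference$traces, protocol))
immobile_fraction(uv, nt, protocol = protocol)
#> immobile fraction: 0.2502
#>   I0 = -0.0007, Ifinal(treated) = 0.4295, Ifinal(reference) = 0.5730
#>   steady window [8, 12] s; UV4 vs NT
```

The simulated ground truth was `f_imm = 0.25`; the pipeline recovers 0.2502
from 3 × 10 noisy cells per condition. Note that the unchallenged reference
has not fully recovered inside the window (0.573, because bound-state
turnover is slow relative to 12 s) — the renormalization by the reference
plateau is exactly what makes the statistic insensitive to that.

The same stages are scriptable from a shell via the thin wrapper in
`inst/cli/`:

```sh
frapkit simulate frap --seed 7 --condition NT --out traces.csv
frapkit analyze frap --traces traces.csv --reference NT --window 8 12 --out results.json
```

Accumulation and flow stages work the same way; see `?simulate_accumulation`,
`?curve_auc`, `?compare_auc`, `?gate_events`, `?relative_levels`,
`?rrs_score`.

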