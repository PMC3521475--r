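# hemocirc

A deterministic, closed-loop, lumped-parameter (0-D) simulator of the human
circulation, built for studying **exercise-induced reflex syncope in severe
aortic valve stenosis (AVS)**.

Severe AVS narrows the left-ventricular outflow, producing a systolic
pressure gradient between the left ventricle and the aorta. Patients often
also carry depressed ventricular contractility from long-standing
compensatory hypertrophy. During exercise, a reflex syncope — a sudden
failure of the autonomic feedback that normally keeps arterial pressure on
target — can combine vasodepressor (loss of venous tone) and
cardioinhibitory (bradycardia, reduced contractility) components in varying
proportion. A lumped-parameter model makes each component separately
switchable and gradable, which cannot be done in a patient.

The package is intended for physiologists, modellers and students of
cardiovascular hemodynamics who want a fully reproducible, scriptable model
with per-beat analysis tools.

## The model

The circulation is an electrical-analog network (pressure ↔ voltage, flow ↔
current, volume ↔ charge): seven compliant compartments — left ventricle
(LV), systemic arteries, systemic veins, right atrium, right ventricle
(RV), pulmonary arteries, pulmonary veins + left atrium — joined by Ohmic
resistances, four of which are ideal diodes (mitral, aortic, tricuspid,
pulmonic valves: no reverse flow, ever). Resistance is measured in
U (1 U = 100 mmHg per 100 mL/s, the analog of 1 MΩ; the severe-AVS element
is the 800 kΩ ↔ 0.8 U series resistor at the LV output).

Each ventricle is a time-varying elastance,

    P(t) = a(t) · E_max · (V − V0) + (V − V0)/C_pass + ITP,

where the activation a(t) occupies a **fixed 0.2 s systole regardless of
heart rate**, E_max is proportional to the effective gain (nominal gain 100
for a healthy LV, ≈20 for the failing one, modulated by the inotropic drive
up to a hard limit of 8 FGU — factor-of-gain units), and ITP is the
respiration-driven intrathoracic pressure (mean −4 mmHg), which lets early
diastolic LV pressure dip slightly below zero.

A homeostatic negative feedback (the sympathetic signal **Sy**, in FGU)
low-pass filters aortic pressure into MAoP and drives three effector limbs —
heart rate, biventricular contractility, venous tone (unstressed-volume
reduction, displayed as CVV) — each with its own on/off switch and clamp
override. Reflex syncope variants are modelled as clamps: (a) HR 120/min,
Sy 1 FGU; (b) HR 120, Sy 0.5; (c) HR 45, Sy 0.5; (d) HR 45, Sy 1.5.

The built-in five-phase protocol (`protocol_a` … `protocol_d`, 550 s,
RK4 at 1 ms): settle-in → sedentary baseline → LV gain 100→20 at 70.5 s →
severe AVS (0.8 U) at 110.5 s → exercise (peripheral resistance halved,
MAoP setpoint reset) at 150.5 s → failure of homeostasis (syncope variant
clamps) at 240.5 s.

## Worked example

```r
library(hemocirc)

tr <- run_scenario("protocol_a")          # 550 s at 1 ms, < 1 s wall time
beat_metrics(tr, window = c(68.7, 69.3))  # the baseline sedentary beat
#>   EDVLV ESVLV  SVLV   EF max_LVP peak_gradient   MAoP    HR      CO
#> 1   140 51.82 88.18 0.63  129.84         23.14 108.52 77.18 6806.29
```

The baseline heart fills to an end-diastolic volume (EDVLV) of 140 mL,
ejects a stroke volume (SVLV) of 88 mL — an ejection fraction (EF) of 63% —
at 77 beats/min, i.e. a cardiac output of 6.8 L/min; the transvalvular
gradient is small because there is no stenosis yet.

`checkpoint_report()` evaluates every per-phase reference value on one run:

```r
checkpoint_report(tr)
#>             metric             phase        window simulated reference_value within_tolerance
#>               SVLV          baseline   68.7-69.3 s     88.18              87             TRUE
#>             EF_pct          baseline   68.7-69.3 s     62.99              63             TRUE
#>  min_diastolic_LVP          baseline   68.7-69.3 s     -0.53               0             TRUE
#>             EF_pct low_contractility 103.7-104.3 s     30.80              30             TRUE
#>      peak_gradient               avs 148.7-149.3 s     51.89              50             TRUE
#>            max_LVP               avs 148.7-149.3 s    155.27             170             TRUE
#>      peak_gradient          exercise 233.7-234.3 s     77.87              70             TRUE
#>               SVLV          exercise 233.7-234.3 s     98.88             107             TRUE
#>  ...                                                                                     TRUE
```

P-V loop analysis of any beat:

```r
cb <- cycle_boundaries(tr)
loop <- pv_loop(tr, cb[which(cb$t_start <= 69 & cb$t_end > 69), ])
loop_area(loop)    # stroke work, mmHg·mL
#> [1] 10765.7
```

A command-line front end ships in `inst/exec/cardiosim`
(`simulate`, `analyze`, `checkpoints` subcommands over CSV/JSON files).

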