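# Normative reference (mean, sd) for 3 x 3 mm fractal-ratio OCTA metrics,
# healthy adults aged 20-67. Device- and population-specific: replace with
# your own cohort's values for clinical use.
SCP:
  faz_area_mm2: {mean: 0.42, sd: 0.01}
  small_spacing_pct: {mean: 36.97, sd: 0.32}
  large_spacing_pct: {mean: 14.85, sd: 0.46}
  vessel_density_pct: {mean: 48.17, sd: 0.69}
DCP:
  faz_area_mm2: {mean: 0.42, sd: 0.01}
  small_spacing_pct: {mean: 34.03, sd: 0.39}
  large_spacing_pct: {mean: 12.19, sd: 0.33}
  vessel_density_pct: {mean: 53.77, sd: 0.64}
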