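# Taste detection thresholds (mg/100 g) and umami potency coefficients
# relative to MSG, the standard inputs of TAV and EUC scoring.
thresholds:
  Glu: {class: umami, threshold_mg_per_100g: 30}
  # Asp: sensory threshold compilations disagree (10 vs 100 mg/100 g). The
  # shipped default is 100, the value consistent with the published TAV and
  # EUC tables of the bundled reference dataset; swap in the commented
  # alternative to follow the 10 mg/100 g lists.
  Asp: {class: umami, threshold_mg_per_100g: 100}
  # Asp: {class: umami, threshold_mg_per_100g: 10}
  Ala: {class: sweet, threshold_mg_per_100g: 6}
  Gly: {class: sweet, threshold_mg_per_100g: 13}
  Thr: {class: sweet, threshold_mg_per_100g: 26}
  Ser: {class: sweet, threshold_mg_per_100g: 15}
  Arg: {class: bitter, threshold_mg_per_100g: 50}
  His: {class: bitter, threshold_mg_per_100g: 20}
  Val: {class: bitter, threshold_mg_per_100g: 15}
  Lys: {class: unflavored, threshold_mg_per_100g: 5}
  Pro: {class: unflavored, threshold_mg_per_100g: 30}
  Tau: {class: unflavored}   # tasteless per se; appears in composition plots only
  GMP: {class: nucleotide, threshold_mg_per_100g: 12.5}
  AMP: {class: nucleotide, threshold_mg_per_100g: 50}
  IMP: {class: nucleotide}   # potency established, detection threshold not
potencies:
  amino: {Glu: 1.000, Asp: 0.077}
  nucleotide: {AMP: 0.18, IMP: 1.0, GMP: 2.3}
  synergy_constant: 1218
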