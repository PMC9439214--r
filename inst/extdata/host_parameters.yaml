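hosts:
  sugar_beet:
    host: Sugar beet
    fecundity:
      r_m: 216.982
      t_max: 30.558
      k: 7.182
    aging:
      a: -4.7
      b: 4.506e-04
      c: -3.837e-05
      sigma: 1.0
    schedule:
      alpha: 0.501
      beta: 1.957
    survival:
      gamma: 1.042
      delta: -5.083
      parameterization: slope_multiplier
    note: Fitted parameter bundle shipped with the package (baseline host).
  erodium_cicutarium:
    host: Erodium cicutarium
    fecundity:
      r_m: 24.872
      t_max: 30.558
      k: 7.182
    aging:
      a: -4.7
      b: 4.506e-04
      c: -3.837e-05
      sigma: 1.108
    schedule:
      alpha: 0.501
      beta: 1.957
    survival:
      gamma: 1.042
      delta: -5.083
      parameterization: slope_multiplier
    note: Fitted parameter bundle shipped with the package.
  kochia_scoparia:
    host: Kochia scoparia
    fecundity:
      r_m: 133.05
      t_max: 30.558
      k: 7.182
    aging:
      a: -4.7
      b: 4.506e-04
      c: -3.837e-05
      sigma: 0.7
    schedule:
      alpha: 0.501
      beta: 1.957
    survival:
      gamma: 1.042
      delta: -5.083
      parameterization: slope_multiplier
    note: Fitted parameter bundle shipped with the package.
  plantago_ovata:
    host: Plantago ovata
    fecundity:
      r_m: 103.146
      t_max: 30.558
      k: 7.182
    aging:
      a: -4.7
      b: 4.506e-04
      c: -3.837e-05
      sigma: 0.796
    schedule:
      alpha: 0.501
      beta: 1.957
    survival:
      gamma: 1.042
      delta: -5.083
      parameterization: slope_multiplier
    note: Fitted parameter bundle shipped with the package.
  salsola_tragus:
    host: Salsola tragus
    fecundity:
      r_m: 28.61
      t_max: 30.558
      k: 7.182
    aging:
      a: -4.7
      b: 4.506e-04
      c: -3.837e-05
      sigma: 0.904
    schedule:
      alpha: 0.501
      beta: 1.957
    survival:
      gamma: 1.042
      delta: -5.083
      parameterization: slope_multiplier
    note: Fitted parameter bundle shipped with the package.
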