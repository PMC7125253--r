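# Final-model population parameter sets for the continuous-infusion 5FU PKPD
# model, in package units (mg, L, h, 1e9/L; slope in L/mg; theta_bsa in 1/m2).
# Two columns are shipped: the direct NONMEM point estimates and the medians
# of a 1000-replicate nonparametric bootstrap. The two differ slightly
# (e.g. CL 256 vs 249 L/h); the bootstrap column is the package default.
# iiv_cv entries are interindividual variabilities expressed as %CV of a
# log-normal distribution; loaders convert to variances via
# omega2 = log(1 + (cv/100)^2). sigma2 entries are proportional
# residual-error variances.
columns:
  bootstrap:
    theta:
      CL: 249.0        # 5FU total clearance, L/h
      Vc: 5.56         # 5FU central volume, L
      Vp: 28.5         # 5FU peripheral volume, L
      Q: 14.8          # intercompartmental clearance, L/h
      CLm: 121.0       # 5FUH2 clearance, L/h
      Vm: 96.7         # 5FUH2 volume, L
      CIRC0: 6.86      # baseline leukocyte count, 1e9/L
      MTT: 281.0       # mean transit time, h
      slope_mono: 1.17 # drug-effect slope, monotherapy, L/mg
      slope_comb: 2.82 # drug-effect slope, cisplatin combination, L/mg
      theta_bsa: 0.77  # fractional clearance change per m2 from reference BSA
    iiv_cv:
      CL: 23.0
      Vc: 145.0
      CLm: 28.9
      Vm: 59.6
      CIRC0: 16.4
    sigma2:
      prop_5fu: 0.32
      prop_5fuh2: 0.14
      prop_wbc: 0.08
  nonmem:
    theta:
      CL: 256.0
      Vc: 5.85
      Vp: 24.0
      Q: 17.3
      CLm: 124.0
      Vm: 100.0
      CIRC0: 7.16
      MTT: 261.0
      slope_mono: 1.31
      slope_comb: 2.10
      theta_bsa: 0.71
    iiv_cv:
      CL: 24.9
      Vc: 130.0
      CLm: 30.5
      Vm: 58.9
      CIRC0: 16.8
    sigma2:
      prop_5fu: 0.36
      prop_5fuh2: 0.14
      prop_wbc: 0.08
fixed:
  Fm: 0.85        # fraction of 5FU converted to 5FUH2 (fixed a priori)
  gamma: 0.17     # feedback exponent (fixed; unstable when estimated)
  n_transit: 3    # transit compartments in the maturation chain
  bsa_ref: 1.95   # reference (cohort median) BSA, m2
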