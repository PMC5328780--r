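neuron:
  C_cpg: 21.0
  gL_cpg: 2.8
  EL_cpg: -65.0
  gP: 10.0
  EP: 50.0
  th_m: -40.0
  sg_m: 6.0
  th_h: -62.0
  sg_h: 3.0
  tauh0: 1620.0
  sg_th: 5.0
  th_t: -30.0
  C_pas: 10.0
  gL_pas: 1.0
  EL_pas: -60.0
  th_s: -43.0
  sg_s: 1.0
  E_inh: -80.0
  E_exc: 0.0
  V_sanity: 200.0
network:
  g_cc: 1.5
  g_cpg_in: 0.8
  g_in_tone: 1.5
  g_in_mn: 4.0
  g_MN: 1.0
muscle:
  tau_act: 20.0
  gain_alpha: 0.56
  gain_beta: 0.55
  gain_gamma: 0.3
sensory:
  tau_p: 150.0
  g_sn: 3.0
  g_snl_lev: 0.05
  g_snl_dep: 0.25
  g_snt_dep: 2.5
  g_snt_lev: 0.25
  g_gate: 2.0
  beta_pr_th: 33.0
  beta_ef_th: 45.0
  hyst: 1.0
  alpha_pro_th: 36.0
  alpha_ret_th: 120.0
modes:
  tetrapod:
    g_app:
      g_app1: 0.05
      g_app2: 0.05
      g_app3: -0.76
      g_app4: 0.25
      g_app5: 0.05
      g_app6: 0.05
      g_app7: 0.05
      g_app8: 0.05
      g_app9: 0.35
      g_app10: 0.44
      g_app11: 0.05
      g_app12: 0.05
      g_app13: 0.05
      g_app14: 0.05
      g_app15: 0.35
      g_app16: 0.4
      g_app17: 0.05
      g_app18: 0.05
    intersegmental:
      g_inh3: 5.0
      g_inh9: 2.0
      theta: 45.0
      slope: 1.5
      E: -80.0
      dgate: 0.0
  tripod:
    g_app:
      g_app1: 0.05
      g_app2: 0.05
      g_app3: 2.2
      g_app4: 1.55
      g_app5: 0.05
      g_app6: 0.05
      g_app7: 0.05
      g_app8: 0.05
      g_app9: 2.0
      g_app10: 1.48
      g_app11: 0.05
      g_app12: 0.05
      g_app13: 0.05
      g_app14: 0.05
      g_app15: 2.0
      g_app16: 1.42
      g_app17: 0.05
      g_app18: 0.05
    intersegmental:
      g_inh3: 2.0
      g_inh9: 2.0
      theta: 45.0
      slope: 1.5
      E: -80.0
      dgate: 0.0
g_d:
  g_d1: 0.9
  g_d2: 0.9
  g_d6: 0.9
  g_d5: 0.9
  g_d7: 0.9
  g_d8: 0.9
  g_d13: 0.9
  g_d14: 0.9
  g_d18: 0.9
  g_d17: 0.9
  g_d19: 0.9
  g_d20: 0.9
  g_d25: 0.9
  g_d26: 0.9
  g_d30: 0.9
  g_d29: 0.9
  g_d31: 0.9
  g_d32: 0.9
decoupling:
  strong_factor: 2.3
  ref_drive: 0.76
  gd_strong: 4.0
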