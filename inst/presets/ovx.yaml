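cm: 20.0
state_label: ovx
channels:
  NaT:
    gbar: 550.0
    erev: 50.0
    block: 0.0
    kin:
      vh_m: -34.0
      k_m: 5.0
      vh_h: -48.0
      k_h: 7.0
      tau_h_base: 0.6
      tau_h_amp: 8.0
  NaP:
    gbar: 0.3
    erev: 50.0
    block: 0.0
    kin:
      vh: -52.0
      k: 5.0
  A:
    gbar: 25.0
    erev: -90.0
    block: 0.0
    kin:
      vh_a: -35.0
      k_a: 9.0
      vh_b: -68.0
      k_b: 6.0
      tau_b: 80.0
  BK:
    gbar: 7.64
    erev: -90.0
    block: 0.0
    kin:
      vh: -5.0
      k: 11.0
      k_ca: 0.2185
  h:
    gbar: 0.35
    erev: -30.0
    block: 0.0
    kin:
      vh: -78.0
      k: 6.0
      tau: 800.0
  SK:
    gbar: 28.1
    erev: -90.0
    block: 0.0
    kin:
      k_ca: 0.3
      hill: 4.0
      tau: 25.0
  M:
    gbar: 0.5
    erev: -90.0
    block: 0.0
    kin:
      vh: -35.0
      k: 10.0
      tau: 120.0
  T:
    gbar: 0.66
    erev: 100.0
    block: 0.0
    kin:
      vh_m: -56.0
      k_m: 6.2
      vh_h: -70.0
      k_h: 5.5
      tau_m: 8.0
      tau_h: 400.0
      tau_h_floor: 0.03
  Ca:
    gbar: 2.1
    erev: 100.0
    block: 0.0
    kin:
      vh_m: -32.3
      k_m: 8.5
      vh_h: -48.9
      k_h: 6.3
      tau_m: 5.5
      tau_h: 25.0
      h_floor: 0.8
  TRPC5:
    gbar: 2.0
    erev: -7.0
    block: 0.0
    kin:
      k_ca: 0.5
      tau: 150.0
      ca_flux_frac: 0.15
      des_max: 0.55
      tau_des: 12000.0
  GIRK:
    gbar: 1.2
    erev: -90.0
    block: 0.0
    kin:
      a0: 0.05
      vh_rect: -30.0
      k_rect: 20.0
      pip2_frac: 0.85
  leak:
    gbar: 1.3
    erev: -70.0
    block: 0.0
    kin: []
calcium:
  kd: 4.33e-05
  tau_d: 120.0
  kb: 2.2e-06
  tau_b: 2000.0
  ca0: 0.1
  ca0_d: 0.02
  k_cdi: 0.2
drive:
  tau_nkb_on: 100.0
  tau_nkb_off: 8000.0
  tau_dyn_on: 500.0
  tau_dyn_off: 8000.0
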