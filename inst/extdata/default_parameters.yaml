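parameters:
  kbar_inf1:
    value: 7.0e-17
    units: M/s
    source: calibrated
  k_inf2:
    value: 8.0e-09
    units: 1/s
    source: calibrated
  k_inf3:
    value: 8.0e-09
    units: 1/s
    source: calibrated
  k_inf4:
    value: 5.0
    units: 1/(M s)
    source: calibrated
  kbar_inf5:
    value: 1.0e-08
    units: 1/s
    source: calibrated
  k_inf6:
    value: 4.0e-08
    units: 1/s
    source: calibrated
  k_inf7:
    value: 2.0e-08
    units: 1/s
    source: calibrated
  k_inf8:
    value: 3.0e-09
    units: 1/s
    source: calibrated
  k_inf9:
    value: 8.0e-09
    units: 1/s
    source: calibrated
  k_inf10:
    value: 1.0e-08
    units: 1/s
    source: calibrated
  k_inf11:
    value: 10.0
    units: 1/(M s)
    source: calibrated
  k_inf12:
    value: 3.0e-08
    units: 1/s
    source: calibrated
  k_inh1a:
    value: 300.0
    units: 1/(M s)
    source: calibrated
  k_inh1b:
    value: 0.001
    units: 1/s
    source: calibrated
  k_inh2:
    value: 0.01
    units: 1/s
    source: calibrated
  k_inh3:
    value: 1.0e-12
    units: M/s
    source: calibrated
  k_inh4:
    value: 1.0e-05
    units: 1/s
    source: calibrated
  k_inh5:
    value: 0.0001
    units: 1/s
    source: calibrated
  k_inh6:
    value: 0.1
    units: 1/s
    source: calibrated
  k_inh7:
    value: 1.0e-05
    units: 1/s
    source: calibrated
  k_inh8:
    value: 0.01
    units: 1/s
    source: calibrated
  k_inh9:
    value: 2000000.0
    units: 1/(M s)
    source: calibrated
  k_inh10:
    value: 0.001
    units: 1/s
    source: calibrated
  k_inh11:
    value: 9.999999999999999e-12
    units: M/s
    source: calibrated
  k_inh12:
    value: 1.0e-05
    units: 1/s
    source: calibrated
  k_inh13:
    value: 1.0e-05
    units: 1/s
    source: calibrated
  k_inh14:
    value: 0.0001
    units: 1/s
    source: calibrated
  k_sma1:
    value: 3.0e-17
    units: M/s
    source: calibrated
  k_sma2:
    value: 1.0e-07
    units: 1/s
    source: calibrated
  k_sma3:
    value: 10000000.0
    units: 1/(M s)
    source: calibrated
  k_sma4:
    value: 0.0001
    units: 1/s
    source: calibrated
  k_sma5:
    value: 1.0e-05
    units: 1/s
    source: calibrated
  k_sma6:
    value: 2.0e-05
    units: 1/s
    source: calibrated
  k_sma7:
    value: 1.0e-13
    units: M/s
    source: calibrated
  k_sma8:
    value: 1.0e-13
    units: M/s
    source: calibrated
  k_sma9:
    value: 1.0e-06
    units: 1/s
    source: calibrated
  k_sma10:
    value: 1.0e-07
    units: 1/s
    source: calibrated
  k_sma11:
    value: 10000000.0
    units: 1/(M s)
    source: calibrated
  k_sma12:
    value: 7000000.0
    units: 1/(M s)
    source: calibrated
  k_sma13:
    value: 0.0
    units: 1/s
    source: calibrated
  k_sma14:
    value: 0.0
    units: 1/s
    source: calibrated
  k_sma15:
    value: 2.0e-06
    units: 1/s
    source: calibrated
  k_sma16:
    value: 2.0e-06
    units: 1/s
    source: calibrated
  k_sma17:
    value: 0.0001
    units: 1/s
    source: calibrated
  k_sma18:
    value: 0.0001
    units: 1/s
    source: calibrated
  k_sma19:
    value: 1.0e-05
    units: 1/s
    source: calibrated
  k_sma20:
    value: 1.0e-05
    units: 1/s
    source: calibrated
  k_sma21:
    value: 1.0e-06
    units: 1/s
    source: calibrated
  k_sma22:
    value: 1.0e-07
    units: 1/s
    source: calibrated
  k_sma23:
    value: 1.0e-06
    units: 1/s
    source: calibrated
  k_sma24:
    value: 1.0e-06
    units: 1/s
    source: calibrated
  k_sma25:
    value: 1.0e-06
    units: 1/s
    source: calibrated
  k_sma28:
    value: 1.0e-06
    units: 1/s
    source: calibrated
  k_sma29:
    value: 1.0e-06
    units: 1/s
    source: calibrated
  k_sma30:
    value: 5.0
    units: 1/(M s)
    source: calibrated
  k_sma31:
    value: 5.0
    units: 1/(M s)
    source: calibrated
  k_sma32:
    value: 1.0e-08
    units: 1/s
    source: calibrated
  k_sma33:
    value: 1.0e-08
    units: 1/s
    source: calibrated
  k_sma34:
    value: 1.0e-06
    units: 1/s
    source: calibrated
  k_sma35:
    value: 1.0e-06
    units: 1/s
    source: calibrated
  k_sma36:
    value: 1.0e-06
    units: 1/s
    source: calibrated
  k_sma37:
    value: 1.0e-06
    units: 1/s
    source: calibrated
  k_sma38:
    value: 1.0e-06
    units: 1/s
    source: calibrated
  k_sma39:
    value: 1.0e-08
    units: 1/s
    source: calibrated
  gamma:
    value: 25.549893340000001
    units: Agatston/(nodules/well)
    source: calibrated
  k_c:
    value: 1.0e-05
    units: nodules/well/(M s)
    source: calibrated
  xi:
    value: 0.15
    units: '1'
    source: literature
  a0:
    value: 44350.0
    units: '1'
    source: literature
  a1:
    value: 6.404
    units: '1'
    source: literature
  b0:
    value: 1.5e-10
    units: M/s
    source: calibrated
  b1:
    value: 0.7
    units: Pa
    source: calibrated
  k_td:
    value: 0.006
    units: 1/Agatston
    source: literature
  tau_ref:
    value: 2.0
    units: Pa
    source: literature
tissue:
  S:
    value: 12.0
    units: cm^2
    source: literature
  S_vic:
    value: 6.0
    units: cm^2
    source: literature
  V_vec:
    value: 2.0e-12
    units: L
    source: literature
  rho_vec:
    value: 10000.0
    units: cells/cm^2
    source: literature
  rho_vic:
    value: 50000.0
    units: cells/cm^2
    source: literature
  alpha:
    value: 5.7e-06
    units: cells/g
    source: literature
initial:
  LDL:
    value: 0.0
    units: M
  oxLDL:
    value: 0.0
    units: M
  mono:
    value: 0.0
    units: M
  macro:
    value: 0.0
    units: M
  foam:
    value: 0.0
    units: M
  TGFb_lat:
    value: 0.0
    units: M
  TGFb_act:
    value: 0.0
    units: M
  'NO':
    value: 0.0
    units: M
  sGC:
    value: 1.0e-07
    units: M
  NOsGC:
    value: 0.0
    units: M
  cGMP:
    value: 0.0
    units: M
  PKG:
    value: 1.0e-06
    units: M
  PKGa:
    value: 0.0
    units: M
  R:
    value: 3.0e-10
    units: M
  RC:
    value: 0.0
    units: M
  S2c:
    value: 1.0e-07
    units: M
  S3c:
    value: 1.0e-07
    units: M
  pS2c:
    value: 0.0
    units: M
  pS3c:
    value: 0.0
    units: M
  S2n:
    value: 0.0
    units: M
  S3n:
    value: 0.0
    units: M
  pS2n:
    value: 0.0
    units: M
  pS3n:
    value: 0.0
    units: M
  pS3i:
    value: 0.0
    units: M
  Ca:
    value: 0.0
    units: Agatston
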