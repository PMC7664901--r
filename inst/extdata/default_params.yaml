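# Default parameterization of the seven-state actomyosin cross-bridge cycle.
#
# Rate constants are of the magnitudes established for fast skeletal myosin II
# by biochemical solution kinetics and single-molecule mechanics near room
# temperature; free-energy levels are constructed so one full cycle dissipates
# exactly dG_ATP = 25 kBT. Stiffness 2.8 pN/nm and the nonlinear (buckling)
# alternative follow single-molecule optical-trap estimates (Kaya & Higuchi).
params:
  kBT: 4.0              # pN nm (~ 290 K)
  ks: 2.8               # pN/nm, cross-bridge stiffness
  dG_ATP: 25.0          # kBT, free energy of MgATP turnover
  d: 36.0               # nm, actin target-zone repeat
  sites_per_zone: 1     # 1 or 3 binding sites per target zone
  site_sep: 5.5         # nm, actin monomer rise along one strand
  x1: 8.0               # nm, AMDP_PP free-energy minimum
  x11: 7.5              # nm, AMDP_PiR / AMD_L minimum (x1 - 0.5)
  x2: 1.0               # nm, AMD_H minimum
  elasticity: linear    # linear | nonlinear
  buckling_w: 2.0       # nm, compressive buckling length (nonlinear mode)
  attach_reach: 2.0     # nm, Gaussian s.d. of the head's axial reach
  rate_cap: 1.0e+6       # 1/s, maximum transition rate
states:                 # basal (chemical) free-energy levels, kBT
  - {state: MT,       attached: no,  xmin: .na, g: 25.0}   # myosin.ATP
  - {state: MDP,      attached: no,  xmin: .na, g: 23.5}   # myosin.ADP.Pi
  - {state: AMDP_PP,  attached: yes, xmin: x1,  g: 21.5}   # pre-power-stroke
  - {state: AMDP_PiR, attached: yes, xmin: x11, g: 19.5}   # Pi-release
  - {state: AMD_L,    attached: yes, xmin: x11, g: 17.0}   # low-force bound
  - {state: AMD_H,    attached: yes, xmin: x2,  g: 4.0}    # high-force bound
  - {state: AM,       attached: yes, xmin: zero, g: 0.0}   # rigor
transitions:
  # k0 is realized at xref; split = fraction of the strain dependence on the
  # forward rate (detailed balance fixes the ratio at every strain).
  - {from: MT,       to: MDP,      type: detached, k0: 100,  xref: .na, split: 1.0, reversible: yes}  # hydrolysis
  - {from: MDP,      to: AMDP_PP,  type: attach,   k0: 200,  xref: x1,  split: 0.5, reversible: yes}  # attachment
  - {from: AMDP_PP,  to: AMDP_PiR, type: stroke,   k0: 1000, xref: x1,  split: 1.0, reversible: yes}  # first sub-stroke
  - {from: AMDP_PiR, to: AMD_L,    type: stroke,   k0: 1000, xref: x11, split: 1.0, reversible: yes}  # Pi release
  - {from: AMD_L,    to: AMD_H,    type: stroke,   k0: 50,   xref: x11, split: 1.0, reversible: yes}  # main power stroke
  - {from: AMD_H,    to: AM,       type: stroke,   k0: 1500, xref: x2,  split: 1.0, reversible: yes}  # ADP release
  - {from: AM,       to: MT,       type: irrev,    k0: 3000, xref: .na, split: .na, reversible: no}   # ATP-induced detachment (mM MgATP)
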