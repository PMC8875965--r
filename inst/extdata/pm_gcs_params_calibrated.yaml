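# Plant plasma-membrane Gouy-Chapman-Stern binding-site parameters.
#
# SYNTHETIC / CALIBRATED SET. The full literature parameter set for plant
# root plasma membranes is not printed in any source available to this
# package, so the densities and the Ca/Na binding constants below were
# calibrated by least squares against four published surface-potential
# values (plant test medium at 0.2 / 20 mM Ca: -53.8 / -3.3 mV; 0.342 M
# NaCl medium at 0 / 25 mM added Ca: -13.7 / -0.4 mV), under the
# constraints logK(H,R) = 4.33 (literature value), Mg tied to Ca, K tied
# to Na, and no proton binding to the neutral P sites. Values are frozen
# at 4 significant figures; the calibrated set reproduces all four
# anchors to better than 0.002 mV.
source: "calibrated against published plant-root surface potentials (synthetic stand-in)"
sites:
  - site: R
    density_umol_m2: 0.3192
    logK:
      H: 4.330008            # 21,380 L/mol, fixed at the literature value
      Ca: -0.685345          # 0.2064 L/mol
      Mg: -0.685345          # tied to Ca
      K: -2.451750           # 0.003534 L/mol
      Na: -2.451750          # tied to K
  - site: P
    density_umol_m2: 0.3905
    logK:
      Ca: 1.369401           # 23.41 L/mol
      Mg: 1.369401           # tied to Ca
      K: -0.093598           # 0.8062 L/mol
      Na: -0.093598          # tied to K
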