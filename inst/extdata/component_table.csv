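# Default C1s component table: one Gaussian (or Gaussian-Lorentzian) line per
# carbon environment. Binding energies anchored to standard C1s shift tables
# and the CHx = 285.0 eV calibration convention; FWHM 1.1 eV for all
# components. Columns: environment, binding energy (eV), FWHM (eV),
# line shape ("gaussian" or "gl"), Lorentzian mix fraction (used by "gl").
environment,be_eV,fwhm_eV,shape,gl_mix
C=C,284.7,1.1,gaussian,0
CHx,285.0,1.1,gaussian,0
C-S,285.4,1.1,gaussian,0
C-C(O)O,285.5,1.1,gaussian,0
C=C-N,285.9,1.1,gaussian,0
C-N,286.2,1.1,gaussian,0
C-OH,286.5,1.1,gaussian,0
C=N,286.9,1.1,gaussian,0
N-C=O,288.1,1.1,gaussian,0
COOH,289.0,1.1,gaussian,0
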