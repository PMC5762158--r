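Place deposited coordinate files here to enable the actomyosin
state-comparison reproductions in the test suite:

  6BNP.pdb  rigor-state actomyosin VI (HR model)
  6BNQ.pdb  ADP-state actomyosin VI (HR model)
  6BNO.pdb  actin alone (HR model)
  4PFO.pdb  Pi-release-state myosin VI crystal structure

e.g. from https://files.rcsb.org/download/6BNP.pdb

Without these files the comparison machinery is still fully exercised on
synthetic models; only the checks against the published numeric values
stay unsatisfied.
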