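# DQ7/DQ8/DQ9 serotype rule over mature DQ beta-chain residues 45 and 57.
# Verification residues 74/84/85 are invariant across these three serotypes
# and are checked for equality only.
motif	serotype
ED	DQ7
EA	DQ7
GA	DQ8
GD	DQ9
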