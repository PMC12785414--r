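# Interstrand exit-region gates: two residue-range segments per region.
# Reg 1: S7A-bulge (139-145) x S10;  Reg 2: S7B (146-153) x S10
# Reg 3: S7A-bulge x S8;             Reg 4: S3 x S11
# Strand residue ranges for S3/S8/S10/S11 are editable defaults; they
# match the synthetic barrel template shipped with the package.
region segment chain start end
"Reg 1" 1 A 139 145
"Reg 1" 2 A 193 200
"Reg 2" 1 A 146 153
"Reg 2" 2 A 193 200
"Reg 3" 1 A 139 145
"Reg 3" 2 A 160 167
"Reg 4" 1 A 40 47
"Reg 4" 2 A 210 217
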