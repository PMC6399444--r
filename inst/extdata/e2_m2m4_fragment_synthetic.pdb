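REMARK   SYNTHETIC stand-in fragment, not crystallographic data.
REMARK   Gln108 (helix M2) and Thr316 (helix M4) of the SERCA1a E2 state,
REMARK   built from idealized residue geometry with the side-chain
REMARK   amide-to-hydroxyl separation set to the 0.65 nm value reported for
REMARK   the E2 crystal arrangement. Used to exercise the shipped atom map
REMARK   and crystal-reference distance machinery offline.
ATOM      1  N   GLN A 108       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  GLN A 108       1.460   0.000   0.000  1.00  0.00           C
ATOM      3  C   GLN A 108       2.000   1.400   0.000  1.00  0.00           C
ATOM      4  O   GLN A 108       1.300   2.400   0.000  1.00  0.00           O
ATOM      5  CB  GLN A 108       2.000  -0.800   1.200  1.00  0.00           C
ATOM      6  CG  GLN A 108       3.500  -0.900   1.300  1.00  0.00           C
ATOM      7  CD  GLN A 108       4.100  -1.800   2.300  1.00  0.00           C
ATOM      8  OE1 GLN A 108       3.500  -2.800   2.700  1.00  0.00           O
ATOM      9  NE2 GLN A 108       5.300  -1.500   2.800  1.00  0.00           N
ATOM     10  N   THR A 316      13.400   1.000   2.600  1.00  0.00           N
ATOM     11  CA  THR A 316      13.800  -0.200   3.300  1.00  0.00           C
ATOM     12  C   THR A 316      15.300  -0.300   3.300  1.00  0.00           C
ATOM     13  O   THR A 316      15.900   0.500   4.000  1.00  0.00           O
ATOM     14  CB  THR A 316      13.200  -1.500   2.800  1.00  0.00           C
ATOM     15  OG1 THR A 316      11.800  -1.500   2.800  1.00  0.00           O
ATOM     16  CG2 THR A 316      13.700  -2.700   3.600  1.00  0.00           C
TER
END
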