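HEADER    SYNTHETIC TOY STRUCTURE FOR B-FACTOR MAPPING EXAMPLES
REMARK    Coordinates are invented; residue numbering follows the
REMARK    galectin-3 CRD convention used by the demo titration fixture.
ATOM      1  N   HIS A 158       1.000   2.000   3.000  1.00 10.00           N
ATOM      2  CA  HIS A 158       2.000   2.500   3.500  1.00 10.00           C
ATOM      3  C   HIS A 158       3.000   3.000   4.000  1.00 10.00           C
ATOM      4  N   PHE A 159       4.000   3.500   4.500  1.00 12.00           N
ATOM      5  CA  PHE A 159       5.000   4.000   5.000  1.00 12.00           C
ATOM      6  N   ASN A 160       6.000   4.500   5.500  1.00 14.00           N
ATOM      7  CA  ASN A 160       7.000   5.000   6.000  1.00 14.00           C
ATOM      8  N   ASN A 174       8.000   5.500   6.500  1.00 16.00           N
ATOM      9  CA  ASN A 174       9.000   6.000   7.000  1.00 16.00           C
ATOM     10  N   THR A 175      10.000   6.500   7.500  1.00 18.00           N
ATOM     11  CA  THR A 175      11.000   7.000   8.000  1.00 18.00           C
TER      12      THR A 175
END
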