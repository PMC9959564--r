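# Nearest-neighbor thermodynamic parameters (Turner 2004 set)
# Units: dH kcal/mol, dG37 kcal/mol (dS derived as (dH - dG37)/310.15)
# STACK key O5I5/O3I3 means  5'-O5 I5-3' paired with 3'-O3 I3-5'
STACK
CC/GG   -13.40   -3.30
CG/GC   -10.60   -2.40
CG/GU    -5.60   -1.40
CU/GG   -12.10   -2.10
CA/GU   -10.40   -2.10
CU/GA   -10.50   -2.10
GC/CG   -14.90   -3.40
GG/CC   -13.40   -3.30
GG/CU    -8.30   -1.50
GU/CG   -12.60   -2.50
GA/CU   -12.40   -2.40
GU/CA   -11.40   -2.20
GC/UG   -12.60   -2.50
GG/UC   -12.10   -2.10
GG/UU   -13.50   -0.50
GU/UG   -14.60    1.30
GA/UU   -12.80   -1.30
GU/UA    -8.80   -1.40
UC/GG    -8.30   -1.50
UG/GC    -5.60   -1.40
UG/GU    -9.30    0.30
UU/GG   -13.50   -0.50
UA/GU    -7.00   -1.00
UU/GA    -3.20   -0.60
AC/UG   -11.40   -2.20
AG/UC   -10.50   -2.10
AG/UU    -3.20   -0.60
AU/UG    -8.80   -1.40
AA/UU    -6.80   -0.90
AU/UA    -9.40   -1.10
UC/AG   -12.40   -2.40
UG/AC   -10.40   -2.10
UG/AU    -7.00   -1.00
UU/AG   -12.80   -1.30
UA/AU    -7.70   -1.30
UU/AA    -6.80   -0.90
# loop initiation free energies at 37 C, by loop size (unpaired nt)
HAIRPIN
 3   5.40
 4   5.60
 5   5.70
 6   5.40
 7   6.00
 8   5.50
 9   6.40
10   6.50
11   6.60
12   6.70
13   6.80
14   6.90
15   6.90
16   7.00
17   7.10
18   7.10
19   7.20
20   7.20
21   7.30
22   7.30
23   7.40
24   7.40
25   7.50
26   7.50
27   7.50
28   7.60
29   7.60
30   7.70
BULGE
 1   3.80
 2   2.80
 3   3.20
 4   3.60
 5   4.00
 6   4.40
 7   4.60
 8   4.70
 9   4.80
10   4.90
11   5.00
12   5.10
13   5.20
14   5.30
15   5.40
16   5.40
17   5.50
18   5.50
19   5.60
20   5.70
21   5.70
22   5.80
23   5.80
24   5.80
25   5.90
26   5.90
27   6.00
28   6.00
29   6.00
30   6.10
# INTERNAL keyed by total unpaired size (both sides summed)
INTERNAL
 2   1.00
 3   1.00
 4   1.10
 5   2.00
 6   2.00
 7   2.10
 8   2.30
 9   2.40
10   2.50
11   2.60
12   2.70
13   2.80
14   2.90
15   2.90
16   3.00
17   3.10
18   3.10
19   3.20
20   3.30
21   3.30
22   3.40
23   3.40
24   3.50
25   3.50
26   3.50
27   3.60
28   3.60
29   3.70
30   3.70
# MULTILOOP: offset a, per-branch b, per-unpaired-nt c (kcal/mol, 37 C)
MULTILOOP  9.30  -0.90  0.00
# log-extrapolation beyond the largest tabulated size:
# G(n) = G(nmax) + 1.75 * kB * T * ln(n/nmax)
MAXLOOP 30
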