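H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
R PMID:7108955
A Kyte, J. and Doolittle, R.F.
T A simple method for displaying the hydropathic character of a protein
J J. Mol. Biol. 157, 105-132 (1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
     3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H SYNBAS0001
D Basic-residue propensity (synthetic scale for this package)
R
A acepred authors
T Synthetic fixture scale
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.20    0.90    0.25    0.10    0.15    0.30    0.10    0.70    0.50    0.15
    0.15    1.00    0.20    0.10    0.25    0.20    0.25    0.20    0.30    0.15
//
H SYNACD0001
D Acidic/hydroxyl propensity (synthetic scale for this package)
R
A acepred authors
T Synthetic fixture scale
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.30    0.10    0.40    0.85    0.20    0.45    0.95    0.25    0.30    0.15
    0.90    0.10    0.20    0.15    0.35    0.80    0.50    0.20    0.35    0.15
//
H SYNCHG0001
D Net side-chain charge at pH 7 (synthetic convention)
R
A acepred authors
T Synthetic fixture scale
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.0     1.0     0.0    -1.0     0.0     0.0    -1.0     0.0     0.5     0.0
     0.0     1.0     0.0     0.0     0.0     0.0     0.0     0.0     0.0     0.0
//
H SYNVOL0001
D Relative residue volume (synthetic scale for this package)
R
A acepred authors
T Synthetic fixture scale
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.17    0.66    0.36    0.35    0.31    0.47    0.46    0.00    0.56    0.52
    0.52    0.59    0.55    0.70    0.40    0.24    0.35    1.00    0.80    0.42
//
H SYNFLX0001
D Backbone flexibility (synthetic scale for this package)
R
A acepred authors
T Synthetic fixture scale
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.36    0.53    0.46    0.51    0.35    0.49    0.50    0.54    0.32    0.46
    0.37    0.47    0.30    0.31    0.51    0.51    0.44    0.31    0.42    0.39
//
H SYNNAX0001
D Scale with missing entries (synthetic; exercises the NA-to-0 rule)
R
A acepred authors
T Synthetic fixture scale
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.50      NA    0.40    0.30    0.20    0.60    0.10    0.80    0.90    0.70
    0.30    0.20      NA    0.60    0.40    0.10    0.50    0.70    0.20    0.90
//
H SYNCST0001
D Constant scale (synthetic; degenerate, uninformative by design)
R
A acepred authors
T Synthetic fixture scale
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.00    1.00    1.00    1.00    1.00    1.00    1.00    1.00    1.00    1.00
    1.00    1.00    1.00    1.00    1.00    1.00    1.00    1.00    1.00    1.00
//
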