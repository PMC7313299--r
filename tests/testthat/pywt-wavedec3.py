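"""Reference 3-level DWT (PyWavelets, periodization mode) for oracle tests.

Usage: python pywt-wavedec3.py <in.tsv> <out.tsv> <order>
Input rows are signals; output rows are the concatenated [a3, d3, d2, d1]
coefficient vectors.
"""
import sys
import warnings

import numpy as np
import pywt

warnings.filterwarnings("ignore")

x = np.loadtxt(sys.argv[1], ndmin=2)
order = int(sys.argv[3])
rows = []
for row in x:
    coeffs = pywt.wavedec(row, "db%d" % order, mode="periodization", level=3)
    rows.append(np.concatenate(coeffs))
np.savetxt(sys.argv[2], np.array(rows), fmt="%.17g")
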