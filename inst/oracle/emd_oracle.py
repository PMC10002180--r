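"""Minimal reference EMD used only as an independent cross-check in tests.

Deliberately simple and structurally different from the package's
implementation: scipy extrema/splines, a fixed number of sifting passes,
no boundary mirroring. Reads a one-column CSV of samples from argv[1] and
writes the IMF matrix (one column per IMF) as CSV to stdout.
"""
import sys

import numpy as np
from scipy.interpolate import CubicSpline
from scipy.signal import argrelextrema

N_SIFTS = 10
MAX_IMFS = 8


def mean_envelope(x):
    t = np.arange(len(x))
    mx = argrelextrema(x, np.greater)[0]
    mn = argrelextrema(x, np.less)[0]
    if len(mx) < 2 or len(mn) < 2:
        return None
    upper = CubicSpline(mx, x[mx], bc_type="natural")(t)
    lower = CubicSpline(mn, x[mn], bc_type="natural")(t)
    return (upper + lower) / 2


def emd(x):
    imfs = []
    resid = x.astype(float)
    for _ in range(MAX_IMFS):
        h = resid.copy()
        for _ in range(N_SIFTS):
            m = mean_envelope(h)
            if m is None:
                break
            h = h - m
        if mean_envelope(resid) is None:
            break
        imfs.append(h)
        resid = resid - h
    return np.column_stack(imfs) if imfs else np.empty((len(x), 0))


if __name__ == "__main__":
    x = np.loadtxt(sys.argv[1])
    np.savetxt(sys.stdout, emd(x), delimiter=",")
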