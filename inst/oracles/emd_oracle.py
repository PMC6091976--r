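#!/usr/bin/env python
"""Minimal reference empirical mode decomposition.

Independent cross-check for the package's EMD: classic sifting with cubic
spline envelopes through local extrema (two extrema mirrored about each
series end) and a Cauchy-type stop criterion. Reads a one-column CSV of
the series from argv[1], writes a CSV with one column per IMF plus the
residual to argv[2].

Usage: python emd_oracle.py in.csv out.csv [n_imf] [sd_tol]
"""
import sys

import numpy as np
from scipy.interpolate import CubicSpline


def local_extrema(x):
    d = np.diff(x)
    nz = np.nonzero(d)[0]
    if nz.size < 2:
        return np.array([], int), np.array([], int)
    s = np.sign(d[nz])
    chg = np.nonzero(s[1:] != s[:-1])[0]
    mx, mn = [], []
    for c in chg:
        left, right = nz[c], nz[c + 1]
        mid = (left + 1 + right) // 2
        (mx if s[c] > 0 else mn).append(mid)
    return np.array(mx, int), np.array(mn, int)


def envelope(x, idx, n):
    if idx.size == 0:
        return np.zeros(n)
    if idx.size == 1:
        return np.full(n, x[idx[0]])
    k = min(2, idx.size)
    pre = -idx[:k][::-1]
    post = 2 * (n - 1) - idx[-k:][::-1]
    xi = np.concatenate([pre, idx, post])
    yi = np.concatenate([x[idx[:k]][::-1], x[idx], x[idx[-k:]][::-1]])
    xi, ui = np.unique(xi, return_index=True)
    return CubicSpline(xi, yi[ui])(np.arange(n))


def is_imf(x):
    mx, mn = local_extrema(x)
    ne = mx.size + mn.size
    s = np.sign(x)
    s = s[s != 0]
    zc = int(np.sum(s[1:] != s[:-1]))
    return abs(ne - zc) <= 1


def sift(x, sd_tol, max_sift):
    h = x.copy()
    for _ in range(max_sift):
        mx, mn = local_extrema(h)
        if mx.size < 2 or mn.size < 2:
            break
        m = 0.5 * (envelope(h, mx, h.size) + envelope(h, mn, h.size))
        h_new = h - m
        sd = np.sum((h - h_new) ** 2) / max(np.sum(h ** 2), 1e-300)
        h = h_new
        if sd < sd_tol and is_imf(h):
            break
    return h


def emd(x, n_imf=6, sd_tol=0.2, max_sift=100):
    out = []
    resid = x.copy()
    for _ in range(n_imf):
        mx, mn = local_extrema(resid)
        if mx.size < 2 or mn.size < 2:
            break
        c = sift(resid, sd_tol, max_sift)
        out.append(c)
        resid = resid - c
    while len(out) < n_imf:
        out.append(np.zeros_like(x))
    return np.column_stack(out + [resid])


def main():
    x = np.loadtxt(sys.argv[1], delimiter=",")
    n_imf = int(sys.argv[3]) if len(sys.argv) > 3 else 6
    sd_tol = float(sys.argv[4]) if len(sys.argv) > 4 else 0.2
    np.savetxt(sys.argv[2], emd(x, n_imf, sd_tol), delimiter=",")


if __name__ == "__main__":
    main()
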