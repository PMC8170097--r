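"""Independent MFCC reference: same standard definition (pre-emphasis 0.97,
25 ms Hamming frames / 10 ms step at 16 kHz, 512-point power spectrum,
26-filter HTK-style mel bank, log energies, orthonormal DCT-II, first 14
coefficients), implemented from scratch with numpy/scipy.

Usage: python mfcc_oracle.py <signal.txt> <out.csv>
signal.txt: one amplitude per line, already at 16 kHz.
"""
import sys

import numpy as np
from scipy.fft import dct

RATE = 16000
FRAME = 400
STEP = 160
NFFT = 512
NFILT = 26
NCOEF = 14


def mel(f):
    return 2595.0 * np.log10(1.0 + f / 700.0)


def imel(m):
    return 700.0 * (10.0 ** (m / 2595.0) - 1.0)


def filterbank():
    pts = np.linspace(mel(0.0), mel(RATE / 2.0), NFILT + 2)
    bins = np.floor((NFFT + 1) * imel(pts) / RATE).astype(int)
    fb = np.zeros((NFILT, NFFT // 2 + 1))
    for m in range(NFILT):
        lo, mid, hi = bins[m], bins[m + 1], bins[m + 2]
        for k in range(lo, mid):
            fb[m, k] = (k - lo) / (mid - lo)
        for k in range(mid, hi):
            fb[m, k] = (hi - k) / (hi - mid)
        # the R construction includes both triangle endpoints; mirror the
        # definition exactly: ramps defined on closed intervals
        if mid > lo:
            fb[m, mid] = 1.0
    return fb


def main(sig_path, out_path):
    x = np.loadtxt(sig_path)
    x = np.append(x[0], x[1:] - 0.97 * x[:-1])
    n_frames = (len(x) - FRAME) // STEP + 1
    win = 0.54 - 0.46 * np.cos(2 * np.pi * np.arange(FRAME) / (FRAME - 1))
    fb = filterbank()
    out = np.zeros((n_frames, NCOEF))
    for i in range(n_frames):
        fr = x[i * STEP:i * STEP + FRAME] * win
        spec = np.abs(np.fft.rfft(fr, NFFT)) ** 2 / NFFT
        fe = np.log(np.maximum(fb @ spec, 1e-12))
        out[i] = dct(fe, type=2, norm="ortho")[:NCOEF]
    np.savetxt(out_path, out, delimiter=",", fmt="%.12e")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
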