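"""Convert between .npy arrays and raw little-endian float64 binaries.

Used by the R package to read/write NumPy traces without an R-side NPY
parser. Usage:
    npy_bridge.py tobin   in.npy  out.bin
    npy_bridge.py frombin in.bin  out.npy
"""
import sys

import numpy as np


def main(argv):
    if len(argv) != 4 or argv[1] not in {"tobin", "frombin"}:
        sys.stderr.write(__doc__)
        return 1
    cmd, src, dst = argv[1], argv[2], argv[3]
    if cmd == "tobin":
        arr = np.load(src)
        if arr.ndim != 1:
            sys.stderr.write("expected a 1-D array\n")
            return 1
        arr.astype("<f8").tofile(dst)
    else:
        arr = np.fromfile(src, dtype="<f8")
        np.save(dst, arr)
        # np.save appends .npy if missing; normalize
        import os
        if not os.path.exists(dst) and os.path.exists(dst + ".npy"):
            os.replace(dst + ".npy", dst)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
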