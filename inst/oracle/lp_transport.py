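"""Independent optimal-transport oracle.

Solves each 1-Wasserstein instance as an explicit linear program over the
transport polytope (uniform mass 1/n_A and 1/n_B on the sample points,
cost |a_i - b_j|) with scipy.optimize.linprog, and prints the optimal
costs. Input: a JSON file [{"a": [...], "b": [...]}, ...]; output: a JSON
list of distances on stdout.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def transport_lp(a, b):
    a = np.asarray(a, dtype=float)
    b = np.asarray(b, dtype=float)
    na, nb = len(a), len(b)
    cost = np.abs(a[:, None] - b[None, :]).ravel()
    A_eq = np.zeros((na + nb, na * nb))
    for i in range(na):
        A_eq[i, i * nb:(i + 1) * nb] = 1.0
    for j in range(nb):
        A_eq[na + j, j::nb] = 1.0
    b_eq = np.concatenate([np.full(na, 1.0 / na), np.full(nb, 1.0 / nb)])
    res = linprog(cost, A_eq=A_eq, b_eq=b_eq, bounds=(0, None),
                  method="highs")
    if not res.success:
        raise RuntimeError(f"LP failed: {res.message}")
    return float(res.fun)


def main():
    with open(sys.argv[1]) as fh:
        instances = json.load(fh)
    out = [transport_lp(inst["a"], inst["b"]) for inst in instances]
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
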