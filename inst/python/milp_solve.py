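#!/usr/bin/env python
"""Branch-and-bound backend for the quadqsar MILP solver contract.

Reads a JSON list of models (sparse triplet rows with two-sided bounds,
variable bounds, integrality flags, per-model time limit), solves each with
HiGHS via scipy.optimize.milp, and writes a JSON list of answers
{status, x, objective}. Statuses: feasible | infeasible | timeout | unbounded.
"""
import json
import sys

import numpy as np
import scipy.sparse as sp
from scipy.optimize import Bounds, LinearConstraint, milp

BIG = 1e29


def decode_inf(v):
    a = np.asarray(v, dtype=float)
    a[a >= BIG] = np.inf
    a[a <= -BIG] = -np.inf
    return a


def solve_one(m):
    n = int(m["n_var"])
    c = np.asarray(m["obj"], dtype=float)
    rlb = decode_inf(m["rlb"])
    rub = decode_inf(m["rub"])
    lb = decode_inf(m["lb"])
    ub = decode_inf(m["ub"])
    integrality = np.asarray(m["integrality"], dtype=int)
    n_row = rlb.shape[0]
    if n_row > 0:
        A = sp.csc_matrix(
            (
                np.asarray(m["A_x"], dtype=float),
                (
                    np.asarray(m["A_i"], dtype=int) - 1,
                    np.asarray(m["A_j"], dtype=int) - 1,
                ),
            ),
            shape=(n_row, n),
        )
        constraints = LinearConstraint(A, rlb, rub)
    else:
        constraints = ()
    res = milp(
        c,
        constraints=constraints,
        bounds=Bounds(lb, ub),
        integrality=integrality,
        options={"time_limit": float(m.get("time_limit", 300.0))},
    )
    if res.status == 0 or (res.status == 1 and res.x is not None):
        return {
            "status": "feasible",
            "x": [float(v) for v in res.x],
            "objective": float(res.fun),
        }
    if res.status == 1:
        return {"status": "timeout", "x": None, "objective": None}
    if res.status == 2:
        return {"status": "infeasible", "x": None, "objective": None}
    if res.status == 3:
        return {"status": "unbounded", "x": None, "objective": None}
    return {"status": "timeout", "x": None, "objective": None}


def main():
    infile, outfile = sys.argv[1], sys.argv[2]
    with open(infile) as fh:
        models = json.load(fh)
    answers = [solve_one(m) for m in models]
    out = {
        "status": [a["status"] for a in answers],
        "x": [a["x"] for a in answers],
        "objective": [a["objective"] for a in answers],
    }
    with open(outfile, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
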