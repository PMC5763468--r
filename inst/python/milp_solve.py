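"""Batch MILP solve via scipy's HiGHS backend.

Reads a JSON file holding a list of problems, solves each with
scipy.optimize.milp, writes a JSON list of results.

Problem fields (1-based indices, R convention):
  obj, integrality (0 cont / 1 int), lb, ub,
  a_row, a_col, a_val, n_con, c_lb, c_ub,
  time_limit (seconds, optional), mip_rel_gap (optional)
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def solve_one(p):
    c = np.asarray(p["obj"], dtype=float)
    n = c.size
    integrality = np.asarray(p["integrality"], dtype=int)
    lb = np.asarray(p["lb"], dtype=float)
    ub = np.asarray(p["ub"], dtype=float)
    n_con = int(p["n_con"])
    constraints = []
    if n_con > 0:
        a = sparse.csc_matrix(
            (
                np.asarray(p["a_val"], dtype=float),
                (
                    np.asarray(p["a_row"], dtype=int) - 1,
                    np.asarray(p["a_col"], dtype=int) - 1,
                ),
            ),
            shape=(n_con, n),
        )
        constraints.append(
            LinearConstraint(
                a,
                np.asarray(p["c_lb"], dtype=float),
                np.asarray(p["c_ub"], dtype=float),
            )
        )
    options = {"presolve": True}
    if p.get("time_limit") is not None:
        options["time_limit"] = float(p["time_limit"])
    # exact optima: HiGHS's default relative gap (1e-4) can return
    # slightly suboptimal incumbents, which breaks oracle comparisons
    options["mip_rel_gap"] = float(p.get("mip_rel_gap", 0.0))
    res = milp(
        c,
        constraints=constraints,
        integrality=integrality,
        bounds=Bounds(lb, ub),
        options=options,
    )
    return {
        "status": int(res.status),
        "message": str(res.message),
        "success": bool(res.success),
        "x": None if res.x is None else [float(v) for v in res.x],
        "fun": None if res.x is None else float(res.fun),
        "mip_gap": None if res.mip_gap is None else float(res.mip_gap),
    }


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    results = [solve_one(p) for p in problems]
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
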