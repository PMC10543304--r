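"""Mixed-integer linear programming backend.

Reads a problem description as JSON from argv[1], solves it with
scipy.optimize.milp (HiGHS) and writes a JSON result to argv[2].

Input schema (0-based indices):
  ncol            number of variables
  obj             objective coefficients (length ncol)
  maximize        bool
  row, col, val   sparse constraint matrix triplets
  lhs, rhs        per-row bounds (use +-1e30 for infinity)
  lb, ub          variable bounds
  integrality     per-variable 0/1 flags
  time_limit      seconds (optional)
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF = 1e29


def main():
    with open(sys.argv[1]) as fh:
        p = json.load(fh)

    ncol = int(p["ncol"])
    obj = np.atleast_1d(np.asarray(p["obj"], dtype=float))
    if p.get("maximize", False):
        obj = -obj

    lhs = np.atleast_1d(np.asarray(p["lhs"], dtype=float))
    rhs = np.atleast_1d(np.asarray(p["rhs"], dtype=float))
    lhs[lhs <= -INF] = -np.inf
    rhs[rhs >= INF] = np.inf
    nrow = len(lhs)
    A = sparse.csc_matrix(
        (np.atleast_1d(np.asarray(p["val"], dtype=float)),
         (np.atleast_1d(np.asarray(p["row"], dtype=int)),
          np.atleast_1d(np.asarray(p["col"], dtype=int)))),
        shape=(nrow, ncol))

    lb = np.atleast_1d(np.asarray(p["lb"], dtype=float))
    ub = np.atleast_1d(np.asarray(p["ub"], dtype=float))
    lb[lb <= -INF] = -np.inf
    ub[ub >= INF] = np.inf

    options = {}
    if p.get("time_limit") is not None:
        options["time_limit"] = float(p["time_limit"])

    res = milp(c=obj,
               constraints=LinearConstraint(A, lhs, rhs) if nrow else (),
               bounds=Bounds(lb, ub),
               integrality=np.atleast_1d(np.asarray(p["integrality"], dtype=int)),
               options=options)

    status = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
              3: "unbounded", 4: "error"}.get(res.status, "error")
    if status == "iteration_limit":
        status = "time_limit"
    fun = res.fun
    if fun is not None and p.get("maximize", False):
        fun = -fun
    out = {
        "status": status,
        "success": bool(res.success),
        "objective": fun,
        "x": None if res.x is None else [float(v) for v in res.x],
        "mip_gap": getattr(res, "mip_gap", None),
    }
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
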