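"""HiGHS MILP runner: reads a problem directory written by the R side,
solves with scipy.optimize.milp, writes result.json (+ x.bin incumbent).

Layout of the problem directory:
  problem.json  {nvar, ncon, nnz, time_limit, mip_rel_gap, verbose}
  obj.bin lb.bin ub.bin rlo.bin rhi.bin ax.bin   float64 little-endian
  intg.bin ai.bin aj.bin                          int32 little-endian
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def main(dirname):
    with open(f"{dirname}/problem.json") as fh:
        meta = json.load(fh)
    nvar, ncon, nnz = meta["nvar"], meta["ncon"], meta["nnz"]
    f8 = lambda name, n: np.fromfile(f"{dirname}/{name}", dtype="<f8", count=n)
    i4 = lambda name, n: np.fromfile(f"{dirname}/{name}", dtype="<i4", count=n)
    c = f8("obj.bin", nvar)
    lb, ub = f8("lb.bin", nvar), f8("ub.bin", nvar)
    integrality = i4("intg.bin", nvar)
    constraints = []
    if ncon > 0 and nnz > 0:
        A = sparse.csc_matrix(
            (f8("ax.bin", nnz), (i4("ai.bin", nnz), i4("aj.bin", nnz))),
            shape=(ncon, nvar))
        constraints = LinearConstraint(A, f8("rlo.bin", ncon), f8("rhi.bin", ncon))
    options = {"time_limit": float(meta["time_limit"]),
               "mip_rel_gap": float(meta["mip_rel_gap"]),
               "disp": bool(meta.get("verbose", False))}
    res = milp(c=c, constraints=constraints, integrality=integrality,
               bounds=Bounds(lb, ub), options=options)
    has_x = res.x is not None
    out = {"status": int(res.status), "message": str(res.message),
           "has_x": has_x,
           "fun": float(res.fun) if has_x else None,
           "bound": (float(res.mip_dual_bound)
                     if getattr(res, "mip_dual_bound", None) is not None else None),
           "gap": (float(res.mip_gap)
                   if getattr(res, "mip_gap", None) is not None else None)}
    if has_x:
        np.asarray(res.x, dtype="<f8").tofile(f"{dirname}/x.bin")
    with open(f"{dirname}/result.json", "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1])
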