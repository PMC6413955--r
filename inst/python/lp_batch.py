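"""Batch LP solver for the scfba R package.

Reads a JSON problem set (shared sparse equality matrix S with S v = 0,
base bounds, and a list of LPs differing in objective and bound overrides),
solves each with scipy's HiGHS interface, and writes a JSON result list.

Infinities are encoded as +/-1e30 in the JSON exchange format.
"""
import json
import sys

import numpy as np
import scipy.sparse as sp
from scipy.optimize import linprog

INF_SENTINEL = 1e29

STATUS = {0: "optimal", 1: "iteration_limit", 2: "infeasible", 3: "unbounded", 4: "error"}


def aslist(v):
    """JSON scalars stand for length-1 arrays in the exchange format."""
    if v is None:
        return []
    return v if isinstance(v, list) else [v]


def decode_bounds(lb, ub):
    lb = np.asarray(lb, dtype=float)
    ub = np.asarray(ub, dtype=float)
    lb[lb <= -INF_SENTINEL] = -np.inf
    ub[ub >= INF_SENTINEL] = np.inf
    return lb, ub


def solve_parsimonious(S, lb, ub, c, opt):
    """Secondary L1 minimization (parsimonious FBA): among the optima of the
    primary LP, return the flux vector of minimal total absolute flux.
    Removes arbitrary-vertex noise in degenerate coordinates. Variables are
    split as v = p - q with p, q >= 0."""
    m, n = S.shape
    A2 = sp.hstack([S, -S], format="csc")
    b2 = np.zeros(m)
    # primary objective held at its optimum
    crow = sp.csr_matrix(np.concatenate([c, -c])[None, :])
    A2 = sp.vstack([A2, crow], format="csc")
    b2 = np.append(b2, opt)
    pb = np.column_stack([np.maximum(lb, 0), np.maximum(ub, 0)])
    qb = np.column_stack([np.maximum(-ub, 0), np.maximum(-lb, 0)])
    bounds = np.vstack([pb, qb])
    res = linprog(c=np.ones(2 * n), A_eq=A2, b_eq=b2, bounds=bounds,
                  method="highs")
    if res.status != 0:
        return None
    return res.x[:n] - res.x[n:]


def main(path_in, path_out):
    with open(path_in) as fh:
        spec = json.load(fh)

    dims = spec["S"]["dims"]
    S = sp.csc_matrix(
        (aslist(spec["S"]["x"]), (np.asarray(aslist(spec["S"]["i"]), dtype=int),
                                   np.asarray(aslist(spec["S"]["j"]), dtype=int))),
        shape=(dims[0], dims[1]),
    )
    base_lb, base_ub = decode_bounds(aslist(spec["lb"]), aslist(spec["ub"]))
    n = dims[1]
    b_eq = np.zeros(dims[0])

    results = []
    for prob in spec["problems"]:
        lb = base_lb.copy()
        ub = base_ub.copy()
        for idx, val in zip(aslist(prob.get("lb_idx")), aslist(prob.get("lb_val"))):
            lb[int(idx)] = -np.inf if val <= -INF_SENTINEL else val
        for idx, val in zip(aslist(prob.get("ub_idx")), aslist(prob.get("ub_val"))):
            ub[int(idx)] = np.inf if val >= INF_SENTINEL else val
        c = np.zeros(n)
        for idx, val in zip(aslist(prob["obj_idx"]), aslist(prob["obj_val"])):
            c[int(idx)] = val
        sense = prob.get("sense", "max")
        if sense == "max":
            c = -c
        res = linprog(c=c, A_eq=S, b_eq=b_eq, bounds=np.column_stack([lb, ub]),
                      method="highs")
        status = STATUS.get(res.status, "error")
        out = {"status": status}
        if res.status == 0:
            obj = float(res.fun)
            out["objective"] = -obj if sense == "max" else obj
            x = res.x
            if prob.get("parsimonious", False):
                x2 = solve_parsimonious(S, lb, ub, c, obj)
                if x2 is not None:
                    x = x2
            if prob.get("need_x", False):
                out["x"] = [float(v) for v in x]
        results.append(out)

    with open(path_out, "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
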