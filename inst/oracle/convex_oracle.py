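#!/usr/bin/env python3
"""Generic convex-programming oracle for the penalized regression models.

Reads a JSON problem description on stdin (or a file given as argv[1]) and
writes a JSON result on stdout. Two modes:

  mode == "fused":
    minimize sum_c ||x_c - Y_c t_c||_2^2
             + rho1 * sum |T|
             + rho2 * sum_{consecutive columns} |t_c - t_{c+1}|
             + rho3 * sum_rows ||T[row, :]||_2
    fields: x (list of per-time vectors), y (list of per-time matrices,
    rows x features), rho1, rho2, rho3.

  mode == "mtg":
    minimize sum_g 0.5 * ||x_g - Y_g t_g||_2^2 + lam * sum_m ||T[m, :]||_2
    fields: x (T x G matrix, columns = genes), y (list over genes of
    T x M matrices), lam.

Both are solved as smooth epigraph reformulations with SLSQP: each
absolute value |v| is replaced by a variable a >= +/-v and each group
norm ||u||_2 by s with s^2 >= ||u||_2^2 (s >= 0), all penalties entering
the objective linearly. The reported objective is recomputed exactly
from the optimal coefficients.
"""
import json
import sys

import numpy as np
from scipy.optimize import minimize


def solve_fused(prob):
    xs = [np.asarray(v, dtype=float) for v in prob["x"]]
    ys = [np.atleast_2d(np.asarray(m, dtype=float)) for m in prob["y"]]
    rho1, rho2, rho3 = prob["rho1"], prob["rho2"], prob["rho3"]
    C = len(xs)
    p = ys[0].shape[1]
    nT = p * C

    def unpack(z):
        return z[:nT].reshape(p, C, order="F")

    def true_obj(T):
        loss = sum(float(np.sum((xs[c] - ys[c] @ T[:, c]) ** 2))
                   for c in range(C))
        pen = rho1 * np.abs(T).sum()
        if C > 1:
            pen += rho2 * np.abs(np.diff(T, axis=1)).sum()
        pen += rho3 * np.linalg.norm(T, axis=1).sum()
        return loss + pen

    # variables: theta (p*C), a (|theta|, p*C), d (|diffs|, p*(C-1)), s (p)
    nD = p * (C - 1)
    n = nT + nT + nD + p

    def objective(z):
        T = unpack(z)
        loss = sum(float(np.sum((xs[c] - ys[c] @ T[:, c]) ** 2))
                   for c in range(C))
        a = z[nT:2 * nT]
        d = z[2 * nT:2 * nT + nD]
        s = z[2 * nT + nD:]
        return loss + rho1 * a.sum() + rho2 * d.sum() + rho3 * s.sum()

    def gradient(z):
        T = unpack(z)
        g = np.zeros(n)
        gt = np.zeros((p, C))
        for c in range(C):
            gt[:, c] = 2.0 * ys[c].T @ (ys[c] @ T[:, c] - xs[c])
        g[:nT] = gt.reshape(-1, order="F")
        g[nT:2 * nT] = rho1
        g[2 * nT:2 * nT + nD] = rho2
        g[2 * nT + nD:] = rho3
        return g

    cons = []

    def abs_cons(z):
        t = z[:nT]
        a = z[nT:2 * nT]
        return np.concatenate([a - t, a + t])

    cons.append({"type": "ineq", "fun": abs_cons})

    if C > 1:
        def diff_cons(z):
            T = unpack(z)
            dv = np.diff(T, axis=1).reshape(-1, order="F")
            d = z[2 * nT:2 * nT + nD]
            return np.concatenate([d - dv, d + dv])
        cons.append({"type": "ineq", "fun": diff_cons})

    def grp_cons(z):
        # s >= sqrt(||row||^2 + eps): unlike s^2 >= ||row||^2, the gradient
        # with respect to s is 1 everywhere, so SLSQP cannot stall at the
        # degenerate cone tip theta = 0, s = 0
        T = unpack(z)
        s = z[2 * nT + nD:]
        return s - np.sqrt(np.sum(T * T, axis=1) + 1e-14)

    cons.append({"type": "ineq", "fun": grp_cons})

    def pack_start(T0):
        z = np.zeros(n)
        z[:nT] = T0.reshape(-1, order="F")
        z[nT:2 * nT] = np.abs(T0).reshape(-1, order="F") + 1e-6
        if C > 1:
            z[2 * nT:2 * nT + nD] = (np.abs(np.diff(T0, axis=1))
                                     .reshape(-1, order="F") + 1e-6)
        z[2 * nT + nD:] = np.linalg.norm(T0, axis=1) + 1e-6
        return z

    # multi-start: SLSQP can stall at the origin, so also try a ridge
    # warm start per time point
    ridge = np.zeros((p, C))
    for c in range(C):
        A = ys[c].T @ ys[c] + 0.1 * np.eye(p)
        ridge[:, c] = np.linalg.solve(A, ys[c].T @ xs[c])
    best = None
    for T0 in (np.zeros((p, C)), ridge):
        res = minimize(objective, pack_start(T0), jac=gradient,
                       method="SLSQP", constraints=cons,
                       options={"maxiter": 2000, "ftol": 1e-10})
        T = unpack(res.x)
        cand = {"objective": true_obj(T), "theta": T,
                "status": int(res.status), "message": str(res.message)}
        if best is None or cand["objective"] < best["objective"]:
            best = cand
    best["theta"] = best["theta"].tolist()
    return best


def solve_mtg(prob):
    x = np.asarray(prob["x"], dtype=float)           # T x G
    ys = [np.asarray(m, dtype=float) for m in prob["y"]]  # G of T x M
    lam = float(prob["lam"])
    T, G = x.shape
    M = ys[0].shape[1]
    nT = M * G

    def unpack(z):
        return z[:nT].reshape(M, G, order="F")

    def true_obj(Th):
        loss = sum(0.5 * float(np.sum((x[:, g] - ys[g] @ Th[:, g]) ** 2))
                   for g in range(G))
        return loss + lam * np.linalg.norm(Th, axis=1).sum()

    n = nT + M

    def objective(z):
        Th = unpack(z)
        loss = sum(0.5 * float(np.sum((x[:, g] - ys[g] @ Th[:, g]) ** 2))
                   for g in range(G))
        return loss + lam * z[nT:].sum()

    def gradient(z):
        Th = unpack(z)
        g = np.zeros(n)
        gt = np.zeros((M, G))
        for gg in range(G):
            gt[:, gg] = ys[gg].T @ (ys[gg] @ Th[:, gg] - x[:, gg])
        g[:nT] = gt.reshape(-1, order="F")
        g[nT:] = lam
        return g

    def grp_cons(z):
        # see solve_fused: sqrt form avoids the degenerate cone tip
        Th = unpack(z)
        s = z[nT:]
        return s - np.sqrt(np.sum(Th * Th, axis=1) + 1e-14)

    def pack_start(T0):
        z = np.zeros(n)
        z[:nT] = T0.reshape(-1, order="F")
        z[nT:] = np.linalg.norm(T0, axis=1) + 1e-6
        return z

    # multi-start: SLSQP can stall at the origin, so also try a ridge
    # warm start per gene
    ridge = np.zeros((M, G))
    for g in range(G):
        A = ys[g].T @ ys[g] + 0.1 * np.eye(M)
        ridge[:, g] = np.linalg.solve(A, ys[g].T @ x[:, g])
    best = None
    for T0 in (np.zeros((M, G)), ridge):
        res = minimize(objective, pack_start(T0), jac=gradient,
                       method="SLSQP",
                       constraints=[{"type": "ineq", "fun": grp_cons}],
                       options={"maxiter": 2000, "ftol": 1e-10})
        Th = unpack(res.x)
        cand = {"objective": true_obj(Th), "theta": Th,
                "status": int(res.status), "message": str(res.message)}
        if best is None or cand["objective"] < best["objective"]:
            best = cand
    Th = best["theta"]
    best["theta"] = Th.tolist()
    best["group_norms"] = np.linalg.norm(Th, axis=1).tolist()
    return best


def main():
    if len(sys.argv) > 1:
        with open(sys.argv[1]) as fh:
            prob = json.load(fh)
    else:
        prob = json.load(sys.stdin)
    if prob["mode"] == "fused":
        out = solve_fused(prob)
    elif prob["mode"] == "mtg":
        out = solve_mtg(prob)
    else:
        raise SystemExit(f"unknown mode: {prob['mode']}")
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
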