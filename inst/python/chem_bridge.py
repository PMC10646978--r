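#!/usr/bin/env python
"""Batch cheminformatics backend for the immunoloop R package.

Reads a JSON request {"op": ..., "smiles": [...], ...} from argv[1] and
writes a JSON response to argv[2].  One process invocation handles an
arbitrarily large batch so the RDKit import cost is paid once per call.

Ops:
  canonical  -> {"canonical": [smi|None, ...]}
  graph      -> kekulized heavy-atom graphs per input (atoms/bonds), plus
                canonical SMILES and heavy-atom count
  ecfp       -> Morgan radius-2 (ECFP4) on-bit indices (0-based), n_bits param
  fragments  -> counts over the 85 RDKit fr_* substructure descriptors
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Fragments

RDLogger.DisableLog("rdApp.*")

FR_NAMES = sorted(n for n in dir(Fragments) if n.startswith("fr_"))


def _mol(smi, strip_stereo=False):
    if smi is None:
        return None
    m = Chem.MolFromSmiles(smi)
    if m is not None and strip_stereo:
        Chem.RemoveStereochemistry(m)
    return m


def op_canonical(req):
    strip = bool(req.get("strip_stereo", False))
    out = []
    for smi in req["smiles"]:
        m = _mol(smi, strip)
        out.append(Chem.MolToSmiles(m) if m is not None else None)
    return {"canonical": out}


def op_graph(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi, strip_stereo=True)
        if m is None:
            out.append(None)
            continue
        can = Chem.MolToSmiles(m)
        mk = Chem.Mol(m)
        try:
            Chem.Kekulize(mk, clearAromaticFlags=True)
        except Exception:
            out.append(None)
            continue
        atoms = [[a.GetSymbol(), a.GetFormalCharge(), a.GetTotalNumHs()]
                 for a in mk.GetAtoms()]
        bonds = [[b.GetBeginAtomIdx(), b.GetEndAtomIdx(),
                  int(b.GetBondTypeAsDouble())] for b in mk.GetBonds()]
        out.append({"atoms": atoms, "bonds": bonds, "can": can,
                    "heavy": mk.GetNumHeavyAtoms()})
    return {"graphs": out}


def op_ecfp(req):
    n_bits = int(req.get("n_bits", 2048))
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        fp = AllChem.GetMorganFingerprintAsBitVect(m, 2, nBits=n_bits)
        out.append(sorted(fp.GetOnBits()))
    return {"bits": out, "n_bits": n_bits}


def op_fragments(req):
    funcs = [getattr(Fragments, n) for n in FR_NAMES]
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        out.append([int(f(m)) for f in funcs])
    return {"names": FR_NAMES, "counts": out}


OPS = {"canonical": op_canonical, "graph": op_graph,
       "ecfp": op_ecfp, "fragments": op_fragments}


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    res = OPS[req["op"]](req)
    with open(sys.argv[2], "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
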