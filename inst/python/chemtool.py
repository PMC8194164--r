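#!/usr/bin/env python
"""RDKit helper behind the targetfish R package.

Subcommands (all read/write plain text; one JSON object per output line):

  parse --format smiles|sdf --in FILE
      -> {"i": <0-based input index>, "ok": true, "id": ..., "smiles": <canonical>,
          "n_heavy": ..., "mw": ...}   or {"i": ..., "ok": false, "error": ...}

  fp --in FILE --algorithms a,b,c
      input: one SMILES per line (already canonical or not; parsed fresh)
      -> one line per molecule: {"i":0, "fps": {"morgan": {"nbits":2048, "on":[...]}, ...}}
         on-bit indices are 0-based.

  atoms --format sdf|mol --in FILE
      -> one line per molecule: {"i":0, "ok":true, "smiles":..., "atoms":[{"element":..,
          "x":..,"y":..,"z":..,"charge":..,"aromatic":..,"donor":..,"acceptor":..}, ...],
          "rings": [[0-based aromatic ring atom indices], ...], "bonds": [[i,j], ...]}

Bit lengths: morgan(r=2) 2048, maccs 166 (RDKit bit 0 dropped), daylight (RDKit
path fingerprint) 2048, avalon 512, atompairs 2048, torsion 2048,
pharmacophore2d (Gobbi) folded to 2048.
"""

import argparse
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, MACCSkeys, rdMolDescriptors
from rdkit.Avalon import pyAvalonTools
from rdkit.Chem.Pharm2D import Generate, Gobbi_Pharm2D

RDLogger.DisableLog("rdApp.*")

FP_NBITS = {
    "morgan": 2048,
    "maccs": 166,
    "daylight": 2048,
    "avalon": 512,
    "atompairs": 2048,
    "torsion": 2048,
    "pharmacophore2d": 2048,
}


def _on_bits(bv):
    return sorted(bv.GetOnBits())


def compute_fp(mol, algorithm):
    n = FP_NBITS[algorithm]
    if algorithm == "morgan":
        return _on_bits(AllChem.GetMorganFingerprintAsBitVect(mol, 2, nBits=n))
    if algorithm == "maccs":
        # RDKit MACCS is 167 bits with bit 0 permanently unset; shift to 166 keys.
        return [b - 1 for b in MACCSkeys.GenMACCSKeys(mol).GetOnBits()]
    if algorithm == "daylight":
        return _on_bits(Chem.RDKFingerprint(mol, fpSize=n))
    if algorithm == "avalon":
        return _on_bits(pyAvalonTools.GetAvalonFP(mol, nBits=n))
    if algorithm == "atompairs":
        return _on_bits(rdMolDescriptors.GetHashedAtomPairFingerprintAsBitVect(mol, nBits=n))
    if algorithm == "torsion":
        return _on_bits(rdMolDescriptors.GetHashedTopologicalTorsionFingerprintAsBitVect(mol, nBits=n))
    if algorithm == "pharmacophore2d":
        sparse = Generate.Gen2DFingerprint(mol, Gobbi_Pharm2D.factory)
        return sorted({b % n for b in sparse.GetOnBits()})
    raise ValueError("unknown fingerprint algorithm: %s" % algorithm)


def iter_smiles_lines(path):
    """Yield (index, smiles, id_or_None) from a SMILES file (id in column 2)."""
    with open(path) as fh:
        i = 0
        for raw in fh:
            line = raw.strip()
            if not line or line.startswith("#"):
                continue
            parts = line.split(None, 1)
            smi = parts[0]
            mid = parts[1].strip() if len(parts) > 1 else None
            yield i, smi, mid
            i += 1


def cmd_parse(args):
    out = sys.stdout
    if args.format == "smiles":
        for i, smi, mid in iter_smiles_lines(args.infile):
            mol = Chem.MolFromSmiles(smi)
            if mol is None or mol.GetNumHeavyAtoms() < 1:
                rec = {"i": i, "ok": False, "id": mid, "input": smi,
                       "error": "unparsable or empty SMILES"}
            else:
                rec = {"i": i, "ok": True, "id": mid,
                       "smiles": Chem.MolToSmiles(mol),
                       "n_heavy": mol.GetNumHeavyAtoms(),
                       "mw": round(Descriptors.MolWt(mol), 4)}
            out.write(json.dumps(rec) + "\n")
    else:  # sdf
        supplier = Chem.SDMolSupplier(args.infile, sanitize=True, removeHs=False)
        for i, mol in enumerate(supplier):
            if mol is None:
                out.write(json.dumps({"i": i, "ok": False, "id": None,
                                      "error": "unparsable SDF record"}) + "\n")
                continue
            mid = mol.GetProp("_Name") if mol.HasProp("_Name") else None
            if mid is not None and mid.strip() == "":
                mid = None
            heavy = Chem.RemoveHs(mol)
            out.write(json.dumps({"i": i, "ok": True, "id": mid,
                                  "smiles": Chem.MolToSmiles(heavy),
                                  "n_heavy": heavy.GetNumHeavyAtoms(),
                                  "mw": round(Descriptors.MolWt(mol), 4)}) + "\n")


def cmd_fp(args):
    algorithms = [a.strip() for a in args.algorithms.split(",") if a.strip()]
    unknown = [a for a in algorithms if a not in FP_NBITS]
    if unknown:
        sys.stderr.write("unknown algorithm(s): %s\n" % ",".join(unknown))
        sys.exit(2)
    if args.nbits:
        for spec in args.nbits.split(","):
            alg, _, n = spec.partition(":")
            if alg not in FP_NBITS or alg == "maccs":
                sys.stderr.write("cannot override bit length for: %s\n" % alg)
                sys.exit(2)
            FP_NBITS[alg] = int(n)
    out = sys.stdout
    for i, smi, _ in iter_smiles_lines(args.infile):
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.write(json.dumps({"i": i, "ok": False,
                                  "error": "unparsable SMILES: %s" % smi}) + "\n")
            continue
        fps = {}
        for alg in algorithms:
            try:
                fps[alg] = {"nbits": FP_NBITS[alg], "on": compute_fp(mol, alg)}
            except Exception as exc:  # typed per-algorithm failure
                out.write(json.dumps({"i": i, "ok": False, "algorithm": alg,
                                      "error": str(exc)}) + "\n")
                break
        else:
            out.write(json.dumps({"i": i, "ok": True, "fps": fps}) + "\n")


def mol_atom_table(mol):
    conf = mol.GetConformer()
    feats = {"donor": set(), "acceptor": set()}
    # Lipinski-style donor/acceptor perception on the heavy-atom graph
    from rdkit.Chem import Lipinski  # noqa: F401  (import kept local, cheap)
    for match in mol.GetSubstructMatches(Chem.MolFromSmarts("[$([N;!H0;v3,v4&+1]),$([O,S;H1;+0]),$([n;H1;+0])]")):
        feats["donor"].add(match[0])
    for match in mol.GetSubstructMatches(Chem.MolFromSmarts("[$([O,S;H1;v2;!$(*-*=[O,N,P,S])]),$([O,S;H0;v2]),$([O,S;-]),$([N;v3;!$(N-*=[O,N,P,S])]),$([nH0,o,s;+0])]")):
        feats["acceptor"].add(match[0])
    atoms = []
    for atom in mol.GetAtoms():
        pos = conf.GetAtomPosition(atom.GetIdx())
        atoms.append({
            "element": atom.GetSymbol(),
            "x": round(pos.x, 4), "y": round(pos.y, 4), "z": round(pos.z, 4),
            "charge": atom.GetFormalCharge(),
            "aromatic": atom.GetIsAromatic(),
            "donor": atom.GetIdx() in feats["donor"],
            "acceptor": atom.GetIdx() in feats["acceptor"],
        })
    rings = []
    ri = mol.GetRingInfo()
    for ring in ri.AtomRings():
        if all(mol.GetAtomWithIdx(a).GetIsAromatic() for a in ring):
            rings.append(list(ring))
    bonds = [[b.GetBeginAtomIdx(), b.GetEndAtomIdx()] for b in mol.GetBonds()]
    return atoms, rings, bonds


def cmd_atoms(args):
    out = sys.stdout
    supplier = Chem.SDMolSupplier(args.infile, sanitize=True, removeHs=False)
    for i, mol in enumerate(supplier):
        if mol is None:
            out.write(json.dumps({"i": i, "ok": False,
                                  "error": "unparsable SDF record"}) + "\n")
            continue
        if mol.GetNumConformers() == 0:
            out.write(json.dumps({"i": i, "ok": False,
                                  "error": "no coordinates"}) + "\n")
            continue
        atoms, rings, bonds = mol_atom_table(mol)
        heavy = Chem.RemoveHs(mol)
        mid = mol.GetProp("_Name") if mol.HasProp("_Name") else None
        out.write(json.dumps({"i": i, "ok": True, "id": mid,
                              "smiles": Chem.MolToSmiles(heavy),
                              "atoms": atoms, "rings": rings,
                              "bonds": bonds}) + "\n")


def main():
    ap = argparse.ArgumentParser(prog="chemtool")
    sub = ap.add_subparsers(dest="cmd", required=True)

    p = sub.add_parser("parse")
    p.add_argument("--format", choices=["smiles", "sdf"], required=True)
    p.add_argument("--in", dest="infile", required=True)
    p.set_defaults(func=cmd_parse)

    p = sub.add_parser("fp")
    p.add_argument("--in", dest="infile", required=True)
    p.add_argument("--algorithms", required=True)
    p.add_argument("--nbits", default="", help="override lengths, e.g. avalon:1024")
    p.set_defaults(func=cmd_fp)

    p = sub.add_parser("atoms")
    p.add_argument("--format", choices=["sdf", "mol"], default="sdf")
    p.add_argument("--in", dest="infile", required=True)
    p.set_defaults(func=cmd_atoms)

    args = ap.parse_args()
    args.func(args)


if __name__ == "__main__":
    main()
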