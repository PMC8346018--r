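#!/usr/bin/env python
"""Batch chemistry helper for the screenlib R package.

Reads tab-separated "id<TAB>smiles" records on stdin and writes a
tab-separated table with a header line on stdout.  All molecule-level
failures are reported in-band (ok=0 + error column); the exit status is
nonzero only for usage errors, so the R side can attribute problems to
individual records.

Commands:
  standardize                 salt strip / neutralize / canonical tautomer /
                              stereo removal; emits standardized SMILES,
                              average molecular weight and element set
  profile [--smarts FILE]     property profile of (already standardized)
                              structures: counts, logP, QED, SSSR ring atom
                              lists, Murcko scaffold, 2048-bit Morgan
                              fingerprint, matched exclusion SMARTS
  fingerprint [--bits N --radius R]
  murcko
"""

import argparse
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, Lipinski, QED, rdMolDescriptors
from rdkit.Chem import rdFingerprintGenerator
from rdkit.Chem.MolStandardize import rdMolStandardize
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

TOSYL_SMARTS = "S(=O)(=O)O"


def read_records(stream):
    for line in stream:
        line = line.rstrip("\n")
        if not line or line.startswith("#"):
            continue
        parts = line.split("\t")
        if len(parts) < 2:
            yield parts[0], None
        else:
            yield parts[0], parts[1]


def emit(fields):
    sys.stdout.write("\t".join(str(f) for f in fields) + "\n")


def parse_mol(smiles):
    if not smiles:
        return None
    return Chem.MolFromSmiles(smiles)


def cmd_standardize(args):
    uncharger = rdMolStandardize.Uncharger()
    tautomerizer = rdMolStandardize.TautomerEnumerator()
    emit(["id", "ok", "smiles_std", "mw", "elements", "error"])
    for cid, smiles in read_records(sys.stdin):
        mol = parse_mol(smiles)
        if mol is None:
            emit([cid, 0, "", "NA", "", "unparseable"])
            continue
        try:
            mol = rdMolStandardize.Cleanup(mol)
            mol = rdMolStandardize.FragmentParent(mol)
            mol = uncharger.uncharge(mol)
            mol = tautomerizer.Canonicalize(mol)
            Chem.RemoveStereochemistry(mol)
            mol = Chem.MolFromSmiles(Chem.MolToSmiles(mol))
            elements = sorted({a.GetSymbol() for a in mol.GetAtoms()})
            if any(a.GetTotalNumHs() > 0 for a in mol.GetAtoms()):
                elements = sorted(set(elements) | {"H"})
            emit([cid, 1, Chem.MolToSmiles(mol),
                  "%.5f" % Descriptors.MolWt(mol), " ".join(elements), ""])
        except Exception as exc:  # standardization failure -> in-band report
            emit([cid, 0, "", "NA", "", type(exc).__name__])


def load_smarts(path):
    patterns = []
    if path:
        with open(path) as fh:
            for line in fh:
                line = line.strip()
                if not line or line.startswith("#"):
                    continue
                name, smarts = line.split("\t")[:2]
                patt = Chem.MolFromSmarts(smarts)
                if patt is None:
                    raise SystemExit("bad SMARTS for pattern '%s'" % name)
                patterns.append((name, patt))
    return patterns


def cmd_profile(args):
    patterns = load_smarts(args.smarts)
    tosyl = Chem.MolFromSmarts(TOSYL_SMARTS)
    fpgen = rdFingerprintGenerator.GetMorganGenerator(
        radius=args.radius, fpSize=args.bits)
    emit(["id", "ok", "heavy_atoms", "rings", "rotatable_bonds", "hbd",
          "hba", "logp", "qed", "mw", "has_charged_carbon", "has_N_or_O",
          "matched_patterns", "ring_atoms", "murcko", "fp_bits", "error"])
    for cid, smiles in read_records(sys.stdin):
        mol = parse_mol(smiles)
        if mol is None:
            emit([cid, 0] + ["NA"] * 14 + ["unparseable"])
            continue
        matched = [name for name, patt in patterns if mol.HasSubstructMatch(patt)]
        if mol.HasSubstructMatch(tosyl):
            matched.append("tosyl")
        rings = mol.GetRingInfo().AtomRings()
        ring_atoms = "|".join(",".join(str(i) for i in ring) for ring in rings)
        charged_c = any(a.GetSymbol() == "C" and a.GetFormalCharge() != 0
                        for a in mol.GetAtoms())
        has_no = any(a.GetSymbol() in ("N", "O") for a in mol.GetAtoms())
        scaffold = MurckoScaffold.MurckoScaffoldSmiles(mol=mol)
        bits = list(fpgen.GetFingerprint(mol).GetOnBits())
        emit([cid, 1,
              mol.GetNumHeavyAtoms(),
              rdMolDescriptors.CalcNumRings(mol),
              rdMolDescriptors.CalcNumRotatableBonds(mol),
              Lipinski.NumHDonors(mol),
              Lipinski.NumHAcceptors(mol),
              "%.5f" % Descriptors.MolLogP(mol),
              "%.6f" % QED.qed(mol),
              "%.5f" % Descriptors.MolWt(mol),
              int(charged_c), int(has_no),
              ";".join(matched), ring_atoms, scaffold,
              ",".join(str(b) for b in bits), ""])


def cmd_fingerprint(args):
    fpgen = rdFingerprintGenerator.GetMorganGenerator(
        radius=args.radius, fpSize=args.bits)
    emit(["id", "ok", "fp_bits", "error"])
    for cid, smiles in read_records(sys.stdin):
        mol = parse_mol(smiles)
        if mol is None:
            emit([cid, 0, "", "unparseable"])
            continue
        bits = list(fpgen.GetFingerprint(mol).GetOnBits())
        emit([cid, 1, ",".join(str(b) for b in bits), ""])


def cmd_murcko(args):
    emit(["id", "ok", "murcko", "error"])
    for cid, smiles in read_records(sys.stdin):
        mol = parse_mol(smiles)
        if mol is None:
            emit([cid, 0, "", "unparseable"])
            continue
        emit([cid, 1, MurckoScaffold.MurckoScaffoldSmiles(mol=mol), ""])


def main():
    parser = argparse.ArgumentParser(description=__doc__)
    sub = parser.add_subparsers(dest="command", required=True)
    sub.add_parser("standardize")
    p = sub.add_parser("profile")
    p.add_argument("--smarts", default=None)
    p.add_argument("--bits", type=int, default=2048)
    p.add_argument("--radius", type=int, default=2)
    p = sub.add_parser("fingerprint")
    p.add_argument("--bits", type=int, default=2048)
    p.add_argument("--radius", type=int, default=2)
    sub.add_parser("murcko")
    args = parser.parse_args()
    {"standardize": cmd_standardize,
     "profile": cmd_profile,
     "fingerprint": cmd_fingerprint,
     "murcko": cmd_murcko}[args.command](args)


if __name__ == "__main__":
    main()
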