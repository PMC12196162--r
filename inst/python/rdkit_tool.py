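"""Batch chemistry helper used by the senoscreen R package.

Reads SMILES (one per line) from a file, writes one result line per input to
stdout. Failed molecules yield a line starting with "ERROR\t" so the caller
can raise a structured condition; the process itself always exits 0 unless
invoked incorrectly.
"""

import argparse
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors

RDLogger.DisableLog("rdApp.*")


def read_smiles(path):
    with open(path) as fh:
        return [line.rstrip("\n") for line in fh]


def mol_or_none(smi):
    if not smi:
        return None
    return Chem.MolFromSmiles(smi)


def cmd_canon(args):
    for smi in read_smiles(args.infile):
        mol = mol_or_none(smi)
        if mol is None:
            sys.stdout.write("ERROR\tunparseable SMILES\n")
        else:
            sys.stdout.write(Chem.MolToSmiles(mol) + "\n")


def cmd_ecfp(args):
    for smi in read_smiles(args.infile):
        mol = mol_or_none(smi)
        if mol is None:
            sys.stdout.write("ERROR\tunparseable SMILES\n")
            continue
        fp = AllChem.GetMorganFingerprintAsBitVect(
            mol, args.radius, nBits=args.nbits
        )
        bits = sorted(fp.GetOnBits())
        sys.stdout.write(" ".join(str(b) for b in bits) + "\n")


def cmd_desc(args):
    wanted = read_smiles(args.names)
    table = dict(Descriptors.descList)
    missing = [n for n in wanted if n not in table]
    if missing:
        sys.stderr.write("unknown descriptors: %s\n" % ",".join(missing))
        sys.exit(2)
    funcs = [(n, table[n]) for n in wanted]
    for smi in read_smiles(args.infile):
        mol = mol_or_none(smi)
        if mol is None:
            sys.stdout.write("ERROR\tunparseable SMILES\n")
            continue
        vals = []
        for _, fn in funcs:
            try:
                vals.append(repr(float(fn(mol))))
            except Exception:
                vals.append("nan")
        sys.stdout.write("\t".join(vals) + "\n")


def main():
    ap = argparse.ArgumentParser()
    sub = ap.add_subparsers(dest="cmd", required=True)

    p = sub.add_parser("canon")
    p.add_argument("infile")
    p.set_defaults(func=cmd_canon)

    p = sub.add_parser("ecfp")
    p.add_argument("infile")
    p.add_argument("--nbits", type=int, default=2048)
    p.add_argument("--radius", type=int, default=2)
    p.set_defaults(func=cmd_ecfp)

    p = sub.add_parser("desc")
    p.add_argument("infile")
    p.add_argument("--names", required=True)
    p.set_defaults(func=cmd_desc)

    args = ap.parse_args()
    args.func(args)


if __name__ == "__main__":
    main()
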