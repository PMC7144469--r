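"""Compute binary fingerprints for SMILES read from stdin (one per line).

Usage: python fingerprints.py <scheme> <n_bits>
  scheme: morgan_r2 | maccs
Writes one line per input SMILES: either a 0/1 string of length n_bits, or
"ERROR<TAB><message>" for unparseable input. Exits non-zero only on setup
failure, so R can attribute per-record errors.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import MACCSkeys
from rdkit.Chem.rdFingerprintGenerator import GetMorganGenerator

RDLogger.DisableLog("rdApp.*")


def main() -> int:
    scheme = sys.argv[1]
    n_bits = int(sys.argv[2])
    if scheme == "morgan_r2":
        gen = GetMorganGenerator(radius=2, fpSize=n_bits)
        fp_fun = gen.GetFingerprint
    elif scheme == "maccs":
        fp_fun = MACCSkeys.GenMACCSKeys
    else:
        sys.stderr.write(f"unknown scheme: {scheme}\n")
        return 2
    for line in sys.stdin:
        smi = line.strip()
        if not smi:
            sys.stdout.write("ERROR\tempty SMILES\n")
            continue
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            sys.stdout.write(f"ERROR\tunparseable SMILES: {smi}\n")
            continue
        sys.stdout.write(fp_fun(mol).ToBitString() + "\n")
    return 0


if __name__ == "__main__":
    sys.exit(main())
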