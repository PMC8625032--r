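"""Thin RDKit bridge used by the R package for SMILES handling and
deterministic 3D embedding (ETKDG with a fixed random seed, force-field
relaxed). Reads its molecular input from stdin, writes SDF/SMILES to stdout.

Exit codes: 2 = unparseable input, 3 = embedding failure.
"""
import argparse
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def embed(mol, n_confs, seed):
    for attempt in range(3):  # retry with incremented seeds
        params = AllChem.ETKDGv3()
        params.randomSeed = seed + attempt
        ids = AllChem.EmbedMultipleConfs(mol, numConfs=n_confs, params=params)
        if len(ids):
            return list(ids)
    return []


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--mode", required=True,
                    choices=["embed", "canonical", "canonical-molblock"])
    ap.add_argument("--max-confs", type=int, default=1)
    ap.add_argument("--seed", type=int, default=1)
    a = ap.parse_args()
    data = sys.stdin.read()

    if a.mode == "canonical-molblock":
        mol = Chem.MolFromMolBlock(data, sanitize=True)
        if mol is None:
            mol = Chem.MolFromMolBlock(data, sanitize=False)
        if mol is None:
            sys.exit(2)
        print(Chem.MolToSmiles(mol))
        return

    mol = Chem.MolFromSmiles(data.strip())
    if mol is None:
        sys.exit(2)
    if a.mode == "canonical":
        print(Chem.MolToSmiles(mol))
        return

    mol = Chem.AddHs(mol)
    nrot = rdMolDescriptors.CalcNumRotatableBonds(mol)
    n_embed = 1 if nrot == 0 or a.max_confs == 1 else \
        min(3 * a.max_confs, max(20 * nrot, 10))
    ids = embed(mol, n_embed, a.seed)
    if not ids:
        sys.exit(3)
    try:
        AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=200)
    except Exception:
        try:
            AllChem.UFFOptimizeMoleculeConfs(mol, maxIters=200)
        except Exception:
            pass
    writer = Chem.SDWriter(sys.stdout)
    writer.SetKekulize(True)
    for cid in ids:
        writer.write(mol, confId=cid)
    writer.close()


if __name__ == "__main__":
    main()
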