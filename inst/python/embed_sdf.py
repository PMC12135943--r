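"""Deterministic 3D embedding for one SDF record.

Usage: python embed_sdf.py IN.sdf OUT.sdf SEED

Reads the first V2000 record (explicit hydrogens kept), completes implicit
hydrogens, embeds with ETKDGv3 at the given random seed and relaxes with
MMFF94 (UFF fallback). Input atom order is preserved; added hydrogens are
appended after the input atoms.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def main(argv):
    inp, out, seed = argv[1], argv[2], int(argv[3])
    supplier = Chem.SDMolSupplier(inp, removeHs=False, sanitize=True)
    mol = next(iter(supplier), None)
    if mol is None:
        sys.stderr.write("unparseable SDF record\n")
        return 2
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    params.useRandomCoords = False
    if AllChem.EmbedMolecule(mol, params) != 0:
        params.useRandomCoords = True
        if AllChem.EmbedMolecule(mol, params) != 0:
            sys.stderr.write("embedding failed\n")
            return 3
    try:
        if AllChem.MMFFHasAllMoleculeParams(mol):
            AllChem.MMFFOptimizeMolecule(mol, mmffVariant="MMFF94")
        else:
            AllChem.UFFOptimizeMolecule(mol)
    except Exception:
        pass
    writer = Chem.SDWriter(out)
    writer.write(mol)
    writer.close()
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
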