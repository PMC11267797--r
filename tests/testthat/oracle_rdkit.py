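"""Independent chemistry oracle used by the test suite.

Reads JSON {"smiles": [...], "n_random": k} on stdin and writes, per
molecule: RDKit canonical SMILES, heavy-atom count, assigned chiral-centre
count, bridgehead/spiro counts, macrocycle count (SSSR rings > 8),
symmetry classes (canonical ranks without tie-breaking), per-atom Morgan
radius-2 environment identifiers where defined, and k random SMILES
respellings.
"""
import json
import sys

from rdkit import Chem
from rdkit.Chem import AllChem, rdMolDescriptors

def describe(smi, n_random):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False}
    info = {}
    AllChem.GetMorganFingerprint(mol, 2, bitInfo=info, useChirality=False)
    morgan2 = {}
    for env_id, hits in info.items():
        for atom, radius in hits:
            if radius == 2:
                morgan2[atom] = env_id
    ri = mol.GetRingInfo()
    return {
        "ok": True,
        "canonical": Chem.MolToSmiles(mol),
        "n_atoms": mol.GetNumAtoms(),
        "n_chiral": len(Chem.FindMolChiralCenters(mol, includeUnassigned=False)),
        "n_bridgehead": rdMolDescriptors.CalcNumBridgeheadAtoms(mol),
        "n_spiro": rdMolDescriptors.CalcNumSpiroAtoms(mol),
        "n_macrocycle": sum(1 for r in ri.AtomRings() if len(r) > 8),
        "sym_class": list(Chem.CanonicalRankAtoms(mol, breakTies=False)),
        "morgan2_atoms": sorted(morgan2),
        "morgan2_ids": [morgan2[a] for a in sorted(morgan2)],
        "random_smiles": [
            Chem.MolToSmiles(mol, doRandom=True) for _ in range(n_random)
        ],
    }

def main():
    req = json.load(sys.stdin)
    out = [describe(s, req.get("n_random", 0)) for s in req["smiles"]]
    json.dump(out, sys.stdout)

if __name__ == "__main__":
    main()
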