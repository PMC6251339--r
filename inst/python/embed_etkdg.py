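"""Deterministic 3D embedding of SMILES with RDKit ETKDGv3.

Usage: python embed_etkdg.py <smiles_file> <seed> <out_sdf>

Reads one SMILES per line (optionally tab-followed by an id), adds explicit
hydrogens, embeds one conformer with the given random seed, and writes an SD
file. Records that fail to parse or embed are written as a comment line to
stderr and skipped; callers match outputs to inputs via the molecule title.
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def main(smiles_file, seed, out_sdf):
    writer = Chem.SDWriter(out_sdf)
    with open(smiles_file) as fh:
        for lineno, line in enumerate(fh):
            line = line.strip()
            if not line:
                continue
            smiles = line.split("\t")[0]
            title = line.split("\t")[1] if "\t" in line else str(lineno)
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                sys.stderr.write("PARSE_FAIL\t%s\n" % title)
                continue
            mol = Chem.AddHs(mol)
            params = AllChem.ETKDGv3()
            params.randomSeed = int(seed)
            if AllChem.EmbedMolecule(mol, params) != 0:
                sys.stderr.write("EMBED_FAIL\t%s\n" % title)
                continue
            mol.SetProp("_Name", title)
            writer.write(mol)
    writer.close()


if __name__ == "__main__":
    main(sys.argv[1], int(sys.argv[2]), sys.argv[3])
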