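"""Batch synthetic-accessibility scoring.

Reads SMILES, one per line, on stdin; writes one score (or NA for
unparsable input) per line on stdout. Uses the reference RDKit
contributed implementation (fragment contributions + complexity
penalty, range ~1 easy to ~10 hard).
"""
import os
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import RDConfig

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
RDLogger.DisableLog("rdApp.*")
import sascorer  # noqa: E402

for line in sys.stdin:
    smi = line.strip()
    if not smi:
        continue
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        sys.stdout.write("NA\n")
    else:
        sys.stdout.write("%.6f\n" % sascorer.calculateScore(mol))
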