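"""Independent Shrake-Rupley SASA oracle (biotite backend).

Usage: python biotite_sasa.py <pdb> <probe> <n_points>
Prints per-residue SASA as TSV (chain, resnum, sasa) using the same
element-based vdW radii as the R implementation, so only the quadrature
differs.
"""
import sys

import numpy as np
import biotite.structure as struc
from biotite.structure.io.pdb import PDBFile

RADII = {"C": 1.7, "N": 1.55, "O": 1.52, "S": 1.8, "H": 1.2}
DEFAULT = 1.8


def main():
    pdb_path, probe, n_points = sys.argv[1], float(sys.argv[2]), int(sys.argv[3])
    arr = PDBFile.read(pdb_path).get_structure(model=1)
    radii = np.array([RADII.get(e.upper(), DEFAULT) for e in arr.element])
    atom_sasa = struc.sasa(
        arr,
        probe_radius=probe,
        point_number=n_points,
        point_distr="Fibonacci",
        vdw_radii=radii,
        ignore_ions=False,
    )
    res_ids = {}
    for i in range(arr.array_length()):
        key = (arr.chain_id[i], int(arr.res_id[i]))
        res_ids[key] = res_ids.get(key, 0.0) + float(atom_sasa[i])
    for (chain, resnum), sasa in res_ids.items():
        print(f"{chain}\t{resnum}\t{sasa:.6f}")


if __name__ == "__main__":
    main()
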