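{
  "_comment": "Synthetic stand-in marker catalog: open, widely used lineage and pathway markers assembled for this package; not a licensed curated panel.",
  "cell_types": {
    "T_cells": ["CD3D", "CD3E", "CD3G", "CD2", "CD6"],
    "CD8_T": ["CD8A", "CD8B", "GZMA", "GZMK", "PRF1"],
    "Treg": ["FOXP3", "IL2RA", "IKZF2", "CTLA4"],
    "macrophages": ["CD163", "CD68", "MSR1", "MRC1", "CSF1R"],
    "B_cells": ["CD19", "MS4A1", "CD79A", "CD79B", "BLK"],
    "NK": ["NCR1", "KLRD1", "NKG7", "KLRB1"],
    "CD56dim_NK": ["FCGR3A", "KIR2DL3", "SPON2"],
    "exhausted_CD8": ["PDCD1", "LAG3", "HAVCR2", "TIGIT"],
    "DC": ["ITGAX", "CD1C", "BATF3", "FLT3"],
    "neutrophils": ["FCGR3B", "CEACAM8", "FUT4", "CSF3R"],
    "Th1": ["TBX21", "IFNG", "IL12RB2", "STAT4"],
    "CD45": ["PTPRC"]
  },
  "pathways": {
    "cytotoxicity": ["GZMB", "GNLY", "KLRK1", "FASLG"],
    "antigen_processing": ["TAP1", "TAP2", "B2M", "PSMB9", "HLA-A"],
    "chemokine_signalling": ["CXCL9", "CXCL10", "CXCL11", "CXCR3", "CCL5"]
  },
  "housekeeping": ["ACTB", "GAPDH", "TUBB", "POLR2A", "TBP", "RPL19"]
}
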