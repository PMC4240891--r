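probe_id	gene_symbol	metagene	mhc_class_ii
mdsyn_0001_at	HLA-DRA	M/D	yes
mdsyn_0002_at	HLA-DRA	M/D	yes
mdsyn_0003_at	HLA-DRB1	M/D	yes
mdsyn_0004_at	HLA-DRB1	M/D	yes
mdsyn_0005_at	HLA-DMA	M/D	yes
mdsyn_0006_at	HLA-DMA	M/D	yes
mdsyn_0007_at	HLA-DMB	M/D	yes
mdsyn_0008_at	HLA-DMB	M/D	yes
mdsyn_0009_at	HLA-DPA1	M/D	yes
mdsyn_0010_at	HLA-DPA1	M/D	yes
mdsyn_0011_at	HLA-DPB1	M/D	yes
mdsyn_0012_at	HLA-DPB1	M/D	yes
mdsyn_0013_at	HLA-DQA1	M/D	yes
mdsyn_0014_at	HLA-DQA1	M/D	yes
mdsyn_0015_at	HLA-DQB1	M/D	yes
mdsyn_0016_at	HLA-DQB1	M/D	yes
mdsyn_0017_at	CD74	M/D	yes
mdsyn_0018_at	CD74	M/D	yes
mdsyn_0019_at	CSF1R	M/D	no
mdsyn_0020_at	CSF1R	M/D	no
mdsyn_0021_at	MDSYN01	M/D	no
mdsyn_0022_at	MDSYN01	M/D	no
mdsyn_0023_at	MDSYN02	M/D	no
mdsyn_0024_at	MDSYN03	M/D	no
mdsyn_0025_at	MDSYN04	M/D	no
mdsyn_0026_at	MDSYN05	M/D	no
mdsyn_0027_at	MDSYN06	M/D	no
mdsyn_0028_at	MDSYN07	M/D	no
mdsyn_0029_at	MDSYN08	M/D	no
mdsyn_0030_at	MDSYN09	M/D	no
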