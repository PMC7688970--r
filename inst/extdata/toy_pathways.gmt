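PW_TCR_SIGNALING	PW_TCR_SIGNALING toy pathway	CD4	CD8A	CD8B	IL7R	G00001	G00002	G00003	G00004	G00005	G00006	G00007	G00008
PW_BCR_SIGNALING	PW_BCR_SIGNALING toy pathway	MS4A1	CD79A	CD79B	G00005	G00006	G00007	G00008	G00009	G00010	G00011	G00012	G00013	G00014
PW_NK_CYTOTOXICITY	PW_NK_CYTOTOXICITY toy pathway	NKG7	GNLY	KLRD1	FCGR3A	G00010	G00011	G00012	G00013	G00014	G00015	G00016	G00017	G00018
PW_PHAGOCYTOSIS	PW_PHAGOCYTOSIS toy pathway	CD14	LYZ	S100A8	MS4A7	LST1	G00015	G00016	G00017	G00018	G00019	G00020	G00021	G00022
PW_LEUKEMIA	PW_LEUKEMIA toy pathway	MS4A1	CD79A	GZMK	G00020	G00021	G00022	G00023	G00024	G00025	G00026	G00027	G00028	G00029	G00030
PW_VIRAL_INFECTION	PW_VIRAL_INFECTION toy pathway	CCR7	LST1	G00025	G00026	G00027	G00028	G00029	G00030	G00031	G00032	G00033	G00034	G00035	G00036	G00037	G00038
PW_GLYCOLYSIS	PW_GLYCOLYSIS toy pathway	G00040	G00041	G00042	G00043	G00044	G00045	G00046	G00047	G00048	G00049	G00050	G00051	G00052	G00053	G00054	G00055
PW_OXPHOS	PW_OXPHOS toy pathway	G00050	G00051	G00052	G00053	G00054	G00055	G00056	G00057	G00058	G00059	G00060	G00061	G00062	G00063	G00064	G00065	G00066	G00067	G00068
PW_SPLICEOSOME	PW_SPLICEOSOME toy pathway	G00060	G00061	G00062	G00063	G00064	G00065	G00066	G00067	G00068	G00069	G00070	G00071	G00072	G00073	G00074	G00075	G00076	G00077	G00078	G00079	G00080
PW_RIBOSOME	PW_RIBOSOME toy pathway	G00075	G00076	G00077	G00078	G00079	G00080	G00081	G00082	G00083	G00084	G00085	G00086	G00087	G00088	G00089	G00090	G00091	G00092	G00093	G00094	G00095
PW_CELL_CYCLE	PW_CELL_CYCLE toy pathway	G00085	G00086	G00087	G00088	G00089	G00090	G00091	G00092	G00093	G00094	G00095	G00096	G00097	G00098	G00099	G00100	G00101	G00102	G00103	G00104	G00105
PW_MISC_DISEASE	PW_MISC_DISEASE toy pathway	G00095	G00096	G00097	G00098	G00099	G00100	G00101	G00102	G00103	G00104	G00105	G00106	G00107	G00108	G00109	G00110	G00111	G00112	G00113	G00114	G00115
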