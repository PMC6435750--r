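asv_id	reads
ASV_LGC_00001	28810
ASV_LGC_00002	22885
ASV_LGC_00003	22720
ASV_LGC_00004	16750
ASV_LGC_00005	10787
ASV_LGC_00006	6207
ASV_LGC_00007	5465
ASV_LGC_00008	5459
ASV_LGC_00009	5251
ASV_LGC_00010	4500
ASV_LGC_00011	4070
ASV_LGC_00012	3558
ASV_LGC_00013	3288
ASV_LGC_00014	2200
ASV_LGC_00015	1616
ASV_LGC_00016	1259
ASV_LGC_00017	1096
ASV_LGC_00018	1061
ASV_LGC_00019	1045
ASV_LGC_00022	369
ASV_LGC_00023	277
ASV_LGC_00024	248
ASV_LGC_00025	234
ASV_LW_00001	67761
ASV_LW_00002	37318
ASV_LW_00003	35194
ASV_LW_00004	25692
ASV_LW_00005	20779
ASV_LW_00006	20153
ASV_LW_00007	14869
ASV_LW_00008	13511
ASV_LW_00009	7310
ASV_LW_00010	5640
ASV_LW_00011	2806
ASV_LW_00012	2610
ASV_LW_00013	2357
ASV_LW_00014	1862
ASV_LW_00015	1078
ASV_LW_00016	935
ASV_LW_00017	908
ASV_LW_00018	841
ASV_LW_00020	668
ASV_LW_00021	661
ASV_LW_00022	462
ASV_LW_00024	366
ASV_LW_00027	205
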