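asv_id	dataset	genus	taxon
ASV_LGC_00001	LGC	Micromonas	Micromonas bravo clade B2
ASV_LGC_00002	LGC	Ostreococcus	Ostreococcus lucimarinus
ASV_LGC_00003	LGC	Ostreococcus	Ostreococcus clade E
ASV_LGC_00004	LGC	Bathycoccus	Bathycoccus prasinos
ASV_LGC_00005	LGC	Micromonas	Micromonas commoda clade A2
ASV_LGC_00006	LGC	Ostreococcus	Ostreococcus clade B
ASV_LGC_00007	LGC	Micromonas	Micromonas commoda clade A1
ASV_LGC_00008	LGC	Micromonas	Micromonas bravo clade B1
ASV_LGC_00009	LGC	Micromonas	Micromonas clade B5
ASV_LGC_00010	LGC	Mantoniella	Mantoniella squamata
ASV_LGC_00011	LGC	Mantoniella	Mantoniella clade B
ASV_LGC_00012	LGC	Ostreococcus	Ostreococcus tauri
ASV_LGC_00013	LGC	Ostreococcus	Ostreococcus tauri
ASV_LGC_00014	LGC	Micromonas	Micromonas polaris
ASV_LGC_00015	LGC	Micromonas	Micromonas clade B4
ASV_LGC_00016	LGC	Micromonas	Micromonas pusilla
ASV_LGC_00017	LGC	Micromonas	Micromonas clade B3
ASV_LGC_00018	LGC	Ostreococcus	Ostreococcus tauri
ASV_LGC_00019	LGC	Micromonas	Micromonas clade B5
ASV_LGC_00022	LGC	Ostreococcus	Ostreococcus mediterraneus
ASV_LGC_00023	LGC	Ostreococcus	Ostreococcus clade E
ASV_LGC_00024	LGC	Ostreococcus	Ostreococcus mediterraneus
ASV_LGC_00025	LGC	Ostreococcus	Ostreococcus lucimarinus
ASV_LW_00001	LW	Ostreococcus	Ostreococcus mediterraneus
ASV_LW_00002	LW	Ostreococcus	Ostreococcus clade E
ASV_LW_00003	LW	Micromonas	Micromonas polaris
ASV_LW_00004	LW	Mantoniella	Mantoniella squamata
ASV_LW_00005	LW	Bathycoccus	Bathycoccus prasinos
ASV_LW_00006	LW	Micromonas	Micromonas bravo clade B2
ASV_LW_00007	LW	Micromonas	Micromonas commoda clade A2
ASV_LW_00008	LW	Ostreococcus	Ostreococcus tauri
ASV_LW_00009	LW	Ostreococcus	Ostreococcus lucimarinus
ASV_LW_00010	LW	Ostreococcus	Ostreococcus tauri
ASV_LW_00011	LW	Micromonas	Micromonas pusilla
ASV_LW_00012	LW	Micromonas	Micromonas commoda clade A1
ASV_LW_00013	LW	Micromonas	Micromonas bravo clade B1
ASV_LW_00014	LW	Micromonas	Micromonas clade B3
ASV_LW_00015	LW	Micromonas	Micromonas clade B4
ASV_LW_00016	LW	Mantoniella	Mantoniella clade B
ASV_LW_00017	LW	Ostreococcus	Ostreococcus tauri
ASV_LW_00018	LW	Mantoniella	Mantoniella clade A
ASV_LW_00020	LW	Micromonas	Micromonas polaris
ASV_LW_00021	LW	Micromonas	Micromonas clade B5
ASV_LW_00022	LW	Micromonas	Micromonas commoda clade A2
ASV_LW_00024	LW	Ostreococcus	Ostreococcus clade B
ASV_LW_00027	LW	Micromonas	Micromonas bravo clade B1
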