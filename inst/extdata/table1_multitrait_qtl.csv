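# Curated transcription of the published multi-trait QTL table (40 regions).
# Coordinates are 1-based inclusive on the MSU7/IRGSP rice assembly.
# phenotypes: trait-temperature labels joined with "+" (E = electrolyte
# leakage, L = low-temperature seedling survivability, LT50 = median lethal
# temperature). cluster_overlap: TvS / S / T tags joined with "+", empty when
# no cluster-specific QTL overlapped. published_qtl: legacy QTL names joined
# with ";", empty when none.
qtl,chr,start,end,phenotypes,cluster_overlap,peak_lod,peak_snp_gene,published_qtl
qMT1-1,1,10527625,11389874,E10+L10,TvS,5.444609,,Locus2
qMT1-2,1,13105151,14895303,E10+E16+L12,TvS,4.769976,,
qMT1-3,1,15272806,17301559,E10+L12,TvS,5.906907,,
qMT1-4,1,19518259,20986910,E8+E12,TvS,6.768674,,Locus4;qCTS1-3
qMT2-1,2,17820486,18028915,L4+L8,,4.680601,LOC_Os02g30270,
qMT2-2,2,20805063,21772969,E10+L4,TvS,7.292885,,
qMT3-1,3,21728962,23622225,E10+E12+L8+L10+L12+L16,S+TvS,6.272784,,qCTS3-11
qMT3-2,3,23729655,25203390,E10+L10+L12,S+TvS,7.380266,,qLTSS3-3/qLTS3-2
qMT4-1,4,9599400,11394804,L10+L12,TvS,6.484325,,
qMT4-2,4,28197218,29473755,E10+L12,TvS,12.14515,,Locus47;qLTSS4-2;qCTS4-3
qMT4-3,4,34467694,35089971,E4+L10,S+TvS,6.47215,LOC_Os04g58780,qLTSS4-3/qLTS4
qMT5-1,5,69986,1409302,E8+L10+L16+LT50,TvS,7.38114,,Locus51
qMT5-2,5,6600746,8783967,E10+L10+L12,TvS,6.324189,,qLTS5;qCTS5-3
qMT5-3,5,27413208,29075588,E16+L16,,4.955528,LOC_Os05g48960,Locus56
qMT6-1,6,690949,1804604,E16+L12,S+TvS,7.250662,LOC_Os06g02710,Locus57;qPGC6-1
qMT6-2,6,3567142,4288870,E16+L12,TvS,5.286129,LOC_Os06g07420,
qMT6-3,6,22367941,23364932,E10+L4+L12,,5.466931,,qLTG6
qMT7-1,7,592074,1198046,L12+L16,TvS,7.1194,,qCTS7-1
qMT7-2,7,1452372,2559101,E8+L10,S+TvS,10.08297,,Locus69;qLTSS7-1
qMT7-3,7,3402347,3683917,E12+L12,TvS,6.412739,LOC_Os07g07240,
qMT7-4,7,6870947,7663360,E16+L12,TvS,5.970675,LOC_Os07g12330,
qMT7-5,7,7997910,8776532,L12+L16,TvS,6.408,,qLTSS7-2
qMT7-6,7,15627934,16632053,E16+L10,S+TvS,5.094292,,Locus75;qCTS7
qMT7-7,7,22505330,23930131,E10+L8,TvS,7.906038,,qCTS7-4
qMT8-1,8,4409763,5060164,E12+L12,TvS,7.134518,,qLSS8-1
qMT8-2,8,9468694,10399998,L4+L12,TvS,7.793283,,qCTS8-2
qMT8-3,8,16369660,16896911,L4+L12,TvS,6.393616,LOC_Os08g27240,Locus84;qLTSS8-2/qLTS8
qMT8-4,8,26014290,27371604,E8+E10+L16,TvS,5.37007,LOC_Os08g41830,Locus87;COLD2
qMT9-1,9,3149137,4733475,E8+E10,TvS,6.185335,,Locus91;qCTS9-3/qCTS9-4/qCTS9-5
qMT9-2,9,5186978,6076169,E8+E10,TvS,8.264567,,Locus93;qPGCG9-1
qMT9-3,9,6569358,7630726,E4+L10,TvS,5.145748,,qPGCG9-1
qMT9-4,9,15055972,15835730,E4+L10,TvS,5.000415,LOC_Os09g25220,Locus97;qLTG-9;qPGCG9-2/qLTSS9-2
qMT10-1,10,1740269,3057764,E16+L10,TvS,6.125558,,
qMT10-2,10,3909466,5322884,L8+L10,S+TvS,10.35381,,Locus101;qLTSS10-1
qMT10-3,10,6299787,6300600,L12+LT50,TvS,7.180984,LOC_Os10g11354,qLTSS10-1
qMT10-4,10,12242058,15899908,L10+L12+LT50,S+TvS,7.843522,,Locus104;qLTSS10-2
qMT11-1,11,15593585,16583082,L12+L16,,5.455106,LOC_Os11g28184,
qMT11-2,11,17316314,18487194,E10+L12,S+TvS,5.02026,LOC_Os11g31620,Locus111;qLTSS11-3;qCTS11-5
qMT11-3,11,25159572,25809234,L10+L12,,5.266234,,Locus116;qCTS11-10
qMT12,12,2192895,4043986,E8+L10+L12,S+TvS,8.710121,LOC_Os12g06270,Locus121
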