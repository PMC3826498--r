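nchar_id	vista_id	active_tissues	genes_within_1mb	aliases
ANC162	hs169	neural_tube	ATG4C,DOCK7,FOXD3,ALG6,ANGPTL3,EFCAB7,DLEU2L,USP1,PGM1,ITGB3BP,KANK4,ROR1,L1TD1
HAR164	hs1198	other	PKN2,LMO4,GTF2B,CCBL2,RBMXL1,GBP3,GBP1
2xHAR.97	hs878	limb,tail	PKN2,GTF2B,LMO4,CCBL2,RBMXL1,GBP3,GBP1,GBP2
ANC494	hs327	hindbrain	PKN2,GTF2B,CCBL2,RBMXL1,GBP3,GBP1,GBP2,GBP7,GBP4,GBP5,GBP6
ANC547	hs1301	forebrain	C11orf58,SOX6,PLEKHA7,RPS13,PIK3C2A,NUCB2,NCR3LG1,KCNJ11
2xHAR.514	hs234	midbrain,eye	RCN1,PAX6,ELP4,IMMP1L,DNAJC24,DCDC1,DCDC5,WT1,EIF3M	ANC553
2xHAR.447	hs798	neural_tube,forebrain	DERA,STRAP,EPS8,SLC15A5,MGST1,LMO3,RERG,PTPRO
HACNS567	hs882	neural_tube,hindbrain,midbrain,dorsal_root_ganglion,trigeminal	KLHL1,DACH1
ANC86	hs828	hindbrain	C15orf41,MEIS2
ANC806	hs634	neural_tube,hindbrain,midbrain,forebrain	SALL3,ATP9B
HAR122	hs1181	heart	FANCL	HACNS851
2xHAR.238	hs522	hindbrain,forebrain,other	TFCP2L1,GLI2,CLASP1,MKI67IP,TSN,INHBB,RALB,TMEM185B	BUSH35,HACNS4
HAR2	hs521	limb,branchial_arch,eye,ear	AC064874.1,AC079135.1,GBX2,AGAP1,ASB18,IQCA1,CXCR7,SH3BP4	ANC6,BUSH38,HACNS1,2xHAR.3
HAR104	hs526	forebrain	FAM53A,SLBP,TMEM129,TACC3,FGFR3,NKX1-1,CRIPAK,LETM1,WHSC1,UVSSA,MAEA,CTBP1,SPON2,AC092535.1,WHSC2,C4orf48,NAT8L,RNF212,FGFRL1,SLC26A1,POLN,HAUS3,IDUA,DGKQ,MXD4,TMEM175,GAK,CPLX1,ZFYVE28,RP11-503N18.3,RNF4,PCGF3,MFSD7,ATP5I,MYL5,PDE6B	HACNS33,ANC107
ANC1061	hs847	forebrain	BEND4,SLC30A9,DCAF4L1,TMEM33,SHISA3,PHOX2B,ATP8A1,GRXCR1,LIMCH1,UCHL1,APBB2
ANC55	hs1175	forebrain,nose	ID4,MBOAT1,E2F3,CDKAL1	HACNS549
HACNS21	hs1366	midbrain	BTBD9,GLO1,DNAH8,ZFAND3,GLP1R,MDGA1,SAYSD1,KCNK5,CCDC167,KCNK17,KCNK16,FTSJD2
HACNS584	hs1738	limb	GRIK2,ASCC3,SIM1
HAR143	hs1809	neural_tube,hindbrain,midbrain,forebrain	FEZF1,AASS,RNF133,RNF148,PTPRZ1,CADPS2,TAS2R16,SLC13A1,FAM3C
HAR118	hs669	midbrain	RUNX1T1,SLC26A7,LRRC69,OTUD6B,TMEM55A,RP11-122A3.2	HACNS126
HAR34	hs852	forebrain,facial_mesenchyme	LINC00583,MPDZ,NFIB,ZDHHC21,CER1,LURAP1L
ANC1335	hs123	forebrain	ARX,POLA1,PCYT1B,MAGEB18,MAGEB6,MAGEB5,PDK3
2xHAR.393	mm170	heart	IQGAP1,ZNF774,GABARAPL3,CRTC3,NGRN,RP11-697E2.6,TTLL13,CIB1,GDPGP1,SEMA4B,IDH2,BLM,ZNF710,FURIN,FES,C15orf38,C15orf38-AP3S2,MAN2A2,AP3S2,UNC45A,HDDC3,RCCD1,ANPEP,PRC1,VPS33B,MESP2,MESP1,SV2B,WDR93,PEX11A,PLIN1,KIF7,TICRR,RHCG
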