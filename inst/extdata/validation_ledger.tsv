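construct_id	source	outcome
c01	this_study	positive
c02	this_study	positive
c03	this_study	positive
c04	this_study	positive
c05	this_study	positive
c06	this_study	positive
c07	this_study	positive
c08	this_study	positive
c09	this_study	positive
c10	this_study	positive
c11	this_study	positive
c12	this_study	positive
c13	this_study	positive
c14	this_study	positive
c15	this_study	positive
c16	this_study	positive
c17	this_study	positive
c18	this_study	positive
c19	this_study	positive
c20	this_study	positive
c21	this_study	positive
c22	this_study	positive
c23	this_study	positive
c24	this_study	positive
c25	this_study	negative
c26	this_study	negative
c27	this_study	negative
c28	this_study	negative
c29	this_study	negative
ANC162	vista	positive
HAR164	vista	positive
2xHAR.97	vista	positive
ANC494	vista	positive
ANC547	vista	positive
2xHAR.514	vista	positive
2xHAR.447	vista	positive
HACNS567	vista	positive
ANC86	vista	positive
ANC806	vista	positive
HAR122	vista	positive
2xHAR.238	vista	positive
HAR2	vista	positive
HAR104	vista	positive
ANC1061	vista	positive
ANC55	vista	positive
HACNS21	vista	positive
HACNS584	vista	positive
HAR143	vista	positive
HAR118	vista	positive
HAR34	vista	positive
ANC1335	vista	positive
2xHAR.393	vista	positive
vista_neg_01	vista	negative
vista_neg_02	vista	negative
vista_neg_03	vista	negative
vista_neg_04	vista	negative
vista_neg_05	vista	negative
vista_neg_06	vista	negative
vista_neg_07	vista	negative
vista_neg_08	vista	negative
vista_neg_09	vista	negative
vista_neg_10	vista	negative
vista_neg_11	vista	negative
vista_neg_12	vista	negative
vista_neg_13	vista	negative
vista_neg_14	vista	negative
vista_neg_15	vista	negative
vista_neg_16	vista	negative
vista_neg_17	vista	negative
vista_neg_18	vista	negative
vista_neg_19	vista	negative
vista_neg_20	vista	negative
vista_neg_21	vista	negative
vista_neg_22	vista	negative
vista_neg_23	vista	negative
vista_neg_24	vista	negative
NPAS3_cluster_01	prior	positive
NPAS3_cluster_02	prior	positive
NPAS3_cluster_03	prior	positive
NPAS3_cluster_04	prior	positive
NPAS3_cluster_05	prior	positive
NPAS3_cluster_06	prior	positive
NPAS3_cluster_07	prior	positive
NPAS3_cluster_08	prior	positive
NPAS3_cluster_09	prior	positive
NPAS3_cluster_10	prior	negative
NPAS3_cluster_11	prior	negative
NPAS3_cluster_12	prior	negative
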