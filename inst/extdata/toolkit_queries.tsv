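gene_name	class	query_id
SPO11	meiosis_specific	Q_SPO11
DMC1	meiosis_specific	Q_DMC1
HOP1	meiosis_specific	Q_HOP1
HOP2	meiosis_specific	Q_HOP2
MER3	meiosis_specific	Q_MER3
MND1	meiosis_specific	Q_MND1
MSH4	meiosis_specific	Q_MSH4
MSH5	meiosis_specific	Q_MSH5
ZIP1	meiosis_specific	Q_ZIP1
PCH2	meiosis_specific	Q_PCH2
REC8	meiosis_specific	Q_REC8
ZIP4	meiosis_specific	Q_ZIP4
HAP2	plasmogamy	Q_HAP2
PRM1	plasmogamy	Q_PRM1
KEX2	plasmogamy	Q_KEX2
CD9	plasmogamy	Q_CD9
TPM1	plasmogamy	Q_TPM1
MYO2	plasmogamy	Q_MYO2
BNI1	plasmogamy	Q_BNI1
RVS161	plasmogamy	Q_RVS161
KAR2	karyogamy	Q_KAR2
CINI1	karyogamy	Q_CINI1
CINI2	karyogamy	Q_CINI2
KAR4	karyogamy	Q_KAR4
SEC63	karyogamy	Q_SEC63
BIK1	karyogamy	Q_BIK1
CIN4	karyogamy	Q_CIN4
KAR3	karyogamy	Q_KAR3
SEC72	karyogamy	Q_SEC72
CDC4	karyogamy	Q_CDC4
CDC34	karyogamy	Q_CDC34
JEM1	karyogamy	Q_JEM1
CDC28	karyogamy	Q_CDC28
KEM1	karyogamy	Q_KEM1
SRG001	other	Q_SRG001
SRG002	other	Q_SRG002
SRG003	other	Q_SRG003
SRG004	other	Q_SRG004
SRG005	other	Q_SRG005
SRG006	other	Q_SRG006
SRG007	other	Q_SRG007
SRG008	other	Q_SRG008
SRG009	other	Q_SRG009
SRG010	other	Q_SRG010
SRG011	other	Q_SRG011
SRG012	other	Q_SRG012
SRG013	other	Q_SRG013
SRG014	other	Q_SRG014
SRG015	other	Q_SRG015
SRG016	other	Q_SRG016
SRG017	other	Q_SRG017
SRG018	other	Q_SRG018
SRG019	other	Q_SRG019
SRG020	other	Q_SRG020
SRG021	other	Q_SRG021
SRG022	other	Q_SRG022
SRG023	other	Q_SRG023
SRG024	other	Q_SRG024
SRG025	other	Q_SRG025
SRG026	other	Q_SRG026
SRG027	other	Q_SRG027
SRG028	other	Q_SRG028
SRG029	other	Q_SRG029
SRG030	other	Q_SRG030
SRG031	other	Q_SRG031
SRG032	other	Q_SRG032
SRG033	other	Q_SRG033
SRG034	other	Q_SRG034
SRG035	other	Q_SRG035
SRG036	other	Q_SRG036
SRG037	other	Q_SRG037
SRG038	other	Q_SRG038
SRG039	other	Q_SRG039
SRG040	other	Q_SRG040
SRG041	other	Q_SRG041
SRG042	other	Q_SRG042
SRG043	other	Q_SRG043
SRG044	other	Q_SRG044
SRG045	other	Q_SRG045
SRG046	other	Q_SRG046
SRG047	other	Q_SRG047
SRG048	other	Q_SRG048
SRG049	other	Q_SRG049
SRG050	other	Q_SRG050
SRG051	other	Q_SRG051
SRG052	other	Q_SRG052
SRG053	other	Q_SRG053
SRG054	other	Q_SRG054
SRG055	other	Q_SRG055
SRG056	other	Q_SRG056
SRG057	other	Q_SRG057
SRG058	other	Q_SRG058
SRG059	other	Q_SRG059
SRG060	other	Q_SRG060
SRG061	other	Q_SRG061
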