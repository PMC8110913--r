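id	betweenness	closeness	degree	direction	type
rno-miR-466d	0.51218231	0.45475113	67	up	miRNA
rno-miR-30c-5p	0.19202477	0.35828877	28	up	miRNA
TCONS_00032291	0.13638041	0.35263158	19	down	lncRNA
rno-miR-330-5p	0.0980652	0.35078534	19	up	miRNA
rno-miR-672-3p	0.09227397	0.3972332	19	up	miRNA
rno-miR-105	0.0628762	0.2942899	16	up	miRNA
rno-miR-743b-3p	0.18723038	0.35608309	15	down	miRNA
rno-miR-200b-3p	0.06427476	0.33059211	14	up	miRNA
rno-miR-19b-3p	0.15041392	0.36144578	13	down	miRNA
rno-miR-20b-5p	0.1312424	0.34883721	13	down	miRNA
rno-miR-19a-3p	0.1326247	0.31007752	12	down	miRNA
rno-miR-182	0.12489841	0.33057851	12	down	miRNA
NONRATT026999.2	0.09955192	0.2942899	12	up	lncRNA
NONRATT023112.2	0.05022828	0.33895447	12	down	lncRNA
rno-miR-185-3p	0.04457109	0.35502959	12	up	miRNA
rno-miR-149-5p	0.0367307	0.32576985	12	up	miRNA
NONRATT019326.2	0.21525703	0.35928144	11	up	lncRNA
NONRATT009530.2	0.19168702	0.36474164	11	up	lncRNA
Camk1d	0.07605598	0.40361446	11	down	mRNA
rno-miR-98-5p	0.09080408	0.2919708	10	down	miRNA
rno-miR-873-5p	0.03179831	0.27762431	10	up	miRNA
rno-miR-381-3p	0.09927927	0.30781011	9	down	miRNA
NONRATT000711.2	0.09817817	0.28103044	9	up	lncRNA
rno-miR-125b-5p	0.0752682	0.34582133	9	down	miRNA
rno-miR-148a-3p	0.05789145	0.30075188	9	down	miRNA
NONRATT021956.2	0.05212423	0.30044843	9	down	lncRNA
rno-miR-323-3p	0.03536281	0.32967033	9	up	miRNA
TCONS_00019774	0.03441627	0.29777778	9	down	lncRNA
NONRATT023352.2	0.02355001	0.29558824	9	down	lncRNA
rno-miR-204-3p	0.01989314	0.35765125	9	up	miRNA
Slitrk1	0.01385154	0.30454545	9	down	mRNA
NONRATT022294.2	0.09576549	0.3	8	up	lncRNA
Angptl4	0.09104243	0.2484472	8	up	mRNA
NONRATT028502.2	0.08986369	0.29411765	8	down	lncRNA
NONRATT016973.2	0.08342507	0.27272727	8	up	lncRNA
rno-miR-181b-5p	0.07952858	0.32608696	8	down	miRNA
NONRATT030423.2	0.05755366	0.32345013	8	up	lncRNA
Sdc1	0.03704544	0.3125	8	up	mRNA
rno-miR-291a-3p	0.02976731	0.28920863	8	down	miRNA
NONRATT030971.2	0.02028265	0.29646018	8	down	lncRNA
Ggt7	0.01764119	0.35387324	8	down	mRNA
Map3k12	0.01396893	0.29955291	8	down	mRNA
NONRATT012376.2	0.07174532	0.32697548	7	down	lncRNA
NONRATT015872.2	0.06823347	0.318542	7	up	lncRNA
TCONS_00005669	0.0267793	0.30781011	7	down	lncRNA
NONRATT030340.2	0.02432357	0.26979866	7	down	lncRNA
NONRATT023047.2	0.01498462	0.38803089	7	down	lncRNA
NONRATT026313.2	0.01112549	0.3236715	7	down	lncRNA
Cdh11	0.00978699	0.36086176	7	down	mRNA
Smarca2	0.00489491	0.3236715	7	down	mRNA
Slc24a2	0.00114177	0.33555927	7	down	mRNA
Cend1	0.00095987	0.32057416	7	down	mRNA
TCONS_00021415	0.09286285	0.28301887	6	up	lncRNA
Prdm1	0.05749742	0.31114551	6	up	mRNA
NONRATT023367.2	0.03062845	0.26728723	6	up	lncRNA
rno-miR-665	0.03050819	0.28389831	6	up	miRNA
rno-let-7f-5p	0.02487038	0.3125	6	down	miRNA
NONRATT028236.2	0.02255182	0.302267	6	down	lncRNA
NONRATT015923.2	0.02175692	0.26966292	6	down	lncRNA
NONRATT027089.2	0.02005236	0.31662269	6	down	lncRNA
NONRATT009857.2	0.01741403	0.30362538	6	down	lncRNA
Tgif1	0.0162247	0.28309859	6	up	mRNA
rno-miR-465-3p	0.0158817	0.28470255	6	up	miRNA
NONRATT012977.2	0.01428249	0.35201401	6	down	lncRNA
NONRATT006267.2	0.0135891	0.35387324	6	down	lncRNA
NONRATT011107.2	0.01284285	0.3295082	6	down	lncRNA
NONRATT023553.2	0.01258839	0.32524272	6	down	lncRNA
rno-miR-140-5p	0.01137994	0.34010152	6	up	miRNA
Syt2	0.00482999	0.27346939	6	down	mRNA
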