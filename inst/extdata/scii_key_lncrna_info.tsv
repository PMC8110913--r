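id	fold_change	p_value	degree	betweenness	closeness	direction
NONRATT026999.2	2.62678022728	0.018017	12	0.099551912	0.2942899	up
NONRATT019326.2	2.56469830552	0.034967	11	0.21525703	0.35928144	up
NONRATT009530.2	355.506999015	0.036493	11	0.19168702	0.36474164	up
TCONS_00032291	-3.07336006	0.034165	19	0.13638041	0.35263158	down
NONRATT023112.2	-3.29641383	0.033856	12	0.05022828	0.33895447	down
NONRATT021956.2	-2.58208307	0.045792	9	0.05212423	0.30044843	down
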