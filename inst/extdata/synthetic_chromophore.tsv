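name	x	y	z	q_ground	q_excited	alpha
C1	0	0	-0.35	-0.128571428571429	-0.178571428571429	0.0012
C2	0	0	-0.233333333333333	0.171428571428571	0.138095238095238	0.0012
C3	0	0	-0.116666666666667	-0.128571428571429	-0.145238095238095	0.0012
C4	0	0	0	0.171428571428571	0.171428571428571	0.0012
C5	0	0	0.116666666666667	-0.128571428571429	-0.111904761904762	0.0012
C6	0	0	0.233333333333333	0.171428571428571	0.204761904761905	0.0012
C7	0	0	0.35	-0.128571428571429	-0.0785714285714285	0.0012
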