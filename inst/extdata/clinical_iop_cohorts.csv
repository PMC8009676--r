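cohort,patient,eye,iop_before,iop_after
1,1,OD,23,16
1,2,OD,33,22
1,3,OD,36,28
1,4,OD,17,9
1,5,OS,17,11
1,6,OS,31,12
1,7,OS,25,16
1,8,OS,34,26
1,9,OD,25,19
1,9,OS,20,16
1,10,OS,26,15
1,11,OS,22,12
1,12,OD,28,20
1,12,OS,27,19
1,13,OD,21,15
1,14,OD,30,13
1,15,OS,15,13
1,16,OS,21,18
1,17,OD,12,10
1,18,OS,29,18
1,19,OD,18,17
2,20,OS,60,44
2,21,OS,17,12
2,22,OD,24,19
2,22,OS,24,18
2,23,OD,30,26
2,23,OS,33,22
2,24,OD,21,16
2,25,OD,28,18
2,26,OS,44,32
2,27,OD,22,16
2,27,OS,22,16
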