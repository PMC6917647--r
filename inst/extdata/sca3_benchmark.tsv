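# strdepth bundled validation cohort: 11 SCA3-positive patients
# columns: patient id, original molecular diagnosis, repeat-expansion
# prediction and p-value from the empirical-distribution caller (exSTRa),
# and the depth Z-score at the SCA3 locus from the method this package
# implements (threshold -0.91).
patient_id	original_diagnosis	exstra_prediction	exstra_p	zscore
2abac	SCA3	SCA2	1.00e-04	-2.00
3038b	SCA3	SCA3	3.00e-04	-2.59
A001	SCA3	SCA6,HD	1.00e-04	-0.86
A032	SCA3	NA	NA	-2.55
A039	SCA3	NA	NA	-1.28
A097	SCA3	NA	NA	-1.88
A115	SCA3	SCA2,SCA17	1.00e-04	-3.50
A140	SCA3	NA	NA	-0.45
B042	SCA3	SCA2,SCA17	2.00e-04	-0.92
B180	SCA3	SCA8	1.00e-04	-2.47
P126	SCA3	SCA17	1.00e-04	-2.31
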