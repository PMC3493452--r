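disease	covariates	coefficients	reference_means	affine
T2D	BMI,age	0.08,0.029	26.5,50	-1.38
T2D	BMI	0.08	26.5	-1.44
T2D	age	0.029	50	-1.28
prostate_cancer	age	0.049	50	-2.49
lung_cancer	age,smoking	0.03,2.6	50,0.25	-3.06
lung_cancer	age	0.04	50	-3.30
lung_cancer	smoking	2.04	0.25	-2.37
breast_cancer	age	0.032	50	-2.26
rheumatoid_arthritis	age,sex	0.022,0.32	50,0.5	-2.46
rheumatoid_arthritis	age	0.022	50	-2.46
rheumatoid_arthritis	sex	0.32	0.5	-2.34
ESKD	age	0.02	50	-2.08
AMD	age,BMI30	0.03,0.61	50,0.30	-2.00
AMD	age	0.04	50	-2.10
AMD	BMI30	0.35	0.30	-1.72
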