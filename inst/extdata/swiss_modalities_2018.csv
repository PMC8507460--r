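modality,frequency_per_1000,dose_vector_msv
conventional radiography,439,0.32
diagnostic mammography,21.1,0.36
screening mammography,11.8,0.36
dental radiography (without CBCT),584,0.02
CBCT,4.7,0.2
CT,135,7.08
conventional radioscopy,5.5,8
coronary angioplasty,6.2,14
other diagnostic interventional,3.7,8
PTCA,3,20
other therapeutic interventional,1.9,20
nuclear medicine,13.3,8.04
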