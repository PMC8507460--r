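modality,frequency_per_1000,dose_per_inhabitant_msv
conventional radiography,473,0.151
diagnostic mammography,20,0.007
screening mammography,11,0.004
dental radiography (without CBCT),572,0.011
CBCT,6,0.001
CT,117,1.000
conventional radioscopy,7,0.059
coronary angioplasty,6,0.080
other diagnostic interventional,2,0.017
PTCA,3,0.054
other therapeutic interventional,2,0.034
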