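modality,billing,ris
conventional radiography,439,421
CT,135,109
diagnostic mammography,21.1,19.1
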