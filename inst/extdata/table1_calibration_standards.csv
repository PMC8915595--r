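name,chi_ref,logk_iam_ref,retention_time_min
Octanophenone,49.4,4.97,4.37
Heptanophenone,45.7,4.30,4.17
Hexanophenone,41.8,3.71,3.93
Valerophenone,37.3,3.16,3.66
Butyrophenone,32.0,2.62,3.32
Propiophenone,25.9,2.15,2.90
Acetophenone,17.2,1.67,2.34
Acetanilide,11.5,1.45,2.04
Paracetamol,2.90,1.20,1.58
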