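name,acid_base_class,chi_reference,chi_new_reference
Carbamazepine,neutral,28.9,27.0
Colchicine,neutral,23.7,23.0
Warfarin,acidic,19.9,24.0
Indomethacin,acidic,32.5,30.0
Nicardipine,weak base,45.9,45.0
Propranolol,basic,45.1,42.0
Imipramine,basic,54.1,45.0
Ketoprofen,strong acid,21.9,20.0
Chlorpromazine,basic,61.9,54.0
Haloperidol,basic,44.3,48
Budesonide,neutral,38.7,38
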