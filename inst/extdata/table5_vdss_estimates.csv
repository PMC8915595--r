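name,acid_base_class,log_vdss_est_r20511,log_vdss_est_p20511,log_vdss_clinical
Acecainide,basic,-0.03,-0.03,0.1
Acetanilide,neutral,-0.12,-0.12,-0.13
Acetazolamide,neutral,-0.47,-0.47,-0.46
Alclofenac,acidic,-1.04,-1.02,-1.1
Amoxapine,basic,0.62,0.57,1.67
Bamethan,basic,0.01,0,0.01
Betamethasone,neutral,0.12,0.12,0.18
Carbamazepine,neutral,-0.07,-0.07,-0.09
Chlorpromazine,basic,0.88,0.82,2.15
Cinoxacin,acidic,-0.38,-0.37,-0.42
Colchicine,neutral,0.02,0.01,0.03
Cytarabine,weak base,-0.26,-0.26,-0.31
Diazoxide,weak acid,-0.19,-0.19,-0.16
Diclofenac,acidic,-0.6,-0.57,-0.67
Diprophylline,neutral,-0.22,-0.23,-0.24
Ethinyl estradiol,neutral,0.28,0.27,0.39
Famotidine,weak base,-0.04,-0.05,-0.06
Felbamate,neutral,0.07,0.07,-0.64
Felodipine,neutral,0.23,0.23,0.35
Fenoprofen,acidic,-1.02,-0.98,-1.27
Finasteride,neutral,0.21,0.21,0.3
Floxacillin,acidic,-0.55,-0.53,-0.56
Flumazenil,neutral,-0.04,-0.04,-0.04
Flurbiprofen,acidic,-1.44,-1.42,-1.56
Furosemide,acidic,-0.7,-0.68,-0.71
Gemfibrozil,acidic,-1.31,-1.27,-1.34
Glipizide,acidic,-0.69,-0.68,-0.73
Griseofulvin,neutral,0.04,0.03,0.12
Hydrochlorothiazide,weak acid,-0.18,-0.17,-0.13
Hydrocortisone,neutral,0.1,0.09,0.12
Imipramine,basic,0.66,0.6,1.16
Indomethacin,acidic,-0.72,-0.69,-0.96
Isradipine,neutral,0.08,0.08,0.13
Ketoconazole,weak base,0.12,0.1,0.32
Ketoprofen,acidic,-0.98,-0.96,-1.01
Labetalol,amphoteric,0.38,0.34,0.71
Lignocaine,basic,0.14,0.16,0.4
Methylprednisolone,neutral,0.12,0.11,0.16
Metronidazole,weak base,-0.24,-0.25,-0.25
Minoxidil,weak base,-0.11,-0.1,-0.04
Nabumetone,neutral,-0.09,-0.09,0.03
Nadolol,basic,-0.34,-0.35,-0.33
Nicardipine,weak base,0.32,0.32,0.47
Nifedipine,neutral,-0.07,-0.07,-0.04
Nitrendipine,neutral,0.08,0.08,0.16
Papaverine,weak base,-0.13,-0.13,0
Pentoxifylline,neutral,-0.07,-0.07,-0.1
Perphenazine,basic,0.66,0.61,1.35
Phenytoin,weak acid,-0.02,-0.02,0.03
Pindolol,basic,0.14,0.13,0.85
Prazosin,weak base,-0.11,-0.13,-0.05
Prednisolone,neutral,0.12,0.12,0.14
Prednisone,neutral,0.03,0.03,0.05
Primidone,neutral,-0.13,-0.13,-0.15
Probenecid,acidic,-0.66,-0.64,-0.75
Procainamide,basic,-0.13,-0.12,0.02
Propanolol,basic,0.64,0.59,1.29
Propylthiouracil,weak acid,-0.31,-0.31,-0.34
Proxyphylline,neutral,-0.75,-0.74,-0.85
Sulfachlorpyridazine,acidic,-0.71,-0.7,-0.76
Sulfameter,acidic,-0.57,-0.57,-0.61
Sulfamethoxypyridazine,weak acid,-0.57,-0.56,-0.59
Sulfinpyrazone,acidic,-0.64,-0.62,-0.65
Sulfisoxazole,acidic,-0.68,-0.67,-0.72
Sulphadimidine,amphoteric,-0.41,-0.41,0.22
Sulpiride,basic,-0.11,-0.1,0.12
Tamoxifen,basic,0.94,0.89,1.48
Theobromine,weak acid,-0.24,-0.25,-0.25
Tolfenamic Acid,acidic,-0.54,-0.49,-0.76
Trazodone,weak base,-0.09,-0.1,0.01
Trimethoprim,weak base,-0.05,-0.06,-0.06
Warfarin,acidic,-0.69,-0.68,-0.78
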