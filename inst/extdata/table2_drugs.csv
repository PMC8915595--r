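name,cas,acid_base_class,chi_iam_ref,log_vdss_clinical
Acecainide,32795-44-1,basic,23.3,0.10
Acetanilide,103-84-4,neutral,10.7,-0.13
Acetazolamide,59-66-5,neutral,1.7,-0.46
Alclofenac,22131-79-9,acidic,17.8,-1.10
Amoxapine,14028-44-5,basic,56.5,1.67
Bamethan,3703-79-5,basic,18.6,0.01
Betamethasone,378-44-9,neutral,31.7,0.18
Carbamazepine,298-46-4,neutral,26.5,-0.09
Chlorpromazine,50-53-3,basic,61.9,2.15
Cinoxacin,28657-80-9,acidic,1.6,-0.42
Colchicine,64-86-8,neutral,23.7,0.03
Cytarabine,147-94-4,weak base,-15.0,-0.31
Diazoxide,364-98-7,weak acid,24.7,-0.16
Diclofenac,15307-86-5,acidic,33.5,-0.67
Diprophylline,479-18-5,neutral,-4.0,-0.24
Ethinyl estradiol,57-63-6,neutral,46.8,0.39
Famotidine,76824-35-6,weak base,15.7,-0.06
Felbamate,25451-15-4,neutral,19.1,-0.64
Felodipine,72509-76-3,neutral,46.1,0.35
Fenoprofen,31879-05-7,acidic,17.2,-1.27
Finasteride,98319-26-7,neutral,38.9,0.30
Floxacillin,5250-39-5,acidic,23.4,-0.56
Flumazenil,78755-81-4,neutral,18.4,-0.04
Flurbiprofen,5104-49-4,acidic,26.8,-1.56
Furosemide,54-31-9,acidic,21.4,-0.71
Gemfibrozil,25812-30-0,acidic,32.9,-1.34
Glipizide,29094-61-9,acidic,21.1,-0.73
Griseofulvin,126-07-8,neutral,33.1,0.12
Hydrochlorothiazide,58-93-5,weak acid,15.9,-0.13
Hydrocortisone,50-23-7,neutral,27.9,0.12
Imipramine,50-49-7,basic,51.6,1.16
Indomethacin,53-86-1,acidic,25.3,-0.96
Isradipine,75695-93-1,neutral,40.0,0.13
Ketoconazole,65277-42-1,weak base,42.9,0.32
Ketoprofen,22071-15-4,acidic,21.9,-1.01
Labetalol,36894-69-6,amphoteric,43.9,0.71
Lignocaine,137-58-6,basic,32.6,0.40
Methylprednisolone,83-43-2,neutral,32.1,0.16
Metronidazole,443-48-1,weak base,-3.3,-0.25
Minoxidil,38304-91-5,weak base,19.0,-0.04
Nabumetone,42924-53-8,neutral,38.4,0.03
Nadolol,42200-33-9,basic,20.2,-0.33
Nicardipine,55985-32-5,weak base,45.9,0.47
Nifedipine,21829-25-4,neutral,29.0,-0.04
Nitrendipine,39562-70-4,neutral,40.5,0.16
Papaverine,58-74-2,weak base,34.4,0.00
Pentoxifylline,6493-05-6,neutral,12.0,-0.10
Perphenazine,58-39-9,basic,56.3,1.35
Phenytoin,57-41-0,weak acid,31.6,0.03
Pindolol,13523-86-9,basic,42.0,0.85
Prazosin,19216-56-9,weak base,31.6,-0.05
Prednisolone,50-24-8,neutral,28.0,0.14
Prednisone,53-03-2,neutral,25.9,0.05
Primidone,125-33-7,neutral,8.9,-0.15
Probenecid,57-66-9,acidic,20.1,-0.75
Procainamide,614-39-1,basic,19.9,0.02
Propanolol,525-66-6,basic,50.8,1.29
Propylthiouracil,51-52-5,weak acid,3.9,-0.34
Proxyphylline,603-00-9,neutral,1.1,-0.85
Sulfachlorpyridazine,80-32-0,acidic,6.0,-0.76
Sulfameter,651-06-9,acidic,3.7,-0.61
Sulfamethoxypyridazine,80-35-3,weak acid,9.6,-0.59
Sulfinpyrazone,57-96-5,acidic,26.1,-0.65
Sulfisoxazole,127-69-5,acidic,2.9,-0.72
Sulphadimidine,57-68-1,amphoteric,34.6,0.22
Sulpiride,15676-16-1,basic,25.5,0.12
Tamoxifen,10540-29-1,basic,58.7,1.48
Theobromine,83-67-0,weak acid,-4.1,-0.25
Tolfenamic Acid,13710-19-5,acidic,36.6,-0.76
Trazodone,19794-93-5,weak base,36.3,0.01
Trimethoprim,738-70-5,weak base,20.8,-0.06
Warfarin,81-81-2,acidic,19.9,-0.78
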