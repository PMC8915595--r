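name,chi_iam_ref,chi_iam_r20511,chi_iam_p20511,logk_hsa_ref,logk_hsa_new,suspect
Acecainide,23.3,17.72,17.57,0.69,0.52,
Acetanilide,10.7,11.55,11.5,0.62,0.43,
Acetazolamide,1.66,0.99,0.74,1.47,1.44,
Alclofenac,17.8,20.47,21.63,5.11,5.4,
Amoxapine,56.5,45.41,44.74,2.15,2.7,
Bamethan,18.6,18.53,18.03,0.49,0.42,
Betamethasone,31.7,30.18,30.05,1.09,1.39,
Carbamazepine,26.5,27.18,27.07,1.99,1.81,
Chlorpromazine,61.9,51.54,50.94,1.18,1.27,hsa_new_missing
Cinoxacin,1.6,5.31,6.67,0.79,0.91,hsa_new_shifted
Colchicine,23.7,23.45,23.18,0.69,0.24,hsa_new_shifted
Cytarabine,-15,-6.76,-6.99,1.59,1.87,hsa_new_shifted
Diazoxide,24.7,23.39,23.44,5.42,5.58,hsa_new_shifted
Diclofenac,33.5,35.18,35.85,0.63,0.24,hsa_new_shifted
Diprophylline,-4,-1.49,-1.98,4.1,4.24,hsa_new_shifted
Ethinyl Estradiol,46.8,45.3,45.23,0.46,0.5,hsa_new_shifted
Famotidine,15.7,16.82,16.08,1.39,3.43,hsa_new_shifted
Felbamate,19.07,39.16,39.21,3.46,4.15,hsa_new_shifted chi_ref_inconsistent
Felodipine,46.1,44.37,44.45,5.91,6.11,hsa_new_shifted
Fenoprofen,17.2,27.17,28.26,1.58,2.32,hsa_new_shifted
Finasteride,38.9,37.15,37.17,3.62,3.55,hsa_new_shifted
Floxacillin,23.4,23.76,24.59,0.56,0.65,hsa_new_shifted
Flumazenil,18.4,18.27,18.27,7.81,8.5,hsa_new_shifted
Flurbiprofen,26.8,30.23,30.89,1.26,4.01,hsa_new_shifted
Furosemide,21.41,21.96,22.69,3.64,8.5,hsa_new_shifted
Gemfibrozil,32.9,33.7,34.53,3.32,4.05,hsa_new_shifted
Glipizide,21.1,22.82,23.22,1.49,1.92,hsa_new_shifted
Griseofulvin,33.1,31.06,30.98,0.77,0.8,hsa_new_shifted
Hydrochlorothiazide,15.9,13.04,13.08,0.92,1.05,hsa_new_shifted
Hydrocortisone,27.9,27.23,27.02,1.95,2.59,hsa_new_shifted
Imipramine,51.6,45.58,44.81,6.17,5.59,hsa_new_shifted
Indomethacin,25.3,32.49,33.16,2.86,3.36,hsa_new_shifted chi_ref_conflicts_suitability_table
Isradipine,40,39.11,39.16,2.9,3.3,hsa_new_shifted
Ketoconazole,42.9,39.5,39.26,4.8,5.4,hsa_new_shifted
Ketoprofen,21.9,22.93,23.89,1.28,1.8,hsa_new_shifted
Labetalol,43.9,38.29,37.48,0.69,0.52,hsa_new_shifted
Lignocaine,32.6,24.89,25.53,1.35,1.53,hsa_new_shifted
Methylprednisolone,32.1,30.91,30.77,0.76,0.28,hsa_new_shifted
Metronidazole,-3.3,-2.71,-3.24,0.66,0.72,hsa_new_shifted
Minoxidil,19,15.93,16.08,3.16,3.41,hsa_new_shifted
Nabumetone,38.4,35.9,35.96,0.49,2.14,hsa_new_shifted
Nadolol,20.2,19.89,19.23,2.93,3.55,hsa_new_shifted
Nicardipine,45.9,43.82,43.73,1.41,1.95,hsa_new_shifted
Nifedipine,29,28.11,28.16,3.13,3.37,hsa_new_shifted
Nitrendipine,40.5,39.06,39.19,2.35,2.7,hsa_new_shifted
Papaverine,34.4,31.22,31.15,0.63,0.39,hsa_new_shifted
Pentoxifylline,12,14.04,13.87,3.27,4.03,hsa_new_shifted
Perphenazine,56.3,49.57,48.97,1.6,2.02,hsa_new_shifted
Phenytoin,31.6,30.18,30.2,0.54,0.63,hsa_new_shifted
Pindolol,42,25.69,25.31,1.81,2.4,hsa_new_shifted
Prazosin,31.6,29.82,29.35,0.89,0.95,hsa_new_shifted
Prednisolone,28,27.31,27.2,0.8,1.08,hsa_new_shifted
Prednisone,25.9,25.25,25.13,0.62,0.42,hsa_new_shifted
Primidone,8.9,10.31,10.49,3.44,4.01,hsa_new_shifted
Probenecid,20.1,23.45,24.38,0.76,0.49,hsa_new_shifted
Procainamide,19.9,11.73,11.89,0.73,1.67,hsa_new_shifted
Propranolol,50.8,42.24,41.46,0.63,1.02,hsa_new_shifted
Propylthiouracil,3.9,6.56,6.52,2.67,3.21,hsa_new_shifted
Proxyphylline,1.1,10.05,10.89,1.97,3.02,hsa_new_shifted
Sulfachlorpyridazine,6,10.08,10.83,2.04,2.2,hsa_new_shifted
Sulfameter,3.7,6.92,7.09,4.09,2.44,hsa_new_shifted
Sulfamethoxypyridazine,9.6,11.11,11.16,2.33,4.27,hsa_new_shifted
Sulfinpyrazone,26.1,26.19,26.89,3.17,2.66,hsa_new_shifted
Sulfisoxazole,2.9,6.48,7.37,1.54,3.68,hsa_new_shifted
Sulphadimidine,34.55,10.89,11.09,0.75,1.72,chi_ref_inconsistent
Sulpiride,25.5,15.8,16.15,4.84,0.71,
Tamoxifen,58.7,54.23,53.78,1.29,4.82,
Theobromine,-4.1,-3.16,-3.71,4.68,0.27,
Tolfenamic Acid,36.6,40.72,41.53,2.46,6.6,
Trazodone,36.3,34.09,33.86,0.8,3.06,
Trimethoprim,20.8,20.99,20.52,4.45,0.95,
Warfarin,19.9,23.47,24.18,0.7,4.16,
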