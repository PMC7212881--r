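type,class,n,cars_correct,tpef_correct,shg_correct,combined_correct
Astrocytoma WHO I + II,tumor,14,9,14,3,14
Astrocytoma WHO III,tumor,36,28,28,19,30
Oligodendroglioma WHO III,tumor,20,15,19,7,17
GBM,tumor,45,39,44,15,45
Recurrent GBM,tumor,18,13,16,10,18
Metastasis of colon cancer,tumor,12,12,12,12,12
Metastasis of lung cancer,tumor,23,22,22,17,23
Metastasis of renal cancer,tumor,10,9,10,9,10
Metastasis of breast cancer,tumor,12,12,12,9,12
Metastasis of melanoma,tumor,14,13,13,10,14
Nontumor brain,nontumor,14,13,12,13,14
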