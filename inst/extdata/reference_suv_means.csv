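subject,group,condition,region,suv
anesthetized_mean,anesthetized,test,cortex,2.51
anesthetized_mean,anesthetized,retest,cortex,2.70
anesthetized_mean,anesthetized,memantine,cortex,3.32
anesthetized_mean,anesthetized,test,caudate_putamen,3.08
anesthetized_mean,anesthetized,retest,caudate_putamen,3.36
anesthetized_mean,anesthetized,memantine,caudate_putamen,4.34
anesthetized_mean,anesthetized,test,thalamus,3.50
anesthetized_mean,anesthetized,retest,thalamus,3.81
anesthetized_mean,anesthetized,memantine,thalamus,4.08
anesthetized_mean,anesthetized,test,hippocampus,2.90
anesthetized_mean,anesthetized,retest,hippocampus,3.18
anesthetized_mean,anesthetized,memantine,hippocampus,4.01
anesthetized_mean,anesthetized,test,cerebellum,2.81
anesthetized_mean,anesthetized,retest,cerebellum,3.16
anesthetized_mean,anesthetized,memantine,cerebellum,3.41
awake_mean,awake,test,cortex,2.10
awake_mean,awake,retest,cortex,2.06
awake_mean,awake,memantine,cortex,3.38
awake_mean,awake,test,caudate_putamen,2.57
awake_mean,awake,retest,caudate_putamen,2.50
awake_mean,awake,memantine,caudate_putamen,4.29
awake_mean,awake,test,thalamus,2.81
awake_mean,awake,retest,thalamus,2.79
awake_mean,awake,memantine,thalamus,4.33
awake_mean,awake,test,hippocampus,2.45
awake_mean,awake,retest,hippocampus,2.41
awake_mean,awake,memantine,hippocampus,4.24
awake_mean,awake,test,cerebellum,2.27
awake_mean,awake,retest,cerebellum,2.25
awake_mean,awake,memantine,cerebellum,3.56
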