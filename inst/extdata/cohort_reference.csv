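group,method,dsc,jsc,svd,voe
noise_rate,baseline_noise0,75.09,63.18,24.91,36.82
noise_rate,baseline_noise50,73.21,61.61,26.79,38.39
noise_rate,baseline_noise100,70.55,58.86,29.45,41.14
comparison,mean_teacher,78.50,66.74,21.50,33.26
comparison,proposed,80.29,68.68,19.71,31.32
ablation,baseline,75.09,63.18,24.91,36.82
ablation,noise_adaptor,78.08,66.08,21.92,33.92
ablation,mpvt,79.27,67.25,20.73,32.75
ablation,wo_input_pert,78.55,66.85,21.45,33.15
ablation,wo_feature_pert,78.42,66.44,21.58,33.56
ablation,one_teacher,77.92,65.74,22.08,34.26
ablation,proposed,80.29,68.68,19.71,31.32
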