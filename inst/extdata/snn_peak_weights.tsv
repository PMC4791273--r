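comparison	peak_mz	weight	auc
normal_vs_carcinoma	2434	0.0212	NA
normal_vs_carcinoma	3008	0.0489	NA
normal_vs_carcinoma	3334	0.0247	NA
normal_vs_carcinoma	3376	0.0580	0.80
normal_vs_carcinoma	3448	0.0760	NA
normal_vs_carcinoma	5150	0.0347	NA
normal_vs_carcinoma	6203	0.0270	NA
normal_vs_carcinoma	6663	0.0501	0.86
normal_vs_carcinoma	7017	0.0381	NA
normal_vs_carcinoma	8581	0.0763	0.88
normal_vs_carcinoma	9274	0.0375	NA
normal_vs_carcinoma	20804	0.0415	NA
normal_vs_carcinoma	22238	0.0334	NA
normal_vs_carcinoma	22533	0.0338	NA
normal_vs_carcinoma	22738	0.0392	NA
diploid_vs_aneuploid	2395	0.1311	0.80
diploid_vs_aneuploid	4761	0.0693	NA
diploid_vs_aneuploid	4798	0.0553	NA
diploid_vs_aneuploid	4977	0.0667	0.81
diploid_vs_aneuploid	6501	0.0249	NA
diploid_vs_aneuploid	6585	0.1204	NA
diploid_vs_aneuploid	6663	0.0774	NA
diploid_vs_aneuploid	7765	0.0358	NA
diploid_vs_aneuploid	7801	0.0273	NA
diploid_vs_aneuploid	8787	0.0537	NA
diploid_vs_aneuploid	12297	0.0245	NA
diploid_vs_aneuploid	15719	0.0298	NA
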