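"family","parameter","segment","b","censored"
"within","HR","Q1",1000,TRUE
"within","HR","R1",1000,TRUE
"within","HR","Q2",1000,TRUE
"within","HR","R2a",106.23,FALSE
"within","HR","R2b",0.26,FALSE
"within","HR","R2c",0.46,FALSE
"within","HR","R2d",0.28,FALSE
"within","HR","R2e",1.98,FALSE
"within","HR","R2f",24.15,FALSE
"within","MAP","R1",0.17,FALSE
"within","MAP","R2f",0.22,FALSE
"within","lnHF","Q1",1000,TRUE
"within","lnHF","R1",0.31,FALSE
"within","lnHF","Q2",1000,TRUE
"within","lnHF","R2a",0.54,FALSE
"within","lnHF","R2b",5.07,FALSE
"within","lnHF","R2c",2.31,FALSE
"within","lnHF","R2d",11.65,FALSE
"within","lnHF","R2e",3.1,FALSE
"within","lnHF","R2f",19.31,FALSE
"within","lnLF","Q1",0.45,FALSE
"within","lnLF","R1",1.52,FALSE
"within","lnLF","Q2",1.04,FALSE
"within","lnLF","R2a",6.01,FALSE
"within","lnLF","R2b",0.18,FALSE
"within","lnLF","R2c",0.16,FALSE
"within","lnLF","R2d",0.21,FALSE
"within","lnLF","R2e",0.16,FALSE
"within","lnLF","R2f",0.23,FALSE
"within","RR","Q1",1000,TRUE
"within","RR","R1",0.34,FALSE
"within","RR","Q2",1000,TRUE
"within","RR","R2a",0.16,FALSE
"within","RR","R2b",0.52,FALSE
"within","RR","R2c",17.89,FALSE
"within","RR","R2d",3.58,FALSE
"within","RR","R2e",0.54,FALSE
"within","RR","R2f",0.15,FALSE
"within","NSFR","Q1",1000,TRUE
"within","NSFR","R1",0.18,FALSE
"within","NSFR","Q2",1000,TRUE
"within","NSFR","R2a",0.17,FALSE
"within","NSFR","R2b",0.36,FALSE
"within","NSFR","R2c",0.27,FALSE
"within","NSFR","R2d",0.2,FALSE
"within","NSFR","R2e",0.15,FALSE
"within","NSFR","R2f",0.35,FALSE
"within","PEP","Q1",0.36,FALSE
"within","PEP","R1",0.15,FALSE
"within","PEP","Q2",0.37,FALSE
"within","PEP","R2a",0.16,FALSE
"within","PEP","R2b",0.2,FALSE
"within","PEP","R2c",0.15,FALSE
"within","PEP","R2d",0.18,FALSE
"within","PEP","R2e",0.18,FALSE
"within","PEP","R2f",0.15,FALSE
"within","CO","Q1",0.2,FALSE
"within","CO","R1",0.19,FALSE
"within","CO","Q2",0.3,FALSE
"within","CO","R2a",0.15,FALSE
"within","CO","R2b",0.16,FALSE
"within","CO","R2c",0.15,FALSE
"within","CO","R2d",0.15,FALSE
"within","CO","R2e",0.15,FALSE
"within","CO","R2f",0.15,FALSE
"within","TPR","Q1",0.4,FALSE
"within","TPR","R1",1.12,FALSE
"within","TPR","Q2",0.15,FALSE
"within","TPR","R2a",0.27,FALSE
"within","TPR","R2b",0.25,FALSE
"within","TPR","R2c",0.17,FALSE
"within","TPR","R2d",0.16,FALSE
"within","TPR","R2e",0.15,FALSE
"within","TPR","R2f",0.18,FALSE
"between","HR","Q1",0.15,FALSE
"between","HR","R1",0.15,FALSE
"between","HR","Q2",0.16,FALSE
"between","HR","R2a",0.16,FALSE
"between","HR","R2b",0.16,FALSE
"between","HR","R2c",0.21,FALSE
"between","HR","R2d",0.19,FALSE
"between","HR","R2e",0.22,FALSE
"between","HR","R2f",0.2,FALSE
"between","MAP","R1",0.37,FALSE
"between","MAP","R2f",1.01,FALSE
"between","lnHF","Q1",0.23,FALSE
"between","lnHF","R1",0.17,FALSE
"between","lnHF","Q2",0.15,FALSE
"between","lnHF","R2a",0.16,FALSE
"between","lnHF","R2b",0.15,FALSE
"between","lnHF","R2c",0.26,FALSE
"between","lnHF","R2d",0.15,FALSE
"between","lnHF","R2e",0.17,FALSE
"between","lnHF","R2f",0.34,FALSE
"between","lnLF","Q1",0.24,FALSE
"between","lnLF","R1",0.21,FALSE
"between","lnLF","Q2",0.33,FALSE
"between","lnLF","R2a",0.3,FALSE
"between","lnLF","R2b",0.17,FALSE
"between","lnLF","R2c",0.15,FALSE
"between","lnLF","R2d",0.16,FALSE
"between","lnLF","R2e",0.17,FALSE
"between","lnLF","R2f",0.53,FALSE
"between","RR","Q1",0.21,FALSE
"between","RR","R1",0.21,FALSE
"between","RR","Q2",0.16,FALSE
"between","RR","R2a",0.15,FALSE
"between","RR","R2b",0.15,FALSE
"between","RR","R2c",0.15,FALSE
"between","RR","R2d",0.16,FALSE
"between","RR","R2e",0.15,FALSE
"between","RR","R2f",0.16,FALSE
"between","NSFR","Q1",0.15,FALSE
"between","NSFR","R1",0.17,FALSE
"between","NSFR","Q2",0.17,FALSE
"between","NSFR","R2a",0.15,FALSE
"between","NSFR","R2b",0.15,FALSE
"between","NSFR","R2c",0.18,FALSE
"between","NSFR","R2d",0.16,FALSE
"between","NSFR","R2e",0.17,FALSE
"between","NSFR","R2f",0.23,FALSE
"between","PEP","Q1",0.16,FALSE
"between","PEP","R1",0.15,FALSE
"between","PEP","Q2",0.16,FALSE
"between","PEP","R2a",0.16,FALSE
"between","PEP","R2b",0.15,FALSE
"between","PEP","R2c",0.17,FALSE
"between","PEP","R2d",0.25,FALSE
"between","PEP","R2e",0.2,FALSE
"between","PEP","R2f",0.15,FALSE
"between","CO","Q1",0.25,FALSE
"between","CO","R1",0.22,FALSE
"between","CO","Q2",0.24,FALSE
"between","CO","R2a",0.29,FALSE
"between","CO","R2b",0.17,FALSE
"between","CO","R2c",0.33,FALSE
"between","CO","R2d",0.28,FALSE
"between","CO","R2e",0.22,FALSE
"between","CO","R2f",0.27,FALSE
"between","TPR","Q1",0.15,FALSE
"between","TPR","R1",0.15,FALSE
"between","TPR","Q2",0.17,FALSE
"between","TPR","R2a",0.15,FALSE
"between","TPR","R2b",0.96,FALSE
"between","TPR","R2c",0.15,FALSE
"between","TPR","R2d",0.17,FALSE
"between","TPR","R2e",0.15,FALSE
"between","TPR","R2f",0.29,FALSE
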