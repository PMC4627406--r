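"variable","anti_min","anti_min_open","anti_max","anti_max_open","pos_min","pos_min_open","pos_max","pos_max_open"
"Age",-Inf,FALSE,64,FALSE,65,FALSE,Inf,FALSE
"N_F_Pred",0,FALSE,0,FALSE,1,FALSE,Inf,FALSE
"N_F_Risk",0,FALSE,0,FALSE,1,FALSE,Inf,FALSE
"Previous DVT",0,FALSE,0,FALSE,1,FALSE,1,FALSE
"Palpitations",0,FALSE,0,FALSE,1,FALSE,1,FALSE
"Cough",0,FALSE,0,FALSE,1,FALSE,1,FALSE
"dDimer",-Inf,FALSE,230,FALSE,230,TRUE,Inf,FALSE
"FC",50,FALSE,99,FALSE,100,FALSE,Inf,FALSE
"WBC",2000,FALSE,10000,TRUE,10000,FALSE,Inf,FALSE
"Cancer at diagnosis",0,FALSE,0,FALSE,1,FALSE,1,FALSE
"Shockindex",0,FALSE,0.89,FALSE,0.9,FALSE,Inf,FALSE
"Cancer",0,FALSE,0,FALSE,1,FALSE,1,FALSE
"RVD",0,FALSE,0,FALSE,1,FALSE,1,FALSE
"Dyspnea",0,FALSE,0,FALSE,1,FALSE,1,FALSE
"Chest pain",0,FALSE,0,FALSE,1,FALSE,1,FALSE
"PCO2",35,FALSE,45,FALSE,45,TRUE,Inf,FALSE
"PO2",-Inf,FALSE,60,FALSE,60,TRUE,Inf,FALSE
"PH",7.3,FALSE,7.42,FALSE,7.42,TRUE,Inf,FALSE
"Hemoptysis",0,FALSE,0,FALSE,1,FALSE,1,FALSE
"Final diagnosis",0,FALSE,0,FALSE,1,FALSE,1,FALSE
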