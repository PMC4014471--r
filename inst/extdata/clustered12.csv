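0.014640728615858335,-0.46277944200728266,-0.90392815680558503,0.037151413754138322,-0.50558580331589942,-0.87212869287401051,-0.0001986544451423533,-0.48664215013564655,-0.96404697724110255,0.02689970016987377,-0.48626621266384418,-0.91611498227905985
-0.010447968056714494,2.221505136167587,4.4210914033776509,-0.0042011096937585998,2.2727215026783867,4.3785000239227312,-0.033805630161719766,2.2574506102717775,4.5005063353140287,-0.063417694339618066,2.1786612429052155,4.5067973376813519
0.092904619490467993,0.89420287227832274,1.8124899077376042,-0.039644725827974583,1.0043430156559143,1.7796389830882102,-0.052481413764174416,0.91683779212375804,1.7303778249313935,0.03202599138996455,0.86380183095393059,1.7520536375734443
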