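"a","b","ab","kd","tau","kf","kb","group","provenance","note"
"DA","D1R","DAD1R",2,1,NA,NA,"b.da_d1r","literature",""
"Golfact","AC5","AC5act",0.6,20,NA,NA,"b.golf_ac5","literature/tuned",""
"Ca","AC5act","AC5actCa",1,0.2,NA,NA,"b.ca_ac5act","literature/tuned",""
"cAMP","PKA","PKAcAMP",2,0.2,NA,NA,"b.camp_pka1","literature",""
"cAMP","PKAcAMP","PKAc",0.5,0.2,NA,NA,"b.camp_pka2","literature",""
"Ca","AC5","AC5Ca",2,0.2,NA,NA,"b.ca_ac5","literature/tuned",""
"CaMCa4","PDE","PDECaM",0.5,1,NA,NA,"b.cam_pde","literature/tuned",""
"Ca","CaM","CaMCa1",16,0.05,NA,NA,"b.cam1","literature",""
"Ca","CaMCa1","CaMCa2",6,0.05,NA,NA,"b.cam2","literature",""
"Ca","CaMCa2","CaMCa3",1.5,0.05,NA,NA,"b.cam3","literature",""
"Ca","CaMCa3","CaMCa4",0.4,0.05,NA,NA,"b.cam4","literature",""
"CaMCa4","PP2B","PP2Bact",0.002,8,NA,NA,"b.cam_pp2b","literature",""
"CaMCa4","CaMKII","CaMKIICaM",0.4,1,NA,NA,"b.cam_camkii","literature",""
"Ca","PP2A","PP2ACa",10,0.3,NA,NA,"b.ca_pp2a","literature",""
"D75","PKAc","D75PKAc",0.033,3,NA,NA,"b.d75_pka","literature/tuned","PKA inhibition by phospho-Thr75; Kd varied in robustness scans"
"D75_137","PKAc","D75_137PKAc",0.033,3,NA,NA,"b.d75s137_pka","literature/tuned",""
"D34","PP1","D34PP1",0.4,10,NA,NA,"b.d34_pp1","literature",""
"D34_137","PP1","D34_137PP1",0.4,10,NA,NA,"b.d34s137_pp1","literature/tuned",""
"I1p","PP1","I1pPP1",0.3,10,NA,NA,"b.i1p_pp1","literature",""
"AMPARp845","Anchor","AMPARp845m",0.2,30,NA,NA,"b.a845_anchor","literature/tuned",""
"AMPARpp","Anchor","AMPARppm",0.05,60,NA,NA,"b.app_anchor","literature/tuned",""
"AMPAR","Anchor","AMPARm",5,10,NA,NA,"b.a_anchor","tuned",""
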