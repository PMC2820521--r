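"enzyme","substrate","product","km","kcat","kf","kb","group","provenance","note"
"DAD1R","Golf","Golfact",2,4,NA,NA,"e.golf_act","literature/tuned","dopamine-bound receptor catalytically activates Golf"
"PP2C","Golfact","Golf",2,1,NA,NA,"e.golf_gap","tuned",""
"AC5act","ATP","cAMP",1000,1.2,NA,NA,"e.ac5act","literature",""
"AC5","ATP","cAMP",1000,0.005,NA,NA,"e.ac5basal","literature/tuned",""
"PDE","cAMP","AMP",5,0.5,NA,NA,"e.pde","literature",""
"PDEp","cAMP","AMP",5,2,NA,NA,"e.pdep","literature/tuned",""
"PDECaM","cAMP","AMP",5,4,NA,NA,"e.pdecam","literature/tuned",""
"PKAc","PDE","PDEp",2,2,NA,NA,"e.pka_pde","literature/tuned",""
"PP2C","PDEp","PDE",5,0.5,NA,NA,"e.pp2c_pdep","literature/tuned",""
"CaMKIICaM","CaMKIICaM","CaMKIIpCaM",10,1,NA,NA,"e.camkii_auto","literature",""
"CaMKIIpCaM","CaMKIICaM","CaMKIIpCaM",5,5,NA,NA,"e.camkii_inter","literature",""
"PP1","CaMKIIpCaM","CaMKIICaM",1,0.05,NA,NA,"e.pp1_camkii","literature",""
"PKAc","PP2A","PP2Ap",1,3,NA,NA,"e.pka_pp2a","literature/tuned","kcat varied in robustness scans"
"PP2C","PP2Ap","PP2A",0.1,0.125,NA,NA,"e.pp2c_pp2ap","literature",""
"CK1","CK1","CK1p",3,0.4,NA,NA,"e.ck1_auto","literature/tuned",""
"PP2Bact","CK1p","CK1",4,8,NA,NA,"e.pp2b_ck1","literature/tuned",""
"CK1","Cdk5","Cdk5act",2,2,NA,NA,"e.ck1_cdk5","literature/tuned","CK1->Cdk5 collapsed to a single enzymatic reaction"
"PP2C","Cdk5act","Cdk5",2,0.22,NA,NA,"e.pp2c_cdk5","literature",""
"PKAc","D000","D34",6,0.1,NA,NA,"e.pka_t34","literature",""
"PKAc","D137","D34_137",6,0.1,NA,NA,"e.pka_t34","literature",""
"PKAc","D75","D34_75",6,0.05,NA,NA,"e.pka_t34_p75","literature/tuned",""
"PKAc","D75_137","D34_75_137",6,0.05,NA,NA,"e.pka_t34_p75","literature/tuned",""
"PP2Bact","D34","D000",10,6,NA,NA,"e.pp2b_t34","literature",""
"PP2Bact","D34_75","D75",10,6,NA,NA,"e.pp2b_t34","literature",""
"PP2Bact","D34_137","D137",10,0.6,NA,NA,"e.pp2b_t34_s137","literature/tuned",""
"PP2Bact","D34_75_137","D75_137",10,0.6,NA,NA,"e.pp2b_t34_s137","literature/tuned",""
"Cdk5act","D000","D75",2,4,NA,NA,"e.cdk5_t75","literature/tuned",""
"Cdk5act","D137","D75_137",2,4,NA,NA,"e.cdk5_t75_s137","literature/tuned",""
"PP2ACa","D75","D000",0.5,12,NA,NA,"e.pp2aca_t75","literature/tuned",""
"PP2ACa","D75_137","D137",0.5,12,NA,NA,"e.pp2aca_t75_s137","literature/tuned",""
"PP2Ap","D75","D000",0.5,18,NA,NA,"e.pp2ap_t75","literature/tuned","kcat varied in robustness scans"
"PP2Ap","D75_137","D137",0.5,18,NA,NA,"e.pp2ap_t75_s137","tuned",""
"CK1","D000","D137",8,0.3,NA,NA,"e.ck1_s137","literature/tuned",""
"CK1","D75","D75_137",8,0.3,NA,NA,"e.ck1_s137_p75","tuned",""
"PP2C","D137","D000",8,3,NA,NA,"e.pp2c_s137","literature",""
"PP2C","D34_137","D34",8,3,NA,NA,"e.pp2c_s137","literature",""
"PP2C","D75_137","D75",8,3,NA,NA,"e.pp2c_s137_p75","tuned",""
"PP2C","D34_75_137","D34_75",8,3,NA,NA,"e.pp2c_s137_p75","tuned",""
"PKAc","I1","I1p",4,0.8,NA,NA,"e.pka_i1","literature",""
"PP2Bact","I1p","I1",3,1,NA,NA,"e.pp2b_i1p","literature",""
"PKAc","AMPAR","AMPARp845",2,0.4,NA,NA,"e.pka_s845","literature",""
"CaMKIIpCaM","AMPARp845m","AMPARppm",2,2,NA,NA,"e.camkii_s831","literature",""
"PP1","AMPARp845","AMPAR",2,0.03,NA,NA,"e.pp1_s845","literature",""
"PP1","AMPARpp","AMPARp845",2,0.03,NA,NA,"e.pp1_s831","literature/tuned",""
"PP2ACa","AMPARp845","AMPAR",2,0.03,NA,NA,"e.pp2a_s845","literature/tuned",""
"PP2ACa","AMPARpp","AMPARp845",2,0.03,NA,NA,"e.pp2a_s831","tuned",""
"PP1","AMPARp845m","AMPARm",2,0.02,NA,NA,"e.pp1_s845m","tuned",""
"PP1","AMPARppm","AMPARp845m",2,0.02,NA,NA,"e.pp1_s831m","tuned",""
"Traffic","AMPAR","AMPARbulk",20,2,NA,NA,"e.traffic_out","tuned",""
"Traffic","AMPARbulk","AMPAR",20,0.5,NA,NA,"e.traffic_in","tuned",""
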