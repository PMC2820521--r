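"species","conc","clamped","note"
"Ca",0.06,TRUE,"input: free calcium, forced waveform"
"DA",0.003,TRUE,"input: extracellular dopamine, forced waveform"
"ATP",2000,TRUE,"constant nucleotide pool"
"Traffic",0.5,TRUE,"constitutive trafficking carrier"
"D1R",1,FALSE,""
"DAD1R",0,FALSE,""
"Golf",2,FALSE,""
"Golfact",0,FALSE,""
"AC5",2.5,FALSE,""
"AC5act",0,FALSE,""
"AC5Ca",0,FALSE,""
"AC5actCa",0,FALSE,""
"cAMP",0.4,FALSE,""
"AMP",0,TRUE,"hydrolysis product sink"
"PKA",1.2,FALSE,""
"PKAcAMP",0,FALSE,""
"PKAc",0,FALSE,""
"PDE",1.2,FALSE,""
"PDEp",0.8,FALSE,""
"PDECaM",0,FALSE,""
"CaM",10,FALSE,""
"CaMCa1",0,FALSE,""
"CaMCa2",0,FALSE,""
"CaMCa3",0,FALSE,""
"CaMCa4",0,FALSE,""
"PP2B",2,FALSE,""
"PP2Bact",0,FALSE,""
"CaMKII",16,FALSE,""
"CaMKIICaM",0,FALSE,""
"CaMKIIpCaM",0,FALSE,""
"PP2A",4,FALSE,""
"PP2ACa",0,FALSE,""
"PP2Ap",0,FALSE,""
"PP1",2,FALSE,""
"PP2C",2,FALSE,""
"CK1",0.2,FALSE,""
"CK1p",0.8,FALSE,""
"Cdk5",1.65,FALSE,""
"Cdk5act",0.15,FALSE,""
"D000",25,FALSE,"DARPP-32, unphosphorylated"
"D34",0,FALSE,""
"D75",25,FALSE,"DARPP-32 phospho-Thr75"
"D137",0,FALSE,""
"D34_75",0,FALSE,""
"D34_137",0,FALSE,""
"D75_137",0,FALSE,""
"D34_75_137",0,FALSE,""
"D75PKAc",0,FALSE,""
"D75_137PKAc",0,FALSE,""
"D34PP1",0,FALSE,""
"D34_137PP1",0,FALSE,""
"I1",1.5,FALSE,""
"I1p",0,FALSE,""
"I1pPP1",0,FALSE,""
"AMPAR",1,FALSE,""
"AMPARp845",0,FALSE,""
"AMPARpp",0,FALSE,""
"Anchor",2,FALSE,""
"AMPARm",0,FALSE,""
"AMPARp845m",0,FALSE,""
"AMPARppm",0,FALSE,""
"AMPARbulk",4,FALSE,""
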