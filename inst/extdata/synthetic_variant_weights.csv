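"variant_id","risk_allele","beta","is_major"
"rs570618","T",0.87,TRUE
"rs10922109","A",-0.97,TRUE
"rs429608","G",-0.56,TRUE
"rs3750846","T",1.03,TRUE
"rs2230199","C",0.35,TRUE
"rsSIM001","A",0.139,FALSE
"rsSIM002","A",0.225,FALSE
"rsSIM003","A",-0.399,FALSE
"rsSIM004","C",-0.173,FALSE
"rsSIM005","A",-0.009,FALSE
"rsSIM006","T",-0.022,FALSE
"rsSIM007","T",-0.153,FALSE
"rsSIM008","T",0.212,FALSE
"rsSIM009","C",0.14,FALSE
"rsSIM010","G",0.013,FALSE
"rsSIM011","C",0.226,FALSE
"rsSIM012","T",-0.187,FALSE
"rsSIM013","T",-0.054,FALSE
"rsSIM014","G",0.149,FALSE
"rsSIM015","A",0.26,FALSE
"rsSIM016","A",0.273,FALSE
"rsSIM017","G",0.05,FALSE
"rsSIM018","T",-0.085,FALSE
"rsSIM019","G",0.297,FALSE
"rsSIM020","T",-0.239,FALSE
"rsSIM021","G",0.18,FALSE
"rsSIM022","G",0.008,FALSE
"rsSIM023","G",0.129,FALSE
"rsSIM024","A",-0.042,FALSE
"rsSIM025","G",-0.083,FALSE
"rsSIM026","C",-0.084,FALSE
"rsSIM027","A",0.014,FALSE
"rsSIM028","G",0.001,FALSE
"rsSIM029","A",0.162,FALSE
"rsSIM030","T",0.198,FALSE
"rsSIM031","T",-0.176,FALSE
"rsSIM032","G",-0.131,FALSE
"rsSIM033","T",-0.066,FALSE
"rsSIM034","G",0.065,FALSE
"rsSIM035","T",0.047,FALSE
"rsSIM036","G",0.028,FALSE
"rsSIM037","A",0.238,FALSE
"rsSIM038","C",0.418,FALSE
"rsSIM039","C",-0.007,FALSE
"rsSIM040","T",0.215,FALSE
"rsSIM041","A",0.034,FALSE
"rsSIM042","G",-0.224,FALSE
"rsSIM043","G",0.052,FALSE
"rsSIM044","T",-0.048,FALSE
"rsSIM045","A",0.06,FALSE
"rsSIM046","T",0.021,FALSE
"rsSIM047","T",0.01,FALSE
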