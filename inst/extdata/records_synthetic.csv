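"age","sex","year","icd_version","underlying_cause","cause_2","cause_3"
0,"male",1970,8,"746.9","",""
0,"female",1970,8,"745.4","",""
1,"male",1985,9,"745.0","428.0",""
2,"female",1985,9,"747.41","",""
45,"male",2005,10,"Q21.0","","I50.9"
30,"female",2005,10,"Q24.9","",""
0,"male",1970,8,"745.1","798.0",""
5,"female",1985,9,"038.9","745.5",""
60,"male",2005,10,"I21.9","Q20.3",""
70,"female",2005,10,"I50.0","Q25.0",""
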