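species,group,endpoint,effect_class,concentration,duration,source,provenance_ok
Chlorolobion braunii,algae,NOEC,chronic_lethal,3995,4,ref70,TRUE
Asellus aquaticus,crustaceans,NOEC,chronic_lethal,2000,21,ref71,TRUE
Daphnia magna,crustaceans,NOEC,chronic_lethal,5000,21,ref8,TRUE
Gammarus fossarum,crustaceans,NOEC,chronic_lethal,500,103,ref72,TRUE
Chironomus tentans,insects,NOEC,chronic_lethal,1400,4,ref73,TRUE
Potamopyrgus antipodarum,molluscs,NOEC,chronic_lethal,100,28,ref74,TRUE
Valvata piscinalis,molluscs,NOEC,chronic_lethal,100,28,ref74,TRUE
Rhinella arenarum,amphibians,NOEC,chronic_lethal,1799,14,ref75,TRUE
Xenopus laevis,amphibians,NOEC,chronic_lethal,23,84,ref76,TRUE
Danio rerio,fish,NOEC,chronic_lethal,1500,21,ref77,TRUE
Oryzias latipes,fish,NOEC,chronic_lethal,598,44,ref78,TRUE
Pimephales promelas,fish,NOEC,chronic_lethal,130,164,ref79,TRUE
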