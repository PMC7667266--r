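ligand_id,name,n,logb1,logb2,logb3,logb4,logb5,logb6,ionic_strength,temperature,source
NTA,"2,2',2''-Nitrilotriacetic acid",3,9.84,12.40,14.23,,,,0.1,25,Daniele
MNTA,"N,N-Bis(carboxymethyl)alanine",3,10.39,12.83,14.27,,,,0.1,20,Riecanska
GLDA,"N,N-Bis(carboxymethyl)glutamic acid",4,9.36,14.39,17.88,20.44,,,0.1,25,GorelovNikolskii
HIMDA,"2,2'-[(2-Hydroxyethyl)imino]diacetic acid",3,8.59,10.83,12.29,,,,1.0,25,Anderegg
EDDM,"2,2'-(1,2-Ethanediyldiimino)dimalonic acid",4,9.4,16.16,19.06,21.27,,,0.1,25,GorelovBabich
EDDS,"2,2'-(1,2-Ethanediyldiimino)disuccinic acid",6,10.1,17.01,20.85,23.90,25.3,27.4,0.1,25,Orama
EDDG,"2,2'-(1,2-Ethanediyldiimino)diglutamic acid",4,9.46,16.27,20.52,23.80,,,0.1,25,GorelovBabich
IDS,"2,2'-Iminodisuccinic acid",5,10.28,14.77,18.23,20.81,22.83,,0.1,25,Knyazeva
EDTA,"2,2',2'',2'''-(1,2-Ethanediyldinitrilo)tetraacetic acid",4,10.21,16.41,19.18,21.20,,,0.1,25,Gridchin
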