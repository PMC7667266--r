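metal_id,ligand_id,log_beta_ml,ionic_strength,temperature,source
Cd,NTA,9.8,0.1,20,SchwarzenbachGut
Pb,NTA,11.34,0.1,25,FelcmanDaSilva
Hg,NTA,13.48,0.5,25,Gritmon
Fe,NTA,15.87,0.1,25,MotekaitisMartell
Mn,NTA,7.44,0.1,20,SchwarzenbachFreitag
Cu,NTA,12.94,0.1,25,FelcmanDaSilva
Zn,NTA,10.67,0.1,20,Schwarzenbach
Ca,NTA,6.57,0.1,25,MoellerFerrus
Cd,MNTA,10.61,0.1,20,Riecanska
Pb,MNTA,12.07,0.1,20,Riecanska
Cu,MNTA,13.88,0.1,20,Riecanska
Zn,MNTA,11.06,0.1,20,Riecanska
Ca,MNTA,6.97,0.1,20,Riecanska
Mg,MNTA,5.83,0.1,20,Riecanska
Hg,GLDA,14.33,0.1,25,GorelovNikolskii
Cu,GLDA,13.09,0.1,25,GorelovNikolskii
Ca,GLDA,5.18,0.1,25,GorelovNikolskii
Mg,GLDA,5.93,0.1,25,GorelovNikolskii
Cd,HIMDA,7.21,0.3,25,Kodama
Pb,HIMDA,9.45,0.1,25,FelcmanDaSilva
Hg,HIMDA,5.48,0.1,20,Schwarzenbach
Fe,HIMDA,11.60,1.0,25,Anderegg
Mn,HIMDA,5.55,0.1,20,Schwarzenbach
Cu,HIMDA,11.72,0.1,25,FelcmanDaSilva
Zn,HIMDA,8.02,0.3,25,Kodama
Ca,HIMDA,4.58,0.1,25,MighriRumpf
Mg,HIMDA,3.5,0.1,25,VerdierPiro
Pb,EDDM,11.12,0.1,25,Gorelov
Hg,EDDM,18.64,0.1,25,GorelovBabich
Mn,EDDM,8.50,0.1,25,SamsonovGorelov
Cu,EDDM,13.0,0.1,25,Mashihara
Ca,EDDM,4.80,0.1,25,GorelovBabich
Mg,EDDM,4.51,0.1,25,GorelovBabich
Cd,EDDS,10.3,0.1,25,Vasilev
Pb,EDDS,11.3,0.1,25,Vasilev
Hg,EDDS,14.40,0.1,25,VasilevZaitseva
Fe,EDDS,20.6,0.1,25,Orama
Mn,EDDS,8.63,0.1,25,VasilevZaitseva
Cu,EDDS,18.7,0.1,25,Orama
Zn,EDDS,13.58,0.1,25,Orama
Ca,EDDS,4.58,0.1,25,Vasilev
Mg,EDDS,5.82,0.1,25,GorelovBabich
Cd,EDDG,8.76,0.1,25,GorelovBabich
Pb,EDDG,8.62,0.1,25,GorelovBabich
Hg,EDDG,16.66,0.1,25,GorelovBabich
Fe,EDDG,15.7,0.1,30,SunarTrivedi
Mn,EDDG,6.74,0.1,25,SamsonovGorelov
Cu,EDDG,12.65,0.1,,Trivedi
Zn,EDDG,10.25,0.1,25,GorelovBabich
Ca,EDDG,2.59,0.1,25,GorelovBabich
Mg,EDDG,3.0,0.1,25,GorelovBabich
Fe,IDS,14.70,0.1,25,NikolskiiKnyazeva
Cu,IDS,12.69,0.1,25,VasilevAl
Zn,IDS,10.30,0.1,25,VasilevAl
Ca,IDS,4.63,0.1,25,Vasilev
Mg,IDS,5.52,0.1,25,Vasilev
Cd,EDTA,16.41,0.1,25,SarmaRay
Pb,EDTA,17.93,0.1,25,SarmaRay
Hg,EDTA,22.02,0.1,25,Brunetti
Fe,EDTA,25.10,0.1,25,Delgado
Mn,EDTA,13.8,0.1,25,SarmaRay
Cu,EDTA,18.7,0.1,25,SarmaRay
Zn,EDTA,16.39,0.1,25,SarmaRay
Ca,EDTA,10.69,0.1,25,SarmaRay
Mg,EDTA,8.9,0.1,25,SarmaRay
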