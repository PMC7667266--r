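metal_id,charge,atomic_weight,hydrolysis_k,hydrolysis_logb
Cd,2,112.41,,
Pb,2,207.20,,
Hg,2,200.59,,
Fe,3,55.845,,
Mn,2,54.938,,
Cu,2,63.55,,
Zn,2,65.38,,
Ca,2,40.078,,
Mg,2,24.305,,
Ni,2,58.69,,
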