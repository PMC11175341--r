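compound,flavor,otv_low,otv_high,beer_low,beer_high
Diacetyl,"butterscotch, buttery",0.10,0.17,0.01,0.12
Isobutanol,alcoholic,10,100,4,24
2-Phenylethanol,"rosy, sweetish",5,125,4,51
Ethyl acetate,"solvent-like, fruity, sweet",25,30,8,32
Acetaldehyde,"grassy, green leaves",10,15,2,20
Dimethyl sulfide,"herbaceous, celery-like",0.09,0.60,0.01,0.14
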