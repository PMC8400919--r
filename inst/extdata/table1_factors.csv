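name,units,low,centre,high,is_dummy
Metanol,uL,98,100,102,FALSE
Mtbe1,uL,196,200,204,FALSE
vortex1,min,165,180,195,FALSE
MTBE2,uL,315,320,325,FALSE
H20,uL,226,230,234,FALSE
Vortex2,min,50,60,70,FALSE
Centrifugation,min,9,10,11,FALSE
Volume for Evaporation,uL,196,200,204,FALSE
Evaporation Temperature,degC,33,35,37,FALSE
Solvent Volume for Reconstitution,uL,196,200,204,FALSE
Dummy Factor,,-1,0,1,TRUE
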