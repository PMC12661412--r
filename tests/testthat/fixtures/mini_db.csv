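# version: '1'
# nu_max: 3
species,Z,A,energy,unit,nu,f_per_nm,se_per_nm
p,1,1,1,MeV,1,0.5,0.01
p,1,1,1,MeV,2,0.3,0.01
p,1,1,1,MeV,3,0.1,0.005
p,1,1,10,MeV,1,0.25,0.01
p,1,1,10,MeV,2,0.15,0.01
p,1,1,10,MeV,3,0.05,0.005
p,1,1,100,MeV,1,0.12,0.01
p,1,1,100,MeV,2,0.07,0.01
p,1,1,100,MeV,3,0.02,0.005
C,6,12,0.5,MeV/u,1,2.0,0.05
C,6,12,0.5,MeV/u,2,1.5,0.05
C,6,12,0.5,MeV/u,3,0.9,0.02
C,6,12,5,MeV/u,1,1.1,0.05
C,6,12,5,MeV/u,2,0.8,0.05
C,6,12,5,MeV/u,3,0.4,0.02
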