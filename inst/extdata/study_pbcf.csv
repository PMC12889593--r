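type,biofilm,microsphere_type,nanodextran,size_nm,charge,t_c,pbcf
FITC-Dx-150,Hydrogel,none,Dx-150,92 - 240,-1.2 ± 0.4 mV,24 min,0.153
FITC-Dx-2000,Hydrogel + neutral spheres,plain,Dx-2000,81 - 330,-2.4 ± 0.7 mV,24 min,0.319
FITC-Dx-150,Hydrogel + neutral spheres,plain,Dx-150,92 - 240,-1.2 ± 0.4 mV,24 min,0.164
FITC-DEAE-150,Hydrogel + neutral spheres,plain,DEAE-150,91 - 183,-0.4 ± 0.4 mV,24 min,0.132
FITC-CM-150,Hydrogel + neutral spheres,plain,CM-150,173 - 1000,-5.7 ± 3.2 mV,24 min,0.160
FITC-Dx-150,Hydrogel + carboxyl (-) spheres,carboxyl,Dx-150,92 - 240,-1.2 ± 0.4 mV,24 min,0.145
FITC-DEAE-150,Hydrogel + carboxyl (-) spheres,carboxyl,DEAE-150,91 - 183,-0.4 ± 0.4 mV,24 min,0.179
FITC-CM-150,Hydrogel + carboxyl (-) spheres,carboxyl,CM-150,173 - 1000,-5.7 ± 3.2 mV,24 min,0.135
FITC-Dx-150,Hydrogel + amino (+) spheres,amino,Dx-150,92 - 240,-1.2 ± 0.4 mV,24 min,0.125
FITC-DEAE-150,Hydrogel + amino (+) spheres,amino,DEAE-150,91 - 183,-0.4 ± 0.4 mV,24 min,0.158
FITC-CM-150,Hydrogel + amino (+) spheres,amino,CM-150,173 - 1000,-5.7 ± 3.2 mV,24 min,0.068
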