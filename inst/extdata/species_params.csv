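species,slope_bb,intercept_bb,gs_ki,gs_kd,vpmax,vcmax,tau_rubisco,f_vmpepc,f_vmrubisco,pdrp,rd
original,4.53,0.020,0.227,0.071,120,60,5,1,0.85,0.040,1
maize,5.183,0.036,0.127,0.123,124.128,49.919,3.881,0.72,0.67,0.058,2.282
sorghum,4.843,0.019,0.257,0.377,133.626,51.082,9.714,0.68,0.56,0.038,0.979
sugarcane,4.941,0.027,0.204,0.221,83.840,52.783,4.776,0.92,0.67,0.037,1.446
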