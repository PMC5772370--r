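condition,poloxamer_percent,size_nm,size_sd_nm,particles_per_ml,particles_sd,molecules_per_particle
SLN1,5,232.1,2.7,61.3e12,0.2e12,2.0e6
SLN2,3,284.2,9.9,33.6e12,0.6e12,3.7e6
SLN3,1,499.1,0.4,27.2e12,0.5e12,4.6e6
SLN4,0.25,540.9,20.5,23.3e12,0.8e12,5.4e6
SLN5,0.1,1644.3,255.9,4.8e12,0.1e12,2.6e7
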