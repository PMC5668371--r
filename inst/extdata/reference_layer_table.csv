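# Published per-layer densities of total (NeuN+) and GABA+ neurons (cells/mm^2)
# and the proportion of GABA+ neurons (%) in rat V1, young adult vs old,
# transcribed from the source study's layer table (means +/- SD).
layer,group,neun_density_mean,neun_density_sd,gaba_density_mean,gaba_density_sd,proportion_mean,proportion_sd
I,young,3309,817,2765,839,82.6,10.6
II-III,young,14668,2948,2139,542,14.8,3.0
IV,young,17882,2928,3034,681,16.8,2.1
V,young,16261,3413,2779,495,18.1,5.6
VI,young,13098,3551,1821,534,14.3,3.2
I,old,3282,522,954,502,29.1,13.8
II-III,old,14568,2749,771,242,5.3,1.3
IV,old,17401,1879,881,196,5.1,1.3
V,old,15868,2275,1117,426,6.9,2.3
VI,old,12887,3869,483,151,4.1,1.9
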