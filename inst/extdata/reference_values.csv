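# Group summary statistics reported by the source single-unit + histology study
# of young adult vs senescent rat primary visual cortex (transcribed printed
# values; means +/- SD as published). n is the published sample size where
# stated (79/83 neurons for response metrics, 6 rats per group for blots);
# NA where the study does not print one.
metric,group,mean,sd,n,units
osi,young,0.71,0.18,79,dimensionless
osi,old,0.48,0.18,83,dimensionless
dsi,young,0.48,0.25,79,dimensionless
dsi,old,0.33,0.17,83,dimensionless
or,young,47.1,27.9,79,spikes/s
or,old,99.1,29.5,83,spikes/s
ar,young,21.9,17.3,79,spikes/s
ar,old,61.5,23.2,83,spikes/s
sa,young,3.4,2.6,79,spikes/s
sa,old,24.7,11.7,83,spikes/s
snr,young,18.3,14.7,79,dimensionless
snr,old,5.2,3.2,83,dimensionless
gad65_intensity,young,0.153,0.045,NA,normalized
gad65_intensity,old,0.136,0.048,NA,normalized
gad67_intensity,young,0.166,0.039,NA,normalized
gad67_intensity,old,0.086,0.032,NA,normalized
gabaar_intensity,young,0.152,0.037,NA,normalized
gabaar_intensity,old,0.118,0.035,NA,normalized
gad65_blot,young,0.671,0.063,6,od_ratio
gad65_blot,old,0.595,0.056,6,od_ratio
gad67_blot,young,0.872,0.079,6,od_ratio
gad67_blot,old,0.694,0.075,6,od_ratio
gabaar_blot,young,0.513,0.099,6,od_ratio
gabaar_blot,old,0.308,0.127,6,od_ratio
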