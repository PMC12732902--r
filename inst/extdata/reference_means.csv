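# Species-mean concentrations (mg/100 g dry weight) for six commercial
# bivalves, keyed in from a published comparative umami survey.
# provenance: reported_mean = mean printed directly (SD printed for
# nucleotides); tav_x_threshold = mean recovered as printed TAV (2 dp) x
# detection threshold, so it carries the TAV's rounding (+-0.005 x T).
# Values the publication does not print are absent rows.
species,compound,mean,sd,n,provenance
M. meretrix,GMP,253.83,27.46,10,reported_mean
C. sinensis,GMP,196.48,19.44,10,reported_mean
M. mercenaria,GMP,243.11,25.96,10,reported_mean
R. philippinarum,GMP,203.02,9.93,10,reported_mean
C. sikamea,GMP,265.17,100.1,10,reported_mean
S. constricta,GMP,226.08,22.66,10,reported_mean
M. meretrix,AMP,111.14,46.93,10,reported_mean
C. sinensis,AMP,51.08,9.08,10,reported_mean
M. mercenaria,AMP,131.29,21.75,10,reported_mean
R. philippinarum,AMP,64.26,14.1,10,reported_mean
C. sikamea,AMP,152.49,66.28,10,reported_mean
S. constricta,AMP,31.34,17.04,10,reported_mean
C. sikamea,Glu,553.46,NA,10,reported_mean
R. philippinarum,Glu,285.03,NA,10,reported_mean
S. constricta,Glu,325.51,NA,10,reported_mean
C. sinensis,Glu,496.8,NA,10,tav_x_threshold
M. meretrix,Glu,434.1,NA,10,tav_x_threshold
M. mercenaria,Glu,375.6,NA,10,tav_x_threshold
C. sikamea,Asp,320,NA,10,tav_x_threshold
C. sinensis,Asp,86,NA,10,tav_x_threshold
M. mercenaria,Asp,328,NA,10,tav_x_threshold
S. constricta,Ala,149.34,NA,10,tav_x_threshold
M. meretrix,Ala,96.3,NA,10,tav_x_threshold
C. sinensis,Ala,78.18,NA,10,tav_x_threshold
C. sikamea,Ala,45.84,NA,10,tav_x_threshold
R. philippinarum,Ala,34.5,NA,10,tav_x_threshold
M. mercenaria,Ala,34.26,NA,10,tav_x_threshold
C. sinensis,Arg,743,NA,10,tav_x_threshold
S. constricta,Arg,634,NA,10,tav_x_threshold
R. philippinarum,Arg,425.5,NA,10,tav_x_threshold
M. meretrix,Arg,276.5,NA,10,tav_x_threshold
M. mercenaria,Arg,236.5,NA,10,tav_x_threshold
C. sikamea,Arg,100,NA,10,tav_x_threshold
M. mercenaria,Tau,2434.33,NA,10,reported_mean
C. sikamea,Tau,2046,NA,10,reported_mean
S. constricta,Tau,322.1,NA,10,reported_mean
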