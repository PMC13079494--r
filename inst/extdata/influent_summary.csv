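analyte_name,detection_frequency,cumulative_conc,cumulative_conc_sd,dl_mg_day,dl_sd,pndl,pndl_sd
PFBS,2,43.8,13.5,10039,3092,12,3
PFBA,1,0,0,0,0,0,0
PFHpA,1,0,0,0,0,0,0
PFOA,3,8.5,0.6,1935,147,4,0.2
PFNA,1,20.1,0.00,13825,0,17,0
PFDA,1,22.3,0.00,5099,0,6,0
6:2 FTS,1,0,0,0,0,0,0
8:2 diPAP,3,198.1,109.1,45369,24984,55,30
PFOPA,3,85.4,23.1,19563,5296,24,6
PFDPA,3,92.9,28.4,21280,6500,26,8
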