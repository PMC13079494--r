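analyte_name,recovery,recovery_sd,mdl_ngL,mql_ngL,method_accuracy,method_precision
PFBS,118.2,18.5,0.03,0.08,80.5,4.7
PFHxS,110.4,18.3,0.3,0.9,91.0,8.9
PFHpS,103.2,13.2,159.9,484.6,86.2,11.5
PFOS,170.8,31.8,1.0,2.9,92.7,20.8
PFNS,80.9,18.7,102.0,308.9,98.9,23.2
PFOSA,70.6,27.0,467.2,1415.8,111.9,42.6
n-MeFOSA,43.6,0.6,756.9,2293.6,99.8,1.7
n-EtFOSA,33.2,1.4,496.7,1505.1,94.0,2.5
n-MeFOSAA,44.4,19.1,7.4,22.5,90.4,36.8
n-EtFOSAA,31.1,13.8,106.2,321.9,136.3,32.0
PFBA,122.7,31.5,0.03,0.08,90.4,15.4
PFPeA,104.0,19.0,31.8,96.2,146.6,24.4
PFHxA,125.0,28.3,1.3,4.0,123.8,25.6
PFHpA,128.3,27.5,0.1,0.4,95.1,20.4
PFOA,113.0,21.2,0.2,0.4,87.9,7.4
PFNA,149.5,25.6,2.2,6.7,85.4,20.4
PFDA,103.2,31.3,1.6,4.9,108.4,18.2
PFUnDA,50.1,24.5,65.9,199.8,68.9,15.4
PFDoDA,44.0,11.4,37.5,113.7,85.6,6.2
PFTrDA,11.5,5.2,14.3,43.3,68.9,29.6
PFTeDA,7.6,2.9,0.4,1.3,119.7,28.3
6:2 FTS,110.4,15.8,1.5,4.5,75.5,8.8
8:2 FTS,296.3,61.9,0.6,1.7,59.0,9.1
5:3 FTC,107.6,20.4,0.3,0.9,88.4,27.9
6:2 diPAP,20.8,5.7,158.8,481.2,131.0,27.9
8:2 diPAP,16.8,6.1,0.2,0.6,129.0,18.1
PFHxPA,135.3,15.5,0.2,0.7,91.7,26.2
PFOPA,107.6,30.5,1.5,4.7,94.3,5.6
PFDPA,239.1,73.5,0.7,2.1,86.1,14.0
6:6 PFPiA,45.5,16.4,3.6,11.0,63.3,5.8
8:8 PFPiA,6.3,1.7,2.6,8.0,114.3,25.5
8:2 monoPAP,,,,,,
Gen X,103.3,18.8,0.3,1.0,71.4,16.7
ADONA,75.7,12.2,0.4,1.3,69.7,13.8
9ClPF3ONS,114.0,22.5,72.4,219.3,93.7,13.8
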