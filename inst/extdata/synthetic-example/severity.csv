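participant_id,ABC_total,ATEC_total,PDD_BI,PGI_R2,SRS,SSP,CARS_2,SAS_parent,Pro_SAS,ADOS_raw,ADOS_adj,ABC_irritability,ABC_lethargy,ABC_stereotypy,ABC_hyperactivity,ABC_speech
ASD-001,62.1,80.1,249.4,2.6,143.5,100.2,54.7,7.4,8.7,27.3,21.9,32.5,18.8,19.1,42.1,9.6
ASD-002,45.8,57.7,195.4,1.9,98.1,142.5,43.9,6.7,8,36.1,14.2,23,0,7.3,41.9,8.7
ASD-003,80.1,38.9,64.8,2.4,135.2,93.1,29.1,5.3,5.3,16.1,11.8,19.2,9.8,6.1,4.7,1.3
ASD-004,128.6,32.1,41.6,3.1,44.5,136.4,20.9,4.1,4,0,20.2,0,33.3,25.8,2.3,10.1
ASD-005,11.2,23.3,0,0,32.2,115.9,11,2,1.6,0.2,5.5,0,5.6,0,0,0
ASD-006,36.6,31.3,87.9,1.4,101.6,147.6,28.5,6,9.6,17.1,14,13.5,0,4,8.2,15
ASD-007,31.3,26.8,0,0.9,84.3,174.7,32.3,1,4.9,5.3,16.3,2.6,20.4,5.8,37.2,1.5
ASD-008,0,0,123.6,1.4,67.9,119.6,29.8,2.7,1.3,10.8,14.6,0,0.6,0,0.4,2.5
ASD-009,56.2,45,67.2,1.4,65.7,95,37,5.7,3.3,2.7,1.6,46.9,11,16,23.8,11.9
ASD-010,119.2,48.5,170.3,3.1,168.9,123.8,34.4,8.2,7.1,19.2,14.4,17.2,11.1,12.8,45.7,18.5
ASD-011,68.3,34.6,119.7,0.7,65.9,108,29.6,3.6,5.4,3,5.3,7.1,0,6.1,22.7,0
ASD-012,74.2,32.2,61.7,0.3,52.1,130,29.4,3.8,1.2,9.4,14.2,0,27.9,0,14.4,2.6
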