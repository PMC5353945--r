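group,sex,onset_age_years,duration_years,age_at_sample,percent_course,strem2_ng_ml
ALS,M,35.8,4.8,36.9,22.8,309.6
ALS,M,50.7,17.0,53.4,16.2,2.6
ALS,M,79.7,1.3,79.8,6.3,10.3
ALS,M,67.4,11.9,72.1,39.2,10.8
ALS,M,71.5,0.8,72.3,90.0,5.7
ALS,F,47.8,14.5,49.3,10.9,3.6
ALS,F,65.3,1.2,66.3,85.7,7.9
ALS,M,64.4,1.0,65.3,100.0,6.9
ALS,M,64.3,0.8,64.8,66.7,2.3
ALS,F,34.4,0.6,34.7,42.9,4.7
ALS,M,54.4,6.9,56.1,24.1,9.0
ALS,M,52.6,5.4,54.0,26.2,27.4
ALS,M,56.4,12.0,57.8,11.8,4.2
ALS,F,76.2,1.0,76.9,75.0,4.9
ALS,F,64.3,0.4,64.5,60.0,8.1
ALS,M,69.4,0.7,69.7,37.5,37.7
ALS,M,42.9,10.5,43.9,9.5,5.3
ALS,M,47.1,1.3,47.7,43.8,18.4
ALS,F,54.2,5.8,54.7,8.7,14.5
ALS,M,57.7,1.1,58.0,30.8,14.8
ALS,F,51.2,5.6,52.3,19.4,22.8
ALS,F,45.2,8.6,46.0,9.7,8.6
ALS,F,59.5,1.4,59.8,17.6,9.9
ALS,M,36.8,4.4,38.7,43.4,8.5
ALS,M,32.0,8.8,37.9,67.0,18.2
ALS,F,50.7,3.8,51.7,26.7,2.9
ALS,M,29.8,4.5,31.5,38.9,2.8
ALS,F,68.5,2.5,69.9,56.7,4.0
ALS,M,81.0,1.6,82.5,94.7,4.3
ALS,M,64.3,4.5,67.6,72.2,25.1
ALS,M,50.6,2.2,51.4,38.5,16.5
ALS,M,65.1,3.6,67.7,72.1,9.7
ALS,F,58.7,1.3,59.6,73.3,16.0
ALS,M,59.2,5.2,62.1,56.5,9.4
ALS,F,60.5,1.7,61.6,65.0,24.8
ALS,M,55.7,1.8,56.9,71.4,16.2
ALS,M,60.1,4.8,62.8,57.9,9.0
ALS,M,65.5,2.4,66.5,41.4,5.1
ALS,F,49.9,3.8,52.5,67.4,17.1
ALS,F,Unavailable,Unavailable,63.8,Unavailable,8.3
ALS,F,52.9,3.4,54.3,41.5,5.1
ALS,M,50.8,2.6,51.4,25.8,7.3
ALS,F,62.1,7.7,68.3,80.4,34.9
ALS,M,32.9,2.6,33.9,38.7,4.7
ALS,F,47.3,1.7,47.8,30.0,4.4
ALS,M,66.6,3.9,69.6,76.6,7.9
Control,M,NA,NA,828,NA,4.0
Control,M,NA,NA,407,NA,6.5
Control,F,NA,NA,717,NA,10.6
Control,F,NA,NA,671,NA,7.0
Control,F,NA,NA,628,NA,2.9
Control,M,NA,NA,573,NA,3.4
Control,F,NA,NA,542,NA,2.6
Control,F,NA,NA,563,NA,4.8
Control,M,NA,NA,455,NA,5.9
Control,M,NA,NA,586,NA,4.8
Control,M,NA,NA,473,NA,14.2
Control,F,NA,NA,587,NA,3.1
Control,F,NA,NA,594,NA,12.9
Control,M,NA,NA,886,NA,9.4
Control,M,NA,NA,782,NA,14.7
Control,M,NA,NA,553,NA,12.3
Control,M,NA,NA,502,NA,5.1
Control,F,NA,NA,701,NA,8.9
Control,M,NA,NA,673,NA,6.7
Control,F,NA,NA,475,NA,3.4
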