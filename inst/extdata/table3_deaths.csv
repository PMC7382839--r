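exposure,site,sex,total,paf_percent,attributable
smoking,lung,men,2055,90.7,1865
smoking,lung,women,1525,87.3,1332
smoking,lung,both,3580,89.3,3197
smoking,larynx,men,148,85.7,127
smoking,larynx,women,23,82.2,19
smoking,larynx,both,171,85.2,146
smoking,oral_cavity_pharynx,men,140,63.9,89
smoking,oral_cavity_pharynx,women,66,59.1,39
smoking,oral_cavity_pharynx,both,206,62.4,129
smoking,esophagus,men,362,58.9,213
smoking,esophagus,women,306,56.8,174
smoking,esophagus,both,668,57.9,387
smoking,bladder,men,417,57.9,241
smoking,bladder,women,201,50.7,102
smoking,bladder,both,618,55.5,343
smoking,liver,men,778,36.7,285
smoking,liver,women,666,18.6,124
smoking,liver,both,1444,28.3,409
smoking,stomach,men,2342,30.8,721
smoking,stomach,women,1136,16.8,191
smoking,stomach,both,3478,26.2,912
smoking,cervix,women,725,25.4,184
smoking,cervix,both,725,25.4,184
smoking,kidney,men,636,29.2,185
smoking,kidney,women,342,8.7,30
smoking,kidney,both,978,22.0,215
smoking,pancreas,men,763,16.7,127
smoking,pancreas,women,816,21.6,176
smoking,pancreas,both,1579,19.2,304
smoking,myeloid_leukemia,men,406,29.4,119
smoking,myeloid_leukemia,women,402,4.5,18
smoking,myeloid_leukemia,both,808,17.0,138
smoking,colorectum,men,1538,16.1,247
smoking,colorectum,women,1562,16.5,258
smoking,colorectum,both,3100,16.3,505
high_bmi,corpus_uteri,women,295,44.8,132
high_bmi,corpus_uteri,both,295,44.8,132
high_bmi,kidney,men,636,26.7,170
high_bmi,kidney,women,342,29.4,100
high_bmi,kidney,both,978,27.6,270
high_bmi,gallbladder,men,560,22.1,124
high_bmi,gallbladder,women,1063,26.8,285
high_bmi,gallbladder,both,1623,25.2,409
high_bmi,liver,men,778,20.5,159
high_bmi,liver,women,666,23.2,155
high_bmi,liver,both,1444,21.7,314
high_bmi,colorectum,men,1538,17.8,274
high_bmi,colorectum,women,1562,11.2,175
high_bmi,colorectum,both,3100,14.5,449
high_bmi,breast,women,1688,13.0,220
high_bmi,breast,both,1688,13.0,220
high_bmi,pancreas,men,763,13.4,102
high_bmi,pancreas,women,816,12.1,99
high_bmi,pancreas,both,1579,12.7,201
high_bmi,multiple_myeloma,men,328,11.5,38
high_bmi,multiple_myeloma,women,284,8.7,25
high_bmi,multiple_myeloma,both,612,10.2,63
high_bmi,thyroid,men,49,17.1,8
high_bmi,thyroid,women,106,6.3,7
high_bmi,thyroid,both,155,9.7,15
high_bmi,prostate,men,2270,8.6,195
high_bmi,prostate,both,2270,8.6,195
high_bmi,ovary,women,469,7.5,35
high_bmi,ovary,both,469,7.5,35
high_bmi,stomach,men,2342,7.1,165
high_bmi,stomach,women,1136,5.5,63
high_bmi,stomach,both,3478,6.6,228
high_bmi,esophagus,men,362,6.5,23
high_bmi,esophagus,women,306,6.1,19
high_bmi,esophagus,both,668,6.3,42
alcohol,oral_cavity_pharynx,men,140,44.6,62
alcohol,oral_cavity_pharynx,women,66,11.1,7
alcohol,oral_cavity_pharynx,both,206,33.9,70
alcohol,esophagus,men,362,39.7,144
alcohol,esophagus,women,306,16.8,51
alcohol,esophagus,both,668,29.2,195
alcohol,larynx,men,148,25.9,38
alcohol,larynx,women,23,7.9,2
alcohol,larynx,both,171,23.5,40
alcohol,gallbladder,men,560,15.3,86
alcohol,gallbladder,women,1063,5.8,61
alcohol,gallbladder,both,1623,9.1,147
alcohol,liver,men,778,8.4,65
alcohol,liver,women,666,5.1,34
alcohol,liver,both,1444,6.9,99
alcohol,colorectum,men,1538,12.1,186
alcohol,colorectum,women,1562,1.1,18
alcohol,colorectum,both,3100,6.6,203
alcohol,breast,women,1688,4.2,72
alcohol,breast,both,1688,4.2,72
alcohol,pancreas,men,763,4.2,32
alcohol,pancreas,women,816,0.7,5
alcohol,pancreas,both,1579,2.4,38
physical_activity,colorectum,men,1538,13.6,210
physical_activity,colorectum,women,1562,16.7,261
physical_activity,colorectum,both,3100,15.2,470
physical_activity,breast,women,1688,11.2,190
physical_activity,breast,both,1688,11.2,190
fruit_veg,larynx,men,148,25.2,37
fruit_veg,larynx,women,23,23.2,5
fruit_veg,larynx,both,171,25.0,43
fruit_veg,oral_cavity_pharynx,men,140,25.2,35
fruit_veg,oral_cavity_pharynx,women,66,23.2,15
fruit_veg,oral_cavity_pharynx,both,206,24.6,51
fruit,lung,men,2055,14.3,294
fruit,lung,women,1525,13.6,207
fruit,lung,both,3580,14.0,501
passive_smoking,lung,men,2055,2.2,46
passive_smoking,lung,women,1525,1.6,24
passive_smoking,lung,both,3580,2.0,70
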