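exposure,site,sex,total,paf_percent,attributable
smoking,lung,men,2163,90.7,1963
smoking,lung,women,1708,87.3,1492
smoking,lung,both,3871,89.2,3454
smoking,larynx,men,225,85.7,193
smoking,larynx,women,28,82.2,23
smoking,larynx,both,253,85.3,216
smoking,oral_cavity_pharynx,men,299,63.9,191
smoking,oral_cavity_pharynx,women,219,59.1,129
smoking,oral_cavity_pharynx,both,518,61.9,321
smoking,esophagus,men,412,58.9,243
smoking,esophagus,women,372,56.8,211
smoking,esophagus,both,784,57.9,454
smoking,bladder,men,964,57.9,558
smoking,bladder,women,382,50.7,194
smoking,bladder,both,1346,55.8,752
smoking,liver,men,866,36.7,317
smoking,liver,women,709,18.6,132
smoking,liver,both,1575,28.5,449
smoking,stomach,men,3429,30.8,1056
smoking,stomach,women,1733,16.8,291
smoking,stomach,both,5162,26.1,1348
smoking,cervix,women,1546,25.4,392
smoking,cervix,both,1546,25.4,392
smoking,kidney,men,1215,29.2,354
smoking,kidney,women,705,8.7,61
smoking,kidney,both,1920,21.6,415
smoking,pancreas,men,794,16.7,133
smoking,pancreas,women,841,21.6,182
smoking,pancreas,both,1635,19.2,314
smoking,myeloid_leukemia,men,522,29.4,153
smoking,myeloid_leukemia,women,514,4.5,23
smoking,myeloid_leukemia,both,1036,17.1,177
smoking,colorectum,men,2952,16.1,474
smoking,colorectum,women,2821,16.5,466
smoking,colorectum,both,5773,16.3,940
high_bmi,corpus_uteri,women,933,44.8,418
high_bmi,corpus_uteri,both,933,44.8,418
high_bmi,kidney,men,1215,26.7,324
high_bmi,kidney,women,705,29.4,207
high_bmi,kidney,both,1920,27.7,531
high_bmi,gallbladder,men,851,22.1,188
high_bmi,gallbladder,women,1848,26.8,496
high_bmi,gallbladder,both,2699,25.3,683
high_bmi,liver,men,866,20.5,177
high_bmi,liver,women,709,23.2,165
high_bmi,liver,both,1575,21.7,342
high_bmi,colorectum,men,2952,16.7,492
high_bmi,colorectum,women,2821,10.8,304
high_bmi,colorectum,both,5773,13.8,796
high_bmi,pancreas,men,794,13.4,107
high_bmi,pancreas,women,841,12.1,102
high_bmi,pancreas,both,1635,12.7,208
high_bmi,breast,women,5391,11.2,603
high_bmi,breast,both,5391,11.2,603
high_bmi,multiple_myeloma,men,434,11.5,50
high_bmi,multiple_myeloma,women,389,8.7,34
high_bmi,multiple_myeloma,both,823,10.2,84
high_bmi,thyroid,men,173,17.1,29
high_bmi,thyroid,women,875,6.3,55
high_bmi,thyroid,both,1048,8.1,85
high_bmi,ovary,women,826,7.5,62
high_bmi,ovary,both,826,7.5,62
high_bmi,stomach,men,3429,7.1,242
high_bmi,stomach,women,1733,5.5,95
high_bmi,stomach,both,5162,6.5,338
high_bmi,esophagus,men,412,6.5,27
high_bmi,esophagus,women,372,6.1,23
high_bmi,esophagus,both,784,6.3,50
high_bmi,prostate,men,6574,3.0,195
high_bmi,prostate,both,6574,3.0,195
alcohol,oral_cavity_pharynx,men,299,44.6,133
alcohol,oral_cavity_pharynx,women,219,11.1,24
alcohol,oral_cavity_pharynx,both,518,30.5,158
alcohol,esophagus,men,412,39.7,163
alcohol,esophagus,women,372,16.8,63
alcohol,esophagus,both,784,28.8,226
alcohol,larynx,men,225,25.9,58
alcohol,larynx,women,28,7.9,2
alcohol,larynx,both,253,23.9,61
alcohol,gallbladder,men,851,15.3,130
alcohol,gallbladder,women,1848,5.8,107
alcohol,gallbladder,both,2699,8.8,237
alcohol,liver,men,866,8.4,73
alcohol,liver,women,709,5.1,36
alcohol,liver,both,1575,6.9,109
alcohol,colorectum,men,2952,12.1,356
alcohol,colorectum,women,2821,1.1,32
alcohol,colorectum,both,5773,6.7,388
alcohol,breast,women,5391,4.2,229
alcohol,breast,both,5391,4.2,229
alcohol,pancreas,men,794,4.2,34
alcohol,pancreas,women,841,0.7,6
alcohol,pancreas,both,1635,2.4,39
physical_activity,colorectum,men,2952,11.4,336
physical_activity,colorectum,women,2821,15.2,428
physical_activity,colorectum,both,5773,13.2,764
physical_activity,breast,women,5391,9.6,520
physical_activity,breast,both,5391,9.6,520
fruit_veg,larynx,men,225,25.2,57
fruit_veg,larynx,women,28,23.2,7
fruit_veg,larynx,both,253,25.0,63
fruit_veg,oral_cavity_pharynx,men,299,25.2,75
fruit_veg,oral_cavity_pharynx,women,219,23.2,51
fruit_veg,oral_cavity_pharynx,both,518,24.4,126
fruit,lung,men,2163,14.3,310
fruit,lung,women,1708,13.6,232
fruit,lung,both,3871,14.0,542
passive_smoking,lung,men,2163,2.2,48
passive_smoking,lung,women,1708,1.6,27
passive_smoking,lung,both,3871,1.9,75
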