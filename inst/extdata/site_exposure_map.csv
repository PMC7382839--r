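exposure,site,sex_restriction
smoking,lung,
smoking,larynx,
smoking,oral_cavity_pharynx,
smoking,esophagus,
smoking,bladder,
smoking,liver,
smoking,stomach,
smoking,cervix,women
smoking,kidney,
smoking,pancreas,
smoking,myeloid_leukemia,
smoking,colorectum,
high_bmi,corpus_uteri,women
high_bmi,kidney,
high_bmi,gallbladder,
high_bmi,liver,
high_bmi,colorectum,
high_bmi,pancreas,
high_bmi,breast,women
high_bmi,multiple_myeloma,
high_bmi,thyroid,
high_bmi,ovary,women
high_bmi,stomach,
high_bmi,esophagus,
high_bmi,prostate,men
alcohol,oral_cavity_pharynx,
alcohol,esophagus,
alcohol,larynx,
alcohol,gallbladder,
alcohol,liver,
alcohol,colorectum,
alcohol,breast,women
alcohol,pancreas,
physical_activity,colorectum,
physical_activity,breast,women
fruit_veg,larynx,
fruit_veg,oral_cavity_pharynx,
fruit,lung,
passive_smoking,lung,
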