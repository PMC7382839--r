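site,sex,cases,deaths
lung,men,2163,2055
lung,women,1708,1525
larynx,men,225,148
larynx,women,28,23
oral_cavity_pharynx,men,299,140
oral_cavity_pharynx,women,219,66
esophagus,men,412,362
esophagus,women,372,306
bladder,men,964,417
bladder,women,382,201
liver,men,866,778
liver,women,709,666
stomach,men,3429,2342
stomach,women,1733,1136
cervix,women,1546,725
kidney,men,1215,636
kidney,women,705,342
pancreas,men,794,763
pancreas,women,841,816
myeloid_leukemia,men,522,406
myeloid_leukemia,women,514,402
colorectum,men,2952,1538
colorectum,women,2821,1562
corpus_uteri,women,933,295
gallbladder,men,851,560
gallbladder,women,1848,1063
breast,women,5391,1688
multiple_myeloma,men,434,328
multiple_myeloma,women,389,284
thyroid,men,173,49
thyroid,women,875,106
ovary,women,826,469
prostate,men,6574,2270
all_sites,both,50320,28010
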