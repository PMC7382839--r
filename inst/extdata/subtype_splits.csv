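site,sex,subtype,fraction,applies_to_exposure
stomach,men,cardia,0.32,high_bmi
stomach,women,cardia,0.22,high_bmi
stomach,men,non_cardia,0.68,
stomach,women,non_cardia,0.78,
esophagus,men,adenocarcinoma,0.15,high_bmi
esophagus,women,adenocarcinoma,0.14,high_bmi
esophagus,men,squamous_cell,0.85,alcohol
esophagus,women,squamous_cell,0.86,alcohol
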