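exposure,sex,mean,sd,cf_mean,cf_sd,sd_source
high_bmi,men,28.42,4.5,22,1,synthetic
high_bmi,women,29.62,5.0,22,1,synthetic
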