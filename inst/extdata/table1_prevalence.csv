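exposure,sex,level,level_order,proportion,is_tmrel
alcohol,men,abstainer,1,0.205,1
alcohol,men,light,2,0.315,0
alcohol,men,moderate,3,0.391,0
alcohol,men,heavy,4,0.088,0
alcohol,women,abstainer,1,0.441,1
alcohol,women,light,2,0.414,0
alcohol,women,moderate,3,0.138,0
alcohol,women,heavy,4,0.007,0
fruit_veg,men,ge400,1,0.116,1
fruit_veg,men,300_399,2,0.091,0
fruit_veg,men,200_299,3,0.181,0
fruit_veg,men,100_199,4,0.380,0
fruit_veg,men,0_99,5,0.232,0
fruit_veg,women,ge400,1,0.147,1
fruit_veg,women,300_399,2,0.119,0
fruit_veg,women,200_299,3,0.198,0
fruit_veg,women,100_199,4,0.369,0
fruit_veg,women,0_99,5,0.166,0
fruit,men,ge250,1,0.062,1
fruit,men,200_249,2,0.061,0
fruit,men,150_199,3,0.112,0
fruit,men,100_149,4,0.077,0
fruit,men,50_99,5,0.275,0
fruit,men,0_49,6,0.412,0
fruit,women,ge250,1,0.065,1
fruit,women,200_249,2,0.079,0
fruit,women,150_199,3,0.154,0
fruit,women,100_149,4,0.061,0
fruit,women,50_99,5,0.305,0
fruit,women,0_49,6,0.336,0
physical_activity,men,ge8000,1,0.006,1
physical_activity,men,4000_7999,2,0.051,0
physical_activity,men,600_3999,3,0.236,0
physical_activity,men,lt600,4,0.707,0
physical_activity,women,ge8000,1,0.002,1
physical_activity,women,4000_7999,2,0.018,0
physical_activity,women,600_3999,3,0.137,0
physical_activity,women,lt600,4,0.843,0
passive_smoking,men,no,1,0.827,1
passive_smoking,men,yes,2,0.173,0
passive_smoking,women,no,1,0.870,1
passive_smoking,women,yes,2,0.130,0
smoking,men,never,1,0.377,1
smoking,men,former,2,0.289,0
smoking,men,current,3,0.334,0
smoking,women,never,1,0.526,1
smoking,women,former,2,0.216,0
smoking,women,current,3,0.258,0
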