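# population_size: 475580
,ref_RA,ref_notRA,no_ref_data
pred_RA,1323,396,2560
pred_notRA,265,10084,459727
no_gp_data,138,1087,
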