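# Reference breakthrough-model parameter table for the same lysozyme /
# nanofiber-membrane system: fitted (cal) and experimental (exp) capacity or
# midpoint parameters, linearized-regression R^2 and percent error E for the
# Thomas (q in mg/g), Bohart-Adams (N_o in mg/mL), Yoon-Nelson (t_05 in min)
# and BDST (Q_o in mg/mL) models, one row per operating condition.
Z_um,pH,C0,F,thomas_qeq,thomas_qexp,thomas_r2,thomas_E,ba_No,ba_No_exp,ba_r2,ba_E,yn_t05,yn_t05_exp,yn_r2,yn_E,bdst_Qo,bdst_Qo_exp,bdst_r2,bdst_E
115,5,2,1,289.252,459.048,1.000,58.702,191.403,161.827,0.978,15.452,2.169,2.330,1.000,7.401,101.969,161.827,1.000,58.701
115,7,2,1,668.131,733.552,0.997,9.792,282.674,258.596,0.913,8.518,5.011,5.018,0.997,0.140,235.586,258.596,0.997,9.767
115,9,2,1,724.858,769.649,0.910,6.179,318.876,271.322,0.821,14.913,5.436,5.497,0.910,1.114,258.354,271.322,0.910,5.019
115,9,0.5,1,248.667,258.754,0.903,4.056,103.885,91.218,0.803,12.193,7.460,7.500,0.903,0.536,88.390,91.218,0.903,3.200
115,9,1,1,434.273,473.958,0.917,9.138,188.782,167.083,0.903,11.494,6.514,6.546,0.917,0.490,154.530,167.083,0.917,8.123
115,9,2,0.1,906.659,961.588,0.896,6.058,385.754,338.985,0.773,12.124,67.999,68.593,0.896,0.873,323.035,338.985,0.896,4.938
115,9,2,0.5,830.626,875.872,0.961,5.447,358.463,308.768,0.815,13.863,12.459,12.525,0.961,0.524,294.054,308.768,0.961,5.004
345,9,2,1,446.741,469.920,0.874,5.188,190.328,165.659,0.993,12.961,10.052,10.366,0.874,3.129,158.373,165.659,0.874,4.601
575,9,2,1,400.782,433.789,0.960,8.236,167.233,152.922,0.917,8.557,15.029,14.863,0.960,1.106,141.275,152.922,0.960,8.244
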